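INHERITANCE_MODES <- c("underdominance", "dominance_P1",
                       "partial_dominance_P1", "additivity",
                       "partial_dominance_P2", "dominance_P2",
                       "overdominance", "unclassified")

#' Classify the inheritance mode of a cross
#'
#' Compares a hybrid phenotype to its two homozygous parents. With P1 the
#' least-fit and P2 the fittest parent (inputs are relabelled if needed)
#' and MPV = (P1 + P2)/2 the mid-parent value, tolerance widths built from
#' the replicate standard deviations define seven ordered bands on the
#' phenotype axis:
#'
#' * underdominance: `Hyb <  P1 - (sP1 + sHyb)`
#' * dominance_P1: within `P1 +/- (sP1 + sHyb)`
#' * partial_dominance_P1: up to `MPV - ((sP1 + sP2)/2 + sHyb)`
#' * additivity: within `MPV +/- ((sP1 + sP2)/2 + sHyb)`
#' * partial_dominance_P2: up to `P2 - (sP2 + sHyb)`
#' * dominance_P2: within `P2 +/- (sP2 + sHyb)`
#' * overdominance: above
#'
#' Bands are lower-bound inclusive / upper-bound exclusive and evaluated
#' in this order (first match wins when large sds make inner bands empty).
#' The full seven-way call is only made when the parents are phenotypically
#' separable, `P1 + sP1 < P2 - sP2`; otherwise only underdominance and
#' overdominance (same outer bounds) can be called and everything between
#' is `unclassified`.
#'
#' @param P1,P2 parental phenotypes (relabelled so P1 <= P2).
#' @param sigmaP1,sigmaP2,sigmaHyb replicate standard deviations
#'   (non-negative).
#' @param Hyb hybrid phenotype.
#' @return data.frame (one row per input; arguments recycle) with columns
#'   `mode` (factor over the seven modes + unclassified), `separable`,
#'   `mpv`.
#' @export
classify_cross <- function(P1, P2, sigmaP1, sigmaP2, Hyb, sigmaHyb) {
  n <- max(length(P1), length(P2), length(Hyb))
  P1 <- rep_len(P1, n); P2 <- rep_len(P2, n); Hyb <- rep_len(Hyb, n)
  sigmaP1 <- rep_len(sigmaP1, n); sigmaP2 <- rep_len(sigmaP2, n)
  sigmaHyb <- rep_len(sigmaHyb, n)
  if (any(c(sigmaP1, sigmaP2, sigmaHyb) < 0, na.rm = TRUE)) {
    stop("standard deviations must be non-negative")
  }
  # P1 is the least-fit parent by convention
  swap <- P1 > P2
  if (any(swap)) {
    tmp <- P1[swap]; P1[swap] <- P2[swap]; P2[swap] <- tmp
    tmp <- sigmaP1[swap]; sigmaP1[swap] <- sigmaP2[swap]
    sigmaP2[swap] <- tmp
  }
  mpv <- (P1 + P2) / 2
  w1 <- sigmaP1 + sigmaHyb          # width around P1
  w2 <- sigmaP2 + sigmaHyb          # width around P2
  wm <- (sigmaP1 + sigmaP2) / 2 + sigmaHyb  # width around MPV
  separable <- P1 + sigmaP1 < P2 - sigmaP2
  lo <- cbind(-Inf, P1 - w1, P1 + w1, mpv - wm, mpv + wm, P2 - w2, P2 + w2)
  hi <- cbind(lo[, -1, drop = FALSE], Inf)
  inband <- Hyb >= lo & Hyb < hi
  inband[, 1] <- Hyb < hi[, 1]
  first <- max.col(inband, ties.method = "first")
  mode <- INHERITANCE_MODES[first]
  # inseparable parents: only the outer bounds can be called
  insep <- !separable
  mode[insep] <- ifelse(
    Hyb[insep] < (P1 - w1)[insep], "underdominance",
    ifelse(Hyb[insep] >= (P2 + w2)[insep], "overdominance",
           "unclassified"))
  data.frame(mode = factor(mode, levels = INHERITANCE_MODES),
             separable = separable, mpv = mpv)
}

#' Classify every heterozygous cross of a panel
#'
#' Looks up the phenotypes and replicate sds of each heterozygous cross
#' and of its two parents (parents are keyed by their own id or by the
#' selfed hybrid id `PxP`) and calls [classify_cross()] per condition.
#'
#' @param phenotypes phenotype table ([aggregate_replicates()]) holding
#'   hybrids and parents.
#' @param panel a `diallel_panel`.
#' @return data.frame with one row per heterozygous cross x condition:
#'   `parent1`, `parent2`, `hybrid_id`, `condition`, `mode`, `separable`,
#'   `mpv`.
#' @export
classify_inheritance <- function(phenotypes, panel) {
  stopifnot(inherits(panel, "diallel_panel"))
  cr <- panel$crosses[!panel$crosses$homozygous, , drop = FALSE]
  out <- lapply(unique(phenotypes$condition), function(cc) {
    ph <- phenotypes[phenotypes$condition == cc, , drop = FALSE]
    med <- stats::setNames(ph$median_value, ph$individual_id)
    sdv <- stats::setNames(ph$replicate_sd, ph$individual_id)
    lk <- function(tbl, id, self) {
      ifelse(id %in% names(tbl), tbl[id],
             ifelse(self %in% names(tbl), tbl[self], NA_real_))
    }
    p1 <- lk(med, cr$parent1, cross_id(cr$parent1, cr$parent1))
    p2 <- lk(med, cr$parent2, cross_id(cr$parent2, cr$parent2))
    s1 <- lk(sdv, cr$parent1, cross_id(cr$parent1, cr$parent1))
    s2 <- lk(sdv, cr$parent2, cross_id(cr$parent2, cr$parent2))
    hy <- med[cr$hybrid_id]
    sh <- sdv[cr$hybrid_id]
    ok <- !(is.na(p1) | is.na(p2) | is.na(hy))
    cls <- classify_cross(p1[ok], p2[ok], s1[ok], s2[ok], hy[ok], sh[ok])
    cbind(cr[ok, c("parent1", "parent2", "hybrid_id")],
          condition = cc, cls, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Summarize inheritance-mode calls for one condition
#'
#' @param calls data.frame of calls (rows of [classify_inheritance()] for
#'   a single condition).
#' @return list with `n_calls`, `frac_separable`, `mode_fractions`
#'   (fractions of the seven modes among separable calls),
#'   `frac_overdominance` / `frac_underdominance` among all calls, and
#'   `predominant_mode` (modal class among separable calls; several if
#'   tied, `NA` if no call is separable).
#' @export
summarize_condition <- function(calls) {
  if (nrow(calls) < 1) stop("need at least one call")
  mode <- as.character(calls$mode)
  sep <- calls$separable
  seven <- INHERITANCE_MODES[1:7]
  mf <- if (any(sep)) {
    table(factor(mode[sep], levels = seven)) / sum(sep)
  } else {
    stats::setNames(rep(NA_real_, 7), seven)
  }
  pred <- if (any(sep)) {
    tb <- table(factor(mode[sep], levels = seven))
    names(tb)[tb == max(tb)]
  } else NA_character_
  list(n_calls = nrow(calls),
       frac_separable = mean(sep),
       mode_fractions = stats::setNames(as.numeric(mf), seven),
       frac_overdominance = mean(mode == "overdominance"),
       frac_underdominance = mean(mode == "underdominance"),
       predominant_mode = pred)
}

#' Per-condition inheritance summary table
#'
#' @param calls data.frame from [classify_inheritance()] (any number of
#'   conditions).
#' @return data.frame, one row per condition, with separable fraction,
#'   over/underdominance fractions and predominant mode (ties joined by
#'   `"/"`).
#' @export
summarize_inheritance <- function(calls) {
  out <- lapply(split(calls, calls$condition), function(cc) {
    s <- summarize_condition(cc)
    data.frame(condition = cc$condition[1], n_calls = s$n_calls,
               frac_separable = s$frac_separable,
               frac_overdominance = s$frac_overdominance,
               frac_underdominance = s$frac_underdominance,
               predominant_mode = paste(s$predominant_mode,
                                        collapse = "/"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
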
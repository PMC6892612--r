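#' Estimate general and specific combining abilities (Griffing)
#'
#' Decomposes half-diallel hybrid phenotypes as
#' `z_ij = mu + g_i + g_j + s_ij + e`: `mu` is the mean over the C(N,2)
#' heterozygous cross phenotypes, the general combining ability of parent
#' i is `g_i = (N-1)/(N-2) * (zbar_i - mu)` with `zbar_i` the mean over
#' the N-1 hybrids involving parent i, and the specific combining ability
#' is the residual `s_ij = z_ij - g_i - g_j - mu`. Homozygous (selfed)
#' hybrids are excluded from estimation; in a full-matrix panel the two
#' reciprocal hybrids of a pair are treated as replicate measurements of
#' the same unordered cross and averaged.
#'
#' @param phenotypes a phenotype table from [aggregate_replicates()]
#'   restricted to one condition (or carrying a single condition).
#' @param panel a `diallel_panel` defining the crosses.
#' @param condition condition to analyse; defaults to the only condition
#'   present.
#' @return object of class `combining_ability`: list with `condition`,
#'   `parents`, `n_parents`, `mu`, `gca` (named vector, sums to ~0),
#'   `sca` (symmetric parent x parent matrix, `NA` diagonal), `z`
#'   (observed cross phenotype matrix), `rep_var` and `rep_n` (per-cross
#'   replicate variance and count, for error-variance estimation).
#' @references Griffing, B. (1956) Concept of general and specific
#'   combining ability in relation to diallel crossing systems.
#' @export
estimate_combining_abilities <- function(phenotypes, panel,
                                         condition = NULL) {
  stopifnot(inherits(panel, "diallel_panel"))
  ph <- phenotypes
  if (is.null(condition)) {
    condition <- unique(ph$condition)
    if (length(condition) != 1) {
      stop("phenotypes carry several conditions; pass `condition`")
    }
  }
  ph <- ph[ph$condition == condition, , drop = FALSE]
  cr <- panel$crosses[!panel$crosses$homozygous, , drop = FALSE]
  parents <- sort(unique(c(panel$crosses$parent1, panel$crosses$parent2)))
  N <- length(parents)
  if (N < 4) stop("need at least 4 parents (estimator ill-conditioned)")
  med <- stats::setNames(ph$median_value, ph$individual_id)
  rv <- stats::setNames(ph$replicate_sd^2, ph$individual_id)
  rn <- stats::setNames(ph$n_replicates, ph$individual_id)
  z <- v <- matrix(NA_real_, N, N, dimnames = list(parents, parents))
  nrep <- matrix(NA_real_, N, N, dimnames = list(parents, parents))
  for (k in seq_len(nrow(cr))) {
    id <- cr$hybrid_id[k]
    if (!id %in% names(med) || is.na(med[id])) next
    i <- cr$parent1[k]; j <- cr$parent2[k]
    # reciprocals are replicate hybrids of the unordered cross: average
    z[i, j] <- z[j, i] <- mean(c(z[i, j], med[[id]]), na.rm = TRUE)
    v[i, j] <- v[j, i] <- mean(c(v[i, j], rv[[id]]), na.rm = TRUE)
    nrep[i, j] <- nrep[j, i] <- mean(c(nrep[i, j], rn[[id]]), na.rm = TRUE)
  }
  up <- upper.tri(z)
  if (anyNA(z[up])) {
    miss <- which(is.na(z) & up, arr.ind = TRUE)
    stop("missing phenotypes for cross(es): ",
         paste(cross_id(parents[miss[, 1]], parents[miss[, 2]]),
               collapse = ", "))
  }
  mu <- mean(z[up])
  zbar <- rowMeans(z, na.rm = TRUE)            # mean over the N-1 hybrids
  gca <- (N - 1) / (N - 2) * (zbar - mu)
  sca <- z - outer(gca, gca, `+`) - mu
  diag(sca) <- NA_real_
  structure(list(condition = condition, parents = parents, n_parents = N,
                 mu = mu, gca = gca, sca = sca, z = z,
                 rep_var = v, rep_n = nrep),
            class = "combining_ability")
}

#' @export
print.combining_ability <- function(x, ...) {
  cat("combining_ability [", x$condition, "]: N =", x$n_parents,
      " mu =", signif(x$mu, 4), "\n")
  if (!is.null(x$h2)) {
    cat("  h2 =", signif(x$h2, 3), " H2 =", signif(x$H2, 3), "\n")
  }
  invisible(x)
}

#' Error terms of the combining-ability estimates
#'
#' Sampling-error terms attached to the Griffing estimates, driven by the
#' replicate variance of each cross phenotype: for parent i,
#' `e_g_i = (N-1)/(N*(N-2)) * mean_j(var_ij / n_ij)`; for cross (i,j),
#' `e_s_ij = (N-3)/(N-1) * var_ij / n_ij`; and the error variance entering
#' the phenotypic-variance denominator is the mean sampling variance of a
#' cross phenotype, `sigma2_e = mean_ij(var_ij / n_ij)`.
#'
#' @param result a `combining_ability` from
#'   [estimate_combining_abilities()].
#' @return the `result` with elements `e_gca` (named per-parent vector),
#'   `e_sca` (symmetric matrix) and `sigma2_e` added.
#' @export
estimate_error_variances <- function(result) {
  stopifnot(inherits(result, "combining_ability"))
  N <- result$n_parents
  v <- result$rep_var
  n <- result$rep_n
  if (anyNA(v[upper.tri(v)]) || anyNA(n[upper.tri(n)])) {
    stop("replicate variances/counts unavailable for some crosses")
  }
  if (all(n[upper.tri(n)] <= 1)) {
    warning("single-replicate phenotypes: sigma2_e set to 0")
  }
  samp <- v / pmax(n, 1)                      # var of a cross phenotype
  result$e_gca <- (N - 1) / (N * (N - 2)) * rowMeans(samp, na.rm = TRUE)
  e_s <- (N - 3) / (N - 1) * samp
  diag(e_s) <- NA_real_
  result$e_sca <- e_s
  result$sigma2_e <- mean(samp[upper.tri(samp)])
  result
}

#' Broad- and narrow-sense heritability from combining abilities
#'
#' The additive variance is the variance over the C(N,2) crosses of
#' `g_i + g_j`; total genetic variance adds the SCA variance. Narrow-sense
#' heritability is `h2 = var_A / (var_A + var_SCA + sigma2_e)` and
#' broad-sense `H2 = (var_A + var_SCA) / (var_A + var_SCA + sigma2_e)`;
#' both are clipped to `[0, 1]`, so `h2 <= H2` always.
#'
#' @param result a `combining_ability` with error variances
#'   ([estimate_error_variances()]); if `sigma2_e` is absent it is
#'   computed first.
#' @return the `result` with `var_additive`, `var_sca`, `h2`, `H2` added
#'   (`NA` with a warning when total variance is zero).
#' @export
estimate_heritabilities <- function(result) {
  stopifnot(inherits(result, "combining_ability"))
  if (is.null(result$sigma2_e)) result <- estimate_error_variances(result)
  up <- upper.tri(result$sca)
  gsum <- outer(result$gca, result$gca, `+`)
  var_a <- stats::var(gsum[up])
  var_s <- stats::var(result$sca[up])
  tot <- var_a + var_s + result$sigma2_e
  result$var_additive <- var_a
  result$var_sca <- var_s
  if (tot <= 0) {
    warning("zero total variance: heritabilities undefined")
    result$h2 <- result$H2 <- NA_real_
  } else {
    result$h2 <- min(1, max(0, var_a / tot))
    result$H2 <- min(1, max(0, (var_a + var_s) / tot))
  }
  result
}

#' Expected hybrid phenotypes under the combining-ability model
#'
#' A heterozygous hybrid's expected phenotype is
#' `mu + g_i + g_j + s_ij` (identically its observed cross phenotype, so
#' the correlation over heterozygous crosses alone is 1 by construction);
#' a homozygous diagonal hybrid, excluded from estimation, is predicted as
#' `mu + 2 g_i`. When a phenotype table is supplied, observed diagonal
#' phenotypes are looked up under the selfed hybrid id (`PxP`) or, failing
#' that, the parent id, and the Pearson correlation is computed over the
#' union.
#'
#' @param result a `combining_ability`.
#' @param phenotypes optional phenotype table supplying observed diagonal
#'   phenotypes.
#' @param include_diagonal include `mu + 2 g_i` predictions?
#' @return list with `table` (parent1, parent2, expected, observed) and
#'   `pearson_r`.
#' @export
expected_phenotypes <- function(result, phenotypes = NULL,
                                include_diagonal = TRUE) {
  stopifnot(inherits(result, "combining_ability"))
  p <- result$parents
  cmb <- utils::combn(length(p), 2)
  gsum <- result$gca[cmb[1, ]] + result$gca[cmb[2, ]]
  exp_het <- result$mu + gsum + result$sca[cbind(cmb[1, ], cmb[2, ])]
  obs_het <- result$z[cbind(cmb[1, ], cmb[2, ])]
  tab <- data.frame(parent1 = p[cmb[1, ]], parent2 = p[cmb[2, ]],
                    expected = exp_het, observed = obs_het,
                    stringsAsFactors = FALSE)
  if (include_diagonal && !is.null(phenotypes)) {
    ph <- phenotypes[phenotypes$condition == result$condition, ,
                     drop = FALSE]
    med <- stats::setNames(ph$median_value, ph$individual_id)
    self_id <- cross_id(p, p)
    obs_d <- ifelse(self_id %in% names(med), med[self_id],
                    ifelse(p %in% names(med), med[p], NA_real_))
    tab <- rbind(tab, data.frame(
      parent1 = p, parent2 = p,
      expected = result$mu + 2 * result$gca,
      observed = as.numeric(obs_d), stringsAsFactors = FALSE))
  }
  ok <- !is.na(tab$observed)
  list(table = tab,
       pearson_r = if (sum(ok) >= 3)
         stats::cor(tab$expected[ok], tab$observed[ok]) else NA_real_)
}

#' Per-condition Griffing analysis of a diallel panel
#'
#' Runs [estimate_combining_abilities()], [estimate_error_variances()] and
#' [estimate_heritabilities()] for every condition in a phenotype table.
#'
#' @param phenotypes phenotype table ([aggregate_replicates()]).
#' @param panel a `diallel_panel`.
#' @return object of class `griffing_result`: list with `per_condition`
#'   (named list of `combining_ability` objects) and `summary`, one row
#'   per condition (`mu`, `var_additive`, `var_sca`, `sigma2_e`, `h2`,
#'   `H2`).
#' @export
griffing_analysis <- function(phenotypes, panel) {
  conds <- unique(phenotypes$condition)
  res <- lapply(conds, function(cc) {
    estimate_heritabilities(
      estimate_combining_abilities(phenotypes, panel, condition = cc))
  })
  names(res) <- conds
  summary <- do.call(rbind, lapply(res, function(r) {
    data.frame(condition = r$condition, mu = r$mu,
               var_additive = r$var_additive, var_sca = r$var_sca,
               sigma2_e = r$sigma2_e, h2 = r$h2, H2 = r$H2,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(per_condition = res, summary = summary),
            class = "griffing_result")
}

#' @export
print.griffing_result <- function(x, ...) {
  cat("griffing_result over", nrow(x$summary), "condition(s)\n")
  print(x$summary, digits = 3)
  invisible(x)
}
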
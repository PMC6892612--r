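#' Normalized growth ratios
#'
#' Fitness proxy per replicate: colony size on the assay condition divided
#' by the matched colony size on the control medium (SC). Pairs with a
#' missing or non-positive control size yield `NA` and are counted in a
#' message.
#'
#' @param condition_sizes,control_sizes numeric vectors of colony sizes,
#'   paired by individual and replicate.
#' @return numeric vector of growth ratios, `NA` where the control is
#'   unusable.
#' @export
compute_growth_ratios <- function(condition_sizes, control_sizes) {
  if (length(condition_sizes) != length(control_sizes)) {
    stop("condition and control size vectors must have equal length")
  }
  bad <- is.na(control_sizes) | control_sizes <= 0
  out <- ifelse(bad, NA_real_, condition_sizes / control_sizes)
  if (any(bad)) {
    message(sum(bad), " replicate(s) dropped: control size missing or <= 0")
  }
  out
}

#' Aggregate replicate growth ratios into per-individual phenotypes
#'
#' The phenotype of an individual in a condition is the median of its
#' replicate growth ratios, which smooths pinning defects and
#' contamination; the replicate standard deviation (n - 1 denominator) and
#' replicate count are kept alongside for error-variance estimation and
#' inheritance-mode classification.
#'
#' @param replicates data.frame with columns `individual_id`, `condition`,
#'   `replicate`, `value` (growth ratio; `NA` allowed).
#' @return a phenotype table: data.frame with one row per
#'   (individual_id, condition) and columns `median_value`,
#'   `replicate_sd`, `n_replicates`. Individuals whose replicates are all
#'   missing get an `NA` median (with a message).
#' @export
aggregate_replicates <- function(replicates) {
  need <- c("individual_id", "condition", "value")
  if (!all(need %in% names(replicates))) {
    stop("replicates needs columns: ", paste(need, collapse = ", "))
  }
  key <- interaction(replicates$individual_id, replicates$condition,
                     drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(replicates)), key)
  agg <- function(ii) {
    v <- replicates$value[ii]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(c(NA_real_, NA_real_, 0))
    c(stats::median(v),
      if (length(v) > 1) stats::sd(v) else 0,
      length(v))
  }
  m <- t(vapply(idx, agg, numeric(3)))
  first <- vapply(idx, `[`, 0L, 1L)
  out <- data.frame(
    individual_id = replicates$individual_id[first],
    condition = replicates$condition[first],
    median_value = m[, 1], replicate_sd = m[, 2],
    n_replicates = as.integer(m[, 3]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (anyNA(out$median_value)) {
    message(sum(is.na(out$median_value)),
            " individual/condition pair(s) with no usable replicate")
  }
  out
}

#' Rank-based inverse normal transform
#'
#' Maps a phenotype vector to standard-normal quantiles: the value of rank
#' r out of n becomes `qnorm((r - 0.5) / n)`. Ties receive the average
#' rank; missing values stay missing. Mixed models assume normally
#' distributed phenotypes, so association scans are run on this scale.
#'
#' @param x numeric vector (>= 2 non-missing values).
#' @return numeric vector of normal scores, mean ~0 and sd ~1.
#' @export
inverse_normal_transform <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 2) stop("need at least two non-missing values")
  if (stats::var(x[ok]) == 0) {
    warning("all values identical; transform maps everything to 0")
  }
  r <- rank(x, ties.method = "average", na.last = "keep")
  stats::qnorm((r - 0.5) / n)
}
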
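#' Encode hybrid genotypes for association testing
#'
#' Additive encoding counts copies of the minor allele (0/1/2); the minor
#' allele is defined within the hybrid panel, ties broken toward the
#' alternate allele. Overdominant encoding is the heterozygosity indicator
#' (0/1), contrasting heterozygotes against both homozygote classes.
#'
#' @param panel a `diallel_panel` with synthesized `hybrid_genotypes`
#'   ([synthesize_hybrid_genotypes()]), sites filtered/pruned beforehand.
#' @param encoding `"additive"` or `"overdominant"`.
#' @return object of class `encoded_genotypes`: list with `encoding`,
#'   `matrix` (hybrids x sites numeric codes), `dosage` (minor-allele
#'   dosage 0/1/2, kept for effect-size contrasts), `maf_panel` (allele
#'   frequency over the 2 x n_hybrids panel alleles), `maf_source`
#'   (source-population annotation, `NA` when absent), `sites`.
#' @export
encode_genotypes <- function(panel, encoding = c("additive",
                                                 "overdominant")) {
  stopifnot(inherits(panel, "diallel_panel"))
  encoding <- match.arg(encoding)
  H <- panel$hybrid_genotypes
  if (is.null(H)) stop("panel has no hybrid genotypes; synthesize first")
  if (anyNA(H)) stop("missing hybrid calls; re-run site filtering")
  alt_freq <- colMeans(H) / 2
  minor_is_alt <- alt_freq <= 0.5            # ties toward alt
  dosage <- H
  dosage[, !minor_is_alt] <- 2L - H[, !minor_is_alt, drop = FALSE]
  X <- if (encoding == "additive") dosage else (H == 1L) * 1L
  storage.mode(X) <- "double"
  sites <- panel$sites
  structure(list(
    encoding = encoding, matrix = X, dosage = dosage,
    maf_panel = pmin(alt_freq, 1 - alt_freq),
    maf_source = if ("maf_source" %in% names(sites))
      sites$maf_source else rep(NA_real_, ncol(H)),
    sites = sites), class = "encoded_genotypes")
}

#' Genomic kinship matrix from standardized dosages
#'
#' `K = Z Z' / m` over the `m` standardized (mean 0, unit variance)
#' dosage columns, excluding monomorphic sites and, for
#' leave-one-chromosome-out (LOCO) scans, all sites on
#' `exclude_chromosome` to avoid proximal contamination. `K` is rescaled
#' so its mean diagonal is 1.
#'
#' @param encoded an `encoded_genotypes` (additive encoding).
#' @param exclude_chromosome chromosome label to leave out, or `NULL`.
#' @return symmetric positive semidefinite kinship matrix.
#' @export
compute_kinship <- function(encoded, exclude_chromosome = NULL) {
  stopifnot(inherits(encoded, "encoded_genotypes"))
  X <- encoded$matrix
  keep <- rep(TRUE, ncol(X))
  if (!is.null(exclude_chromosome)) {
    keep <- keep & !(encoded$sites$chrom %in% exclude_chromosome)
  }
  keep <- keep & (apply(X, 2, stats::sd) > 0)
  if (!any(keep)) stop("no usable sites for kinship computation")
  Z <- scale(X[, keep, drop = FALSE])
  K <- tcrossprod(Z) / ncol(Z)
  K / mean(diag(K))
}

#' Leave-one-chromosome-out kinship matrices
#'
#' @param encoded an `encoded_genotypes`.
#' @return named list, one kinship per chromosome present (computed from
#'   all other chromosomes). With a single chromosome the full-genome
#'   kinship is returned for it, with a warning.
#' @export
loco_kinships <- function(encoded) {
  chroms <- unique(encoded$sites$chrom)
  if (length(chroms) == 1) {
    warning("single chromosome: LOCO impossible, using full kinship")
    return(stats::setNames(list(compute_kinship(encoded)), chroms))
  }
  stats::setNames(lapply(chroms, function(ch) {
    compute_kinship(encoded, exclude_chromosome = ch)
  }), chroms)
}

#' Precompute the mixed-model scan design
#'
#' Eigendecomposes each chromosome's LOCO kinship once and rotates the
#' genotype columns into the eigenbasis, so that repeated scans of the
#' same panel (permutations, many conditions) only pay for the phenotype
#' rotation and the per-chromosome variance-ratio fit.
#'
#' @param encoded an `encoded_genotypes`.
#' @param kinships named per-chromosome kinship list, a single matrix
#'   used for every chromosome, or `NULL` to compute LOCO kinships.
#' @return an `lmm_design` object accepted by [lmm_scan()] and
#'   [permutation_threshold()].
#' @export
lmm_design <- function(encoded, kinships = NULL) {
  chroms <- unique(encoded$sites$chrom)
  if (is.null(kinships)) kinships <- loco_kinships(encoded)
  if (is.matrix(kinships)) {
    kinships <- stats::setNames(rep(list(kinships), length(chroms)),
                                chroms)
  }
  n <- nrow(encoded$matrix)
  per_chrom <- lapply(chroms, function(ch) {
    K <- kinships[[ch]]
    if (is.null(K)) stop("no kinship supplied for chromosome ", ch)
    ee <- eigen(K, symmetric = TRUE)
    d <- pmax(ee$values, 0)
    idx <- which(encoded$sites$chrom == ch)
    Gr <- crossprod(ee$vectors, encoded$matrix[, idx, drop = FALSE])
    list(chrom = ch, U = ee$vectors, d = d, u1 = crossprod(ee$vectors,
                                                           rep(1, n)),
         site_idx = idx, Gr = Gr, Gr2 = Gr^2)
  })
  structure(list(per_chrom = per_chrom, n = n, encoded = encoded),
            class = "lmm_design")
}

# internal: ML fit of the variance ratio delta = sigma2_e / sigma2_g on
# the eigenvalue scale, intercept-only null model, rotated phenotype yr.
fit_delta <- function(yr, d, u1) {
  n <- length(yr)
  nll <- function(log10d) {
    w <- 1 / (d + 10^log10d)
    b0 <- sum(w * u1 * yr) / sum(w * u1^2)
    r <- yr - u1 * b0
    s2 <- sum(w * r^2) / n
    n * log(s2) - sum(log(w))
  }
  opt <- stats::optimize(nll, interval = c(-5, 6))
  # prefer the OLS boundary when it is as good (variance ratio -> Inf)
  if (nll(6) <= opt$objective + 1e-8) return(1e6)
  10^opt$minimum
}

# internal: scan a matrix of phenotype columns Y (n x P) over every site;
# returns list of P x S matrices `p` and `beta` (sites in design order).
scan_matrix <- function(design, Y) {
  Y <- as.matrix(Y)
  n <- design$n
  P <- ncol(Y)
  S <- ncol(design$encoded$matrix)
  pmat <- matrix(NA_real_, P, S)
  bmat <- matrix(NA_real_, P, S)
  # constant phenotype columns carry no signal: p = 1 everywhere
  flat <- apply(Y, 2, stats::var) == 0
  if (all(flat)) {
    pmat[] <- 1
    bmat[] <- 0
    return(list(p = pmat, beta = bmat))
  }
  Y[, flat] <- seq_len(n)  # placeholder, overwritten below
  for (pc in design$per_chrom) {
    Yr <- crossprod(pc$U, Y)
    u1 <- as.numeric(pc$u1)
    W <- matrix(0, n, P)
    for (p in seq_len(P)) {
      delta <- fit_delta(Yr[, p], pc$d, u1)
      W[, p] <- 1 / (pc$d + delta)
    }
    A11 <- colSums(W * u1^2)                       # P
    b1 <- colSums(W * u1 * Yr)                     # P
    yy <- colSums(W * Yr^2)                        # P
    A12 <- crossprod(pc$Gr, W * u1)                # S_c x P
    A22 <- crossprod(pc$Gr2, W)                    # S_c x P
    b2 <- crossprod(pc$Gr, W * Yr)                 # S_c x P
    det <- sweep(A22, 2, A11, `*`) - A12^2
    gvar <- sweep(det, 2, A11, `/`)                # weighted genotype var
    beta <- (sweep(b2, 2, A11, `*`) -
               sweep(A12, 2, b1, `*`)) / det
    beta1 <- (matrix(b1, nrow(A12), P, byrow = TRUE) - A12 * beta) /
      matrix(A11, nrow(A12), P, byrow = TRUE)
    rss <- matrix(yy, nrow(A12), P, byrow = TRUE) -
      beta1 * matrix(b1, nrow(A12), P, byrow = TRUE) - beta * b2
    rss <- pmax(rss, 0)
    se2 <- rss / (n - 2) * matrix(A11, nrow(A12), P, byrow = TRUE) / det
    tstat <- beta / sqrt(se2)
    pv <- 2 * stats::pt(-abs(tstat), df = n - 2)
    degen <- gvar <= 1e-10 | !is.finite(pv)
    pv[degen] <- 1
    beta[degen] <- 0
    pmat[, pc$site_idx] <- t(pv)
    bmat[, pc$site_idx] <- t(beta)
  }
  pmat[flat, ] <- 1
  bmat[flat, ] <- 0
  list(p = pmat, beta = bmat)
}

#' Mixed-model association scan
#'
#' Single-random-effect linear mixed model `y = mu + g*beta + u + eps`,
#' `u ~ N(0, sigma2_g K)`, fitted per chromosome on the eigendecomposition
#' of that chromosome's LOCO kinship. The variance ratio
#' `delta = sigma2_e / sigma2_g` is estimated once per chromosome by
#' maximum likelihood under the null (intercept-only) model and reused for
#' every site on the chromosome; each site's effect is then the
#' generalized-least-squares slope, tested two-sided with `n - 2` degrees
#' of freedom. When `K` is the identity (or the fitted ratio is
#' effectively infinite) the scan reduces exactly to ordinary
#' least-squares regression.
#'
#' @param y numeric phenotype vector, inverse-normal transformed, aligned
#'   with the hybrids (rows) of `encoded`; must be finite.
#' @param encoded an `encoded_genotypes`.
#' @param kinships named per-chromosome kinship list
#'   ([loco_kinships()]), a single matrix to use for every chromosome, or
#'   `NULL` to compute LOCO kinships from `encoded`.
#' @param design optionally a precomputed internal design (as built once
#'   by [permutation_threshold()]); overrides `kinships`.
#' @return data.frame with one row per site: `site_id`, `chrom`, `pos`,
#'   `beta`, `p_value`. Monomorphic sites get `beta = 0`, `p_value = 1`.
#' @export
lmm_scan <- function(y, encoded, kinships = NULL, design = NULL) {
  if (is.null(design)) design <- lmm_design(encoded, kinships)
  if (any(!is.finite(y))) stop("phenotype must be finite")
  if (length(y) != design$n) stop("phenotype length mismatch")
  sc <- scan_matrix(design, matrix(y, ncol = 1))
  data.frame(site_id = design$encoded$sites$site_id,
             chrom = design$encoded$sites$chrom,
             pos = design$encoded$sites$pos,
             beta = sc$beta[1, ], p_value = sc$p[1, ],
             stringsAsFactors = FALSE)
}

#' Permutation-based family-wise significance threshold
#'
#' Shuffles the phenotype across individuals `n_perm` times, reruns the
#' full genome scan for each shuffle, records the genome-wide minimum
#' p-value, and takes the `ceiling(alpha * n_perm)`-th smallest of these
#' minima (the 5th of 100 at `alpha = 0.05`) as the condition's
#' significance threshold; variants passing it have a family-wise error
#' rate of about `alpha`. A pooled alternative (`method = "pooled"`) takes
#' the `alpha` quantile of all permutation p-values instead.
#'
#' @param y phenotype vector (inverse-normal transformed).
#' @param encoded an `encoded_genotypes`.
#' @param kinships as in [lmm_scan()].
#' @param n_perm number of permutations (>= 20).
#' @param alpha family-wise error rate; `alpha * n_perm` must be >= 1.
#' @param seed integer seed for the shuffles.
#' @param method `"minp"` (default) or `"pooled"`.
#' @param design optional precomputed design (shared with [lmm_scan()]).
#' @return list with `threshold_p` and `minima` (the per-permutation
#'   genome-wide minimum p-values).
#' @export
permutation_threshold <- function(y, encoded, kinships = NULL,
                                  n_perm = 100, alpha = 0.05, seed = 1,
                                  method = c("minp", "pooled"),
                                  design = NULL) {
  method <- match.arg(method)
  if (n_perm < 20) stop("n_perm must be >= 20")
  if (alpha * n_perm < 1) stop("alpha * n_perm must be >= 1")
  if (is.null(design)) design <- lmm_design(encoded, kinships)
  set.seed(seed)
  n <- length(y)
  Y <- vapply(seq_len(n_perm), function(i) y[sample.int(n)],
              numeric(n))
  sc <- scan_matrix(design, Y)
  minima <- apply(sc$p, 1, min)
  threshold <- if (method == "minp") {
    sort(minima)[ceiling(alpha * n_perm)]
  } else {
    as.numeric(stats::quantile(sc$p, alpha, names = FALSE))
  }
  list(threshold_p = threshold, minima = minima)
}

#' Cohen's d effect size for a variant
#'
#' Standardized mean difference with pooled standard deviation
#' `sqrt((sd1^2 + sd2^2) / 2)`. Under the additive encoding the contrast
#' is heterozygotes versus major-allele homozygotes (the larger, more
#' powerful homozygote class); under the overdominant encoding it is
#' heterozygotes versus all homozygotes.
#'
#' @param y phenotype vector.
#' @param dosage minor-allele dosage vector (0/1/2) for the site.
#' @param encoding `"additive"` or `"overdominant"`.
#' @return Cohen's d (sign retained), or `NA` if either contrast group
#'   has fewer than 2 members.
#' @export
effect_size <- function(y, dosage, encoding = c("additive",
                                                "overdominant")) {
  encoding <- match.arg(encoding)
  g1 <- y[dosage == 1]
  g2 <- if (encoding == "additive") y[dosage == 0] else y[dosage != 1]
  if (length(g1) < 2 || length(g2) < 2) return(NA_real_)
  pooled <- sqrt((stats::sd(g1)^2 + stats::sd(g2)^2) / 2)
  if (pooled == 0) return(NA_real_)
  (mean(g1) - mean(g2)) / pooled
}

#' Variance explained by a single variant
#'
#' Squared Pearson correlation between the encoded genotype column and the
#' (transformed) phenotype.
#'
#' @param y phenotype vector.
#' @param code encoded genotype vector for the site.
#' @return proportion in `[0, 1]`; 0 (with attribute `zero_variance`)
#'   when the genotype column is constant.
#' @export
variance_explained <- function(y, code) {
  if (stats::var(code) == 0) {
    return(structure(0, zero_variance = TRUE))
  }
  stats::cor(code, y)^2
}

#' Genome-wide association on a diallel panel
#'
#' Per condition and encoding: inverse-normal transform of the hybrid
#' phenotypes, LMM scan with LOCO kinship, permutation threshold,
#' per-site variance explained and Cohen's d, and panel/source MAF
#' annotations. Kinship is always computed from the additive dosages.
#'
#' @param phenotypes phenotype table covering every hybrid of `panel`.
#' @param panel a `diallel_panel` with hybrid genotypes.
#' @param encodings subset of `c("additive", "overdominant")`.
#' @param conditions conditions to scan (default: all in `phenotypes`).
#' @param n_perm,alpha permutation-threshold parameters.
#' @param seed integer; per-(condition, encoding) permutation seeds are
#'   derived from it.
#' @return data.frame of class `association_result`, one row per
#'   site x condition x encoding: `beta`, `p_value`,
#'   `variance_explained`, `cohens_d`, `maf_panel`, `maf_source`,
#'   `threshold_p`, `significant`.
#' @export
run_gwas <- function(phenotypes, panel,
                     encodings = c("additive", "overdominant"),
                     conditions = NULL, n_perm = 100, alpha = 0.05,
                     seed = 1) {
  stopifnot(inherits(panel, "diallel_panel"))
  encodings <- match.arg(encodings, several.ok = TRUE)
  if (is.null(conditions)) conditions <- unique(phenotypes$condition)
  enc_add <- encode_genotypes(panel, "additive")
  kin <- loco_kinships(enc_add)
  ids <- rownames(panel$hybrid_genotypes)
  out <- list()
  task <- 0L
  for (enc_name in encodings) {
    enc <- if (enc_name == "additive") enc_add else
      encode_genotypes(panel, "overdominant")
    design <- lmm_design(enc, kin)
    for (cc in conditions) {
      task <- task + 1L
      ph <- phenotypes[phenotypes$condition == cc, , drop = FALSE]
      med <- stats::setNames(ph$median_value, ph$individual_id)
      if (!all(ids %in% names(med))) {
        stop("phenotypes missing for hybrids: ",
             paste(utils::head(setdiff(ids, names(med)), 5),
                   collapse = ", "))
      }
      y <- inverse_normal_transform(as.numeric(med[ids]))
      scan <- lmm_scan(y, enc, design = design)
      thr <- permutation_threshold(y, enc, n_perm = n_perm,
                                   alpha = alpha,
                                   seed = seed + 977L * task,
                                   design = design)
      ve <- apply(enc$matrix, 2, function(g) {
        as.numeric(variance_explained(y, g))
      })
      cd <- vapply(seq_len(ncol(enc$dosage)), function(s) {
        effect_size(y, enc$dosage[, s], enc_name)
      }, 0)
      scan$condition <- cc
      scan$encoding <- enc_name
      scan$variance_explained <- ve
      scan$cohens_d <- cd
      scan$maf_panel <- enc$maf_panel
      scan$maf_source <- enc$maf_source
      scan$threshold_p <- thr$threshold_p
      scan$significant <- scan$p_value <= thr$threshold_p
      out[[length(out) + 1L]] <- scan
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("association_result", "data.frame")
  res
}

#' Low-frequency-variant enrichment among significant associations
#'
#' Classifies significant sites by their source-population MAF into
#' common (>= `low`), low-frequency (< `low`) and rare (< `rare`, a
#' subset of low-frequency), and compares the variance explained and
#' |Cohen's d| of low-frequency versus common significant sites with
#' two-sided Mann-Whitney-Wilcoxon tests.
#'
#' @param results an `association_result` (or compatible data.frame).
#' @param thresholds named vector with elements `low` and `rare`.
#' @return list with `n_significant`, per-class counts and proportions,
#'   the two rank-sum test results, and `maf_table`
#'   (site, panel and source MAF, significance) for panel-vs-source
#'   scatter plots. Empty summary (with a message) when nothing is
#'   significant.
#' @export
maf_enrichment <- function(results, thresholds = c(low = 0.05,
                                                   rare = 0.01)) {
  if (!all(c("low", "rare") %in% names(thresholds))) {
    stop("thresholds needs elements 'low' and 'rare'")
  }
  maf_table <- unique(results[, c("site_id", "maf_panel", "maf_source",
                                  "significant")])
  sig <- results[results$significant & !is.na(results$maf_source), ,
                 drop = FALSE]
  if (nrow(sig) == 0) {
    message("no significant sites: empty enrichment summary")
    return(list(n_significant = 0L, maf_table = maf_table))
  }
  low <- sig$maf_source < thresholds[["low"]]
  rare <- sig$maf_source < thresholds[["rare"]]
  test_or_na <- function(a, b) {
    if (length(a) >= 2 && length(b) >= 2) {
      stats::wilcox.test(a, b, exact = FALSE)
    } else NULL
  }
  list(
    n_significant = nrow(sig),
    n_low_frequency = sum(low), prop_low_frequency = mean(low),
    n_rare = sum(rare),
    prop_rare_among_low = if (any(low)) sum(rare) / sum(low) else NA_real_,
    n_common = sum(!low),
    ve_test = test_or_na(sig$variance_explained[low],
                         sig$variance_explained[!low]),
    d_test = test_or_na(abs(sig$cohens_d[low]), abs(sig$cohens_d[!low])),
    median_ve_low = stats::median(sig$variance_explained[low]),
    median_ve_common = stats::median(sig$variance_explained[!low]),
    mean_absd_low = mean(abs(sig$cohens_d[low]), na.rm = TRUE),
    mean_absd_common = mean(abs(sig$cohens_d[!low]), na.rm = TRUE),
    max_panel_maf_of_low = if (any(low)) max(sig$maf_panel[low])
      else NA_real_,
    maf_table = maf_table)
}
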
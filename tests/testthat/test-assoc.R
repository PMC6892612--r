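test_that("genotype encodings follow the minor-allele conventions", {
  # founders: 1 alt carrier of 4 at site 1; 3 alt carriers at site 2
  g <- matrix(c(2L, 0L, 0L, 0L,
                2L, 2L, 2L, 0L), nrow = 4)
  p <- founder_panel(g,
                     data.frame(chrom = "chr01", pos = c(10L, 20L),
                                ref = "A", alt = "G"),
                     c("W", "X", "Y", "Z"))
  dp <- synthesize_hybrid_genotypes(
    p, enumerate_half_diallel(p$parent_ids, include_diagonal = TRUE))
  add <- encode_genotypes(dp, "additive")
  od <- encode_genotypes(dp, "overdominant")
  # site 1: alt is minor -> additive code = alt dosage
  expect_equal(unname(add$matrix[, 1]),
               unname(dp$hybrid_genotypes[, 1] * 1))
  # site 2: alt freq 0.75 in founders -> minor is ref, codes flipped
  expect_equal(unname(add$matrix[, 2]),
               unname(2 - dp$hybrid_genotypes[, 2]))
  expect_true(all(od$matrix %in% c(0, 1)))
  expect_equal(unname(od$matrix[, 1]),
               unname((dp$hybrid_genotypes[, 1] == 1L) * 1))
  # het hybrid: additive 1 / od 1; hom-minor: additive 2 / od 0
  het <- which(dp$hybrid_genotypes[, 1] == 1L)[1]
  expect_equal(add$matrix[het, 1], 1)
  expect_equal(od$matrix[het, 1], 1)
  # panel MAF within [0, 0.5] and equal to the founder frequency
  # (site 1: one hom-alt carrier of 4 founders -> 2/8 alleles)
  expect_true(all(add$maf_panel >= 0 & add$maf_panel <= 0.5))
  expect_equal(unname(add$maf_panel), c(1 / 4, 1 / 4))
})

test_that("kinship matches hand linear algebra and is normalized", {
  X <- matrix(c(0, 1, 2,
                2, 0, 0), nrow = 3)
  enc <- encode_matrix(X)
  K <- compute_kinship(enc)
  Z <- scale(X)
  K_hand <- Z %*% t(Z) / 2
  K_hand <- K_hand / mean(diag(K_hand))
  expect_equal(unname(K), unname(K_hand))
  expect_equal(mean(diag(K)), 1)
  expect_true(isSymmetric(K))
  expect_true(all(eigen(K, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
  # identical individuals have off-diagonal equal to diagonal
  X2 <- rbind(X, X[1, ])
  K2 <- compute_kinship(encode_matrix(X2))
  expect_equal(K2[1, 4], K2[1, 1])
  expect_equal(K2[4, 4], K2[1, 1])
  # excluding the only chromosome is an error
  expect_error(compute_kinship(enc, exclude_chromosome = "chr01"),
               "no usable sites")
})

test_that("LMM with identity kinship reproduces OLS exactly", {
  enc <- encode_matrix(matrix(c(0, 0, 1, 1, 2, 2), ncol = 1))
  sc <- lmm_scan(c(0, 1, 1, 2, 2, 3), enc, kinships = diag(6))
  expect_equal(sc$beta, 1.0)
  expect_equal(sc$p_value, 0.03090583, tolerance = 1e-6)
  # F statistic on (1, 4) df implied by the p-value
  expect_equal(qf(1 - sc$p_value, 1, 4), 10.667, tolerance = 1e-3)
  set.seed(51)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    X <- matrix(sample(0:2, 3 * n, TRUE), ncol = 3)
    y <- rnorm(n)
    sc <- lmm_scan(y, encode_matrix(X), kinships = diag(n))
    for (s in 1:3) {
      fit <- summary(lm(y ~ X[, s]))$coefficients
      expect_equal(sc$beta[s], fit[2, 1], tolerance = 1e-8)
      expect_equal(sc$p_value[s], fit[2, 4], tolerance = 1e-8)
    }
  }
  # monomorphic site: p = 1, beta = 0
  Xm <- cbind(c(0, 0, 1, 1, 2, 2), 1)
  scm <- lmm_scan(rnorm(6), encode_matrix(Xm), kinships = diag(6))
  expect_equal(scm$p_value[2], 1)
  expect_equal(scm$beta[2], 0)
  expect_error(lmm_scan(c(1, NA, 1, 1, 1, 2), encode_matrix(Xm),
                        kinships = diag(6)), "finite")
})

test_that("polygenic confounding is absorbed by the kinship term", {
  # phenotype = pure polygenic signal along K's leading eigenvector;
  # the mixed model should drastically deflate single-site significance
  set.seed(52)
  p <- simulate_founders(12, 400, spectrum = uniform_maf_spectrum(),
                         seed = 52)
  dp <- synthesize_hybrid_genotypes(
    p, enumerate_half_diallel(p$parent_ids, include_diagonal = TRUE))
  enc <- encode_genotypes(dp, "additive")
  K <- compute_kinship(enc)
  ev <- eigen(K, symmetric = TRUE)
  y <- ev$vectors[, 1] * sqrt(ev$values[1]) + rnorm(nrow(K), 0, 0.05)
  y <- inverse_normal_transform(y)
  p_lmm <- lmm_scan(y, enc)$p_value
  p_ols <- lmm_scan(y, enc, kinships = diag(length(y)))$p_value
  expect_gt(median(log10(p_lmm)) - median(log10(p_ols)), 0.5)
})

test_that("permutation threshold is the stated order statistic", {
  set.seed(53)
  p <- simulate_founders(8, 60, seed = 53)
  dp <- synthesize_hybrid_genotypes(
    p, enumerate_half_diallel(p$parent_ids, include_diagonal = TRUE))
  enc <- encode_genotypes(dp, "additive")
  y <- inverse_normal_transform(rnorm(nrow(enc$matrix)))
  thr <- permutation_threshold(y, enc, n_perm = 100, alpha = 0.05,
                               seed = 7)
  expect_length(thr$minima, 100)
  expect_equal(thr$threshold_p, sort(thr$minima)[5])
  # seed determinism
  thr2 <- permutation_threshold(y, enc, n_perm = 100, alpha = 0.05,
                                seed = 7)
  expect_identical(thr$minima, thr2$minima)
  # degenerate constant phenotype: all p = 1, threshold 1
  thr3 <- permutation_threshold(rep(0.5, length(y)), enc, n_perm = 20,
                                alpha = 0.05, seed = 1)
  expect_equal(thr3$threshold_p, 1)
  expect_error(permutation_threshold(y, enc, n_perm = 10), "n_perm")
  expect_error(permutation_threshold(y, enc, n_perm = 20,
                                     alpha = 0.01), "alpha")
})

test_that("a planted causal site tops the scan in most replicates", {
  set.seed(54)
  p <- simulate_founders(20, 300, spectrum = uniform_maf_spectrum(),
                         seed = 54)
  dp <- synthesize_hybrid_genotypes(
    p, enumerate_half_diallel(p$parent_ids, include_diagonal = TRUE))
  enc <- encode_genotypes(dp, "additive")
  design <- lmm_design(enc)
  causal <- which.min(abs(enc$maf_panel - 0.4))[1]
  hits <- 0
  for (i in 1:20) {
    y <- scale(enc$matrix[, causal]) + rnorm(nrow(enc$matrix))
    y <- inverse_normal_transform(as.numeric(y))
    sc <- lmm_scan(y, enc, design = design)
    if (which.min(sc$p_value) == causal) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("Cohen's d uses the pooled-sd contrasts of each encoding", {
  two_point <- function(m, s) m + c(-1, 1) * s / sqrt(2)
  # het 1.2 (sd .2) vs hom-major 1.0 (sd .2) -> d = 1
  y <- c(two_point(1.2, 0.2), two_point(1.0, 0.2), two_point(0.8, 0.2))
  dos <- c(1, 1, 0, 0, 2, 2)
  expect_equal(effect_size(y, dos, "additive"), 1.0)
  # means 2.0 vs 1.5, sds 0.3 / 0.4 -> pooled 0.35355, d = 1.4142
  y2 <- c(two_point(2.0, 0.3), two_point(1.5, 0.4))
  expect_equal(effect_size(y2, c(1, 1, 0, 0), "additive"), 0.5 / 0.35355,
               tolerance = 1e-4)
  # overdominant: het equal to pooled homozygotes -> d = 0
  y3 <- c(two_point(1.0, 0.1), two_point(0.9, 0.1), two_point(1.1, 0.1))
  expect_equal(effect_size(y3, c(1, 1, 0, 0, 2, 2), "overdominant"), 0)
  # singleton group -> NA
  expect_true(is.na(effect_size(c(1, 2, 3), c(1, 0, 0), "additive")))
})

test_that("variance explained is the squared genotype correlation", {
  g <- c(0, 0, 1, 1, 2, 2)
  expect_equal(variance_explained(2 * g + 3, g), 1)
  expect_equal(as.numeric(variance_explained(rep(1, 6), rep(2, 6))), 0)
  expect_true(attr(variance_explained(rnorm(6), rep(1, 6)),
                   "zero_variance"))
  # exact r = 0.45 construction
  set.seed(55)
  x <- rnorm(50)
  e <- residuals(lm(rnorm(50) ~ x))
  y <- 0.45 * scale(x)[, 1] + sqrt(1 - 0.45^2) * scale(e)[, 1]
  expect_equal(variance_explained(y, x), 0.2025, tolerance = 1e-6)
  # independent genotype: near-zero on average
  ve <- replicate(100, variance_explained(rnorm(595),
                                          sample(0:2, 595, TRUE)))
  expect_lt(mean(ve), 0.02)
})

test_that("p-values are uniform under a fully null trait", {
  p <- simulate_founders(20, 10000, spectrum = uniform_maf_spectrum(),
                         seed = 56)
  dp <- synthesize_hybrid_genotypes(
    p, enumerate_half_diallel(p$parent_ids, include_diagonal = TRUE))
  enc <- encode_genotypes(dp, "additive")
  set.seed(56)
  y <- inverse_normal_transform(rnorm(nrow(enc$matrix)))
  pv <- lmm_scan(y, enc)$p_value
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("MAF enrichment counts classes and compares effect sizes", {
  mk <- function(n, maf_source, sig = TRUE, ve = 0.2, d = 0.25) {
    data.frame(site_id = sprintf("s%04d", seq_len(n) +
                                   round(1e3 * maf_source[1])),
               maf_panel = pmax(maf_source, 1 / 34),
               maf_source = maf_source, significant = sig,
               variance_explained = ve, cohens_d = d)
  }
  res <- rbind(mk(84, runif(84, 0.05, 0.5)),
               mk(16, runif(16, 0.001, 0.049)))
  enr <- maf_enrichment(res)
  expect_equal(enr$n_significant, 100)
  expect_equal(enr$prop_low_frequency, 0.16)
  expect_equal(enr$n_low_frequency, 16)
  # all common: low/rare classes empty
  enr2 <- maf_enrichment(mk(30, runif(30, 0.1, 0.5)))
  expect_equal(enr2$n_low_frequency, 0)
  expect_equal(enr2$n_rare, 0)
  # nothing significant: empty summary with a note
  expect_message(
    enr3 <- maf_enrichment(mk(10, runif(10, 0.1, 0.5), sig = FALSE)),
    "no significant")
  expect_equal(enr3$n_significant, 0L)
})

test_that("run_gwas assembles aligned per-site results", {
  p <- simulate_founders(8, 150, seed = 57)
  dp <- synthesize_hybrid_genotypes(
    p, enumerate_half_diallel(p$parent_ids, include_diagonal = TRUE))
  m <- simulate_trait_model(p, 5, additive_sd = 0.3, env_sd = 0.05,
                            seed = 57)
  tb <- simulate_colony_data(p, dp, m, condition = "c1", seed = 58)
  ph <- aggregate_replicates(tb)
  res <- run_gwas(ph, dp, n_perm = 20, seed = 5)
  expect_s3_class(res, "association_result")
  expect_equal(nrow(res), 2 * n_sites(p))
  expect_setequal(unique(res$encoding), c("additive", "overdominant"))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_true(all(res$variance_explained >= 0 &
                    res$variance_explained <= 1))
  expect_identical(res$significant, res$p_value <= res$threshold_p)
})
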
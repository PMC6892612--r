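test_that("band arithmetic matches the worked examples", {
  # P1=0.5, P2=1.0, all sds 0.05: additivity band is [0.65, 0.85)
  r <- classify_cross(0.5, 1.0, 0.05, 0.05, 0.75, 0.05)
  expect_equal(as.character(r$mode), "additivity")
  expect_true(r$separable)
  expect_equal(r$mpv, 0.75)
  expect_equal(as.character(
    classify_cross(0.5, 1.0, 0.05, 0.05, 1.12, 0.05)$mode),
    "overdominance")
  # inseparable parents: middle is unclassified, extremes still called
  r3 <- classify_cross(0.9, 1.0, 0.1, 0.1, 0.95, 0.0)
  expect_false(r3$separable)
  expect_equal(as.character(r3$mode), "unclassified")
  expect_equal(as.character(
    classify_cross(0.9, 1.0, 0.1, 0.1, 0.5, 0.1)$mode),
    "underdominance")
  expect_equal(as.character(
    classify_cross(0.9, 1.0, 0.1, 0.1, 1.4, 0.1)$mode),
    "overdominance")
  expect_error(classify_cross(1, 2, -0.1, 0.1, 1.5, 0.1), "non-negative")
})

test_that("band boundaries are lower-inclusive, upper-exclusive", {
  # dominance_P2 band for P1=0, P2=1, sds 0.05, sHyb=0: [0.95, 1.05)
  expect_equal(as.character(
    classify_cross(0, 1, 0.05, 0.05, 0.95, 0)$mode), "dominance_P2")
  expect_equal(as.character(
    classify_cross(0, 1, 0.05, 0.05, 1.05, 0)$mode), "overdominance")
})

test_that("the seven bands tile the axis: exactly one mode per input", {
  set.seed(41)
  for (i in 1:10000) {
    # sds small enough that every band is non-empty (disjoint tiling)
    P1 <- runif(1, 0, 1); P2 <- P1 + runif(1, 0.31, 2)
    s1 <- runif(1, 0, 0.04); s2 <- runif(1, 0, 0.04)
    sh <- runif(1, 0, 0.04)
    hyb <- runif(1, P1 - 1, P2 + 1)
    r <- classify_cross(P1, P2, s1, s2, hyb, sh)
    expect_true(r$separable)
    b <- band_bounds(P1, P2, s1, s2, sh)
    member <- c(hyb < b[1],
                hyb >= b[1] & hyb < b[2], hyb >= b[2] & hyb < b[3],
                hyb >= b[3] & hyb < b[4], hyb >= b[4] & hyb < b[5],
                hyb >= b[5] & hyb < b[6], hyb >= b[6])
    expect_equal(sum(member), 1)
    expect_equal(which(member),
                 match(as.character(r$mode), levels(r$mode)))
  }
})

test_that("classification is symmetric under parent relabelling and
          reflection", {
  set.seed(42)
  mirror <- c(underdominance = "overdominance",
              dominance_P1 = "dominance_P2",
              partial_dominance_P1 = "partial_dominance_P2",
              additivity = "additivity",
              partial_dominance_P2 = "partial_dominance_P1",
              dominance_P2 = "dominance_P1",
              overdominance = "underdominance",
              unclassified = "unclassified")
  for (i in 1:500) {
    P1 <- runif(1); P2 <- P1 + runif(1, 0, 1)
    s1 <- runif(1, 0, 0.2); s2 <- runif(1, 0, 0.2)
    sh <- runif(1, 0, 0.2)
    hyb <- runif(1, P1 - 0.5, P2 + 0.5)
    a <- classify_cross(P1, P2, s1, s2, hyb, sh)
    # swapping the argument order relabels internally: identical call
    b <- classify_cross(P2, P1, s2, s1, hyb, sh)
    expect_identical(a$mode, b$mode)
    # reflecting the phenotype axis mirrors P1-modes onto P2-modes
    # (checked away from band boundaries and for non-degenerate bands,
    # where the first-match tie-break for empty bands cannot bite)
    c_ <- classify_cross(-P2, -P1, s2, s1, -hyb, sh)
    bands <- band_bounds(P1, P2, s1, s2, sh)
    off_boundary <- min(abs(c(-hyb - band_bounds(-P2, -P1, s2, s1, sh),
                              hyb - bands))) > 1e-9
    if (off_boundary && (!a$separable || all(diff(bands) > 0))) {
      expect_equal(as.character(c_$mode),
                   unname(mirror[as.character(a$mode)]))
    }
  }
})

test_that("increasing the hybrid phenotype never moves the call leftward", {
  set.seed(43)
  for (i in 1:200) {
    P1 <- runif(1); P2 <- P1 + runif(1, 0.1, 1.5)
    s1 <- runif(1, 0, 0.3); s2 <- runif(1, 0, 0.3)
    sh <- runif(1, 0, 0.3)
    hybs <- sort(runif(25, P1 - 1, P2 + 1))
    r <- classify_cross(P1, P2, s1, s2, hybs, sh)
    # position of each call along the phenotype axis
    axis_pos <- c(underdominance = 1, dominance_P1 = 2,
                  partial_dominance_P1 = 3, additivity = 4,
                  partial_dominance_P2 = 5, dominance_P2 = 6,
                  overdominance = 7, unclassified = 4)
    expect_true(all(diff(axis_pos[as.character(r$mode)]) >= 0))
  }
})

test_that("panel-level classification and summaries count correctly", {
  # deterministic toy: 4 parents, phenotypes chosen to hit known bands
  pan <- four_parent_panel()
  ph <- rbind(
    data.frame(individual_id = c("A", "B", "C", "D"), condition = "c1",
               median_value = c(0.2, 0.5, 0.8, 1.1), replicate_sd = 0.01,
               n_replicates = 54),
    data.frame(individual_id = c("AxB", "AxC", "AxD", "BxC", "BxD",
                                 "CxD"),
               condition = "c1",
               median_value = c(0.35, 0.5, 0.65, 0.65, 0.8, 0.95),
               replicate_sd = 0.01, n_replicates = 6))
  calls <- classify_inheritance(ph, pan)
  expect_equal(nrow(calls), 6)
  expect_true(all(calls$separable))
  expect_equal(as.character(calls$mode[calls$hybrid_id == "AxB"]),
               "additivity")
  s <- summarize_condition(calls)
  expect_equal(s$n_calls, 6)
  expect_equal(sum(s$mode_fractions), 1)
  tab <- summarize_inheritance(calls)
  expect_equal(nrow(tab), 1)
})

test_that("condition summaries handle ties and empty separable sets", {
  mk <- function(modes, sep) {
    data.frame(parent1 = "A", parent2 = "B", hybrid_id = "AxB",
               condition = "c1",
               mode = factor(modes,
                             levels = levels(classify_cross(0, 1, 0, 0,
                                                            0.5, 0)$mode)),
               separable = sep, mpv = 0.5)
  }
  calls <- mk(c(rep("dominance_P2", 5), rep("additivity", 3),
                rep("overdominance", 2)),
              c(rep(TRUE, 8), FALSE, FALSE))
  s <- summarize_condition(calls)
  expect_equal(s$predominant_mode, "dominance_P2")
  expect_equal(s$frac_overdominance, 0.2)
  # all additivity
  s2 <- summarize_condition(mk(rep("additivity", 10), TRUE))
  expect_equal(s2$predominant_mode, "additivity")
  expect_equal(unname(s2$mode_fractions["additivity"]), 1)
  # nothing separable: no predominant mode, extreme fractions reported
  s3 <- summarize_condition(mk(c("overdominance", "unclassified"),
                               FALSE))
  expect_true(is.na(s3$predominant_mode))
  expect_equal(s3$frac_overdominance, 0.5)
})
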
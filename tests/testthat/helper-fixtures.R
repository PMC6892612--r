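# Shared fixtures, all built in code.

# 3 founders x 5 clean biallelic sites, hand-coded alt dosages
toy_founder_panel <- function() {
  g <- matrix(c(0L, 2L, 0L, 2L, 0L,
                2L, 0L, 0L, 2L, 2L,
                0L, 0L, 2L, 0L, 2L), nrow = 3, byrow = TRUE)
  sites <- data.frame(chrom = c("chr01", "chr01", "chr01", "chr02",
                                "chr02"),
                      pos = c(100L, 500L, 900L, 200L, 700L),
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  founder_panel(g, sites, c("A", "B", "C"))
}

# the additive 4-parent worked half diallel
griffing_phenotypes <- function(z = c(10, 12, 14, 16, 18, 20),
                                rep_sd = 0, n_rep = 6L) {
  data.frame(
    individual_id = c("AxB", "AxC", "AxD", "BxC", "BxD", "CxD"),
    condition = "c1", median_value = z, replicate_sd = rep_sd,
    n_replicates = n_rep, stringsAsFactors = FALSE)
}

four_parent_panel <- function() enumerate_half_diallel(c("A", "B", "C",
                                                         "D"))

# wrap a bare dosage matrix as encoded genotypes (for LMM unit tests)
encode_matrix <- function(X, chrom = "chr01") {
  X <- as.matrix(X)
  chrom <- rep_len(chrom, ncol(X))
  f <- colMeans(X) / 2
  structure(list(
    encoding = "additive", matrix = X, dosage = X,
    maf_panel = pmin(f, 1 - f), maf_source = rep(NA_real_, ncol(X)),
    sites = data.frame(chrom = chrom, pos = seq_len(ncol(X)), ref = "A",
                       alt = "T",
                       site_id = paste0(chrom, "_", seq_len(ncol(X))),
                       stringsAsFactors = FALSE)),
    class = "encoded_genotypes")
}

# independent band oracle for inheritance classification
band_bounds <- function(P1, P2, s1, s2, sh) {
  mpv <- (P1 + P2) / 2
  w1 <- s1 + sh; w2 <- s2 + sh; wm <- (s1 + s2) / 2 + sh
  c(P1 - w1, P1 + w1, mpv - wm, mpv + wm, P2 - w2, P2 + w2)
}
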
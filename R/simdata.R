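#' Minor-allele-frequency spectrum for founder simulation
#'
#' Defines the site-frequency spectrum from which founder minor-allele
#' frequencies are drawn. The default emulates the strongly rare-skewed
#' spectrum of the 1011 *S. cerevisiae* isolate collection, in which 92.7%
#' of polymorphic sites have MAF below 0.05.
#'
#' @param bin_edges strictly increasing MAF breakpoints in `[0, 0.5]`.
#' @param bin_weights sampling probability of each bin; must sum to 1.
#' @return object of class `maf_spectrum`.
#' @export
maf_spectrum <- function(bin_edges = c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
                         bin_weights = c(0.927, 0.022, 0.018, 0.013,
                                         0.011, 0.009)) {
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  if (min(bin_edges) < 0 || max(bin_edges) > 0.5) {
    stop("bin_edges must lie in [0, 0.5]")
  }
  if (length(bin_weights) != length(bin_edges) - 1) {
    stop("need one weight per bin")
  }
  if (any(bin_weights < 0) || abs(sum(bin_weights) - 1) > 1e-8) {
    stop("bin_weights must be non-negative and sum to 1")
  }
  structure(list(bin_edges = bin_edges, bin_weights = bin_weights),
            class = "maf_spectrum")
}

#' Uniform MAF spectrum over an interval
#'
#' Convenience spectrum placing uniform weight on `[lo, hi]`; useful when a
#' rare-skewed spectrum is not wanted (e.g. to maximise distinct genotype
#' patterns).
#' @param lo,hi interval bounds within `[0, 0.5]`.
#' @param n_bins number of equal-width bins.
#' @return a `maf_spectrum`.
#' @export
uniform_maf_spectrum <- function(lo = 0.05, hi = 0.5, n_bins = 9) {
  maf_spectrum(seq(lo, hi, length.out = n_bins + 1),
               rep(1 / n_bins, n_bins))
}

#' Simulate a panel of homozygous founders
#'
#' Draws biallelic sites whose founder-sample minor-allele frequencies
#' follow `spectrum`. Founders are homozygous diploids, so the attainable
#' MAFs are `c / n_founders` for a carrier count `c` in
#' `1..floor(n_founders/2)`; a site's carrier count is drawn uniformly from
#' the counts falling in its sampled bin, with a minimum of one carrier
#' (a bin implying zero carriers falls back to the nearest attainable
#' count). Each site also receives a `maf_source` annotation drawn from the
#' same bin, standing for the site's frequency in the larger source
#' population the founders were sampled from; founder sampling with the
#' one-carrier floor is exactly what boosts low-frequency source variants
#' in the panel. The minor allele is assigned to REF or ALT with equal
#' probability.
#'
#' @param n_founders number of founders (>= 2).
#' @param n_sites number of polymorphic sites (>= 1).
#' @param spectrum a [maf_spectrum()].
#' @param n_chromosomes sites are placed uniformly on this many
#'   chromosomes (default 16, the yeast karyotype), positions uniform on
#'   1..1e6 without replacement.
#' @param seed integer RNG seed; identical calls are byte-identical.
#' @return a [founder_panel()] whose `sites` carry `maf_source`.
#' @export
simulate_founders <- function(n_founders, n_sites,
                              spectrum = maf_spectrum(),
                              n_chromosomes = 16, seed = 1) {
  if (n_founders < 2) stop("n_founders must be >= 2")
  if (n_sites < 1) stop("n_sites must be >= 1")
  stopifnot(inherits(spectrum, "maf_spectrum"))
  pos_weight <- spectrum$bin_weights > 0
  if (all(spectrum$bin_edges[-1][pos_weight] < 1 / (2 * n_founders))) {
    stop("unattainable spectrum: all weight on MAF < 1/(2*n_founders)")
  }
  set.seed(seed)
  n_bins <- length(spectrum$bin_weights)
  c_max <- max(1L, n_founders %/% 2L)
  attainable <- seq_len(c_max)
  lo <- spectrum$bin_edges[-length(spectrum$bin_edges)]
  hi <- spectrum$bin_edges[-1]
  feasible <- lapply(seq_len(n_bins), function(b) {
    attainable[attainable / n_founders >= lo[b] &
               attainable / n_founders < hi[b]]
  })
  bin <- sample.int(n_bins, n_sites, replace = TRUE,
                    prob = spectrum$bin_weights)
  geno <- matrix(0L, n_founders, n_sites)
  maf_source <- numeric(n_sites)
  for (s in seq_len(n_sites)) {
    b <- bin[s]
    cc <- feasible[[b]]
    carriers_n <- if (length(cc)) {
      cc[sample.int(length(cc), 1L)]
    } else {
      # bin implies 0 (or > N/2) carriers: nearest attainable, min 1 carrier
      min(c_max, max(1L, as.integer(round(n_founders * (lo[b] + hi[b]) / 2))))
    }
    geno[sample.int(n_founders, carriers_n), s] <- 2L
    maf_source[s] <- stats::runif(1, lo[b], hi[b])
  }
  # minor allele is REF for a random half of the sites
  flip <- stats::runif(n_sites) < 0.5
  geno[, flip] <- 2L - geno[, flip, drop = FALSE]
  chrom_n <- sample.int(n_chromosomes, n_sites, replace = TRUE)
  pos <- integer(n_sites)
  for (ch in unique(chrom_n)) {
    idx <- which(chrom_n == ch)
    pos[idx] <- sort(sample.int(1e6, length(idx)))
  }
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), "")
  sites <- data.frame(
    chrom = sprintf("chr%02d", chrom_n), pos = pos,
    ref = ref, alt = alt, maf_source = maf_source,
    stringsAsFactors = FALSE)
  parent_ids <- paste0("P", formatC(seq_len(n_founders), width = 2,
                                    flag = "0"))
  founder_panel(geno, sites, parent_ids)
}

#' Simulate a trait architecture over a founder panel
#'
#' Draws a quantitative-trait model with additive effects and dominance
#' deviations at randomly chosen causal sites. Genotypic values follow the
#' Falconer parameterization: at a causal site with additive effect `a`
#' and dominance deviation `d`, the homozygous-alternate genotype
#' contributes `+a`, the homozygous-reference `-a`, and the heterozygote
#' `d`. Complete dominance is `d = +/-a`; over/underdominance is
#' `|d| > |a|`. The implied per-parent additive contributions (`true_gca`)
#' and per-cross non-additive residuals (`true_sca`) are computed by
#' exhaustive evaluation of genotypic values over all heterozygous crosses
#' of the panel, using the same Griffing decomposition the estimator
#' targets.
#'
#' @param panel a `founder_panel`.
#' @param n_causal number of causal sites (0 allowed: pure-noise trait).
#' @param additive_sd sd of the additive effects `a` (phenotype units).
#' @param dominance_fraction fraction of causal sites with complete
#'   dominance (`d = +/-a`, sign random).
#' @param overdominant_fraction fraction of causal sites with
#'   over/underdominance (`|d| > |a|`, sign random).
#' @param env_sd replicate noise sd (>= 0).
#' @param seed integer RNG seed.
#' @return object of class `trait_model` with fields `causal_site_ids`,
#'   `additive_effects`, `dominance_effects`, `env_sd`, `true_mu`,
#'   `true_gca` (named per-parent vector), `true_sca` (symmetric
#'   parent x parent matrix, `NA` diagonal).
#' @export
simulate_trait_model <- function(panel, n_causal, additive_sd = 0.1,
                                 dominance_fraction = 0,
                                 overdominant_fraction = 0,
                                 env_sd = 0.05, seed = 1) {
  stopifnot(inherits(panel, "founder_panel"))
  if (n_causal > n_sites(panel)) stop("n_causal exceeds number of sites")
  if (additive_sd < 0 || env_sd < 0) stop("sds must be non-negative")
  frs <- c(dominance_fraction, overdominant_fraction)
  if (any(frs < 0 | frs > 1) || sum(frs) > 1) {
    stop("fractions must be in [0,1] and sum to at most 1")
  }
  set.seed(seed)
  causal <- sort(sample.int(n_sites(panel), n_causal))
  a <- stats::rnorm(n_causal, 0, additive_sd)
  d <- numeric(n_causal)
  n_dom <- round(dominance_fraction * n_causal)
  n_od <- round(overdominant_fraction * n_causal)
  pick <- sample.int(n_causal, n_dom + n_od)
  dom_idx <- pick[seq_len(n_dom)]
  od_idx <- pick[n_dom + seq_len(n_od)]
  sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
  d[dom_idx] <- sgn(n_dom) * abs(a[dom_idx])
  d[od_idx] <- sgn(n_od) *
    (1.5 * abs(a[od_idx]) + pmax(0.5 * additive_sd, 1e-8))
  model <- structure(
    list(causal_site_ids = panel$sites$site_id[causal],
         causal_index = causal,
         additive_effects = a, dominance_effects = d, env_sd = env_sd),
    class = "trait_model")
  # ground-truth Griffing decomposition over all heterozygous crosses
  N <- n_parents(panel)
  if (N >= 4) {
    cmb <- utils::combn(N, 2)
    gh <- (panel$genotypes[cmb[1, ], causal, drop = FALSE] +
           panel$genotypes[cmb[2, ], causal, drop = FALSE]) %/% 2L
    z <- genotypic_values(model, gh, causal_only = TRUE)
    mu <- mean(z)
    zbar <- vapply(seq_len(N), function(i) {
      mean(z[cmb[1, ] == i | cmb[2, ] == i])
    }, 0)
    gca <- (N - 1) / (N - 2) * (zbar - mu)
    sca <- matrix(NA_real_, N, N,
                  dimnames = list(panel$parent_ids, panel$parent_ids))
    sval <- z - gca[cmb[1, ]] - gca[cmb[2, ]] - mu
    sca[cbind(cmb[1, ], cmb[2, ])] <- sval
    sca[cbind(cmb[2, ], cmb[1, ])] <- sval
    model$true_mu <- mu
    model$true_gca <- stats::setNames(gca, panel$parent_ids)
    model$true_sca <- sca
  }
  model
}

#' Genotypic values of a trait model
#'
#' Evaluates the deterministic genetic value of each individual given its
#' alt-allele dosages at the model's causal sites (columns indexed as in
#' the founder panel the model was built on).
#'
#' @param model a `trait_model`.
#' @param genotypes integer dosage matrix (individuals x all panel sites),
#'   or a matrix restricted to the causal sites if `causal_only = TRUE`.
#' @param causal_only is `genotypes` already restricted to causal columns?
#' @return numeric vector of genotypic values.
#' @export
genotypic_values <- function(model, genotypes, causal_only = FALSE) {
  stopifnot(inherits(model, "trait_model"))
  if (length(model$causal_index) == 0) {
    return(numeric(nrow(genotypes)))
  }
  g <- if (causal_only) genotypes else
    genotypes[, model$causal_index, drop = FALSE]
  a <- model$additive_effects
  d <- model$dominance_effects
  # hom contributes (g - 1) * a, het contributes d
  hom <- sweep(ifelse(g == 1L, 0, g - 1), 2, a, `*`)
  het <- sweep(g == 1L, 2, d, `*`)
  rowSums(hom + het)
}

#' Simulate replicate-level colony growth data
#'
#' Generates a replicate-level growth-ratio table for every cross of a
#' diallel panel and every founder (as homozygous diploid parental
#' strains). Replicate values are the genotypic value plus a common
#' baseline ratio plus i.i.d. noise; by default Gaussian with the model's
#' `env_sd`, optionally scaled Student-t (df = 4) to exercise the
#' robustness of median aggregation.
#'
#' @param panel a `founder_panel`.
#' @param crosses a `diallel_panel`; hybrid genotypes are synthesized if
#'   absent.
#' @param model a `trait_model` built on `panel`.
#' @param n_replicates_hybrid replicates per hybrid (default 6).
#' @param n_replicates_parent replicates per parental strain (default 54).
#' @param condition condition label for the output rows.
#' @param baseline growth ratio of the zero-genotypic-value background
#'   (default 1).
#' @param noise `"gaussian"` or `"t4"`.
#' @param seed integer RNG seed.
#' @return data.frame with columns `individual_id`, `condition`,
#'   `replicate`, `value`; one row per replicate measurement. Hybrids are
#'   keyed by `hybrid_id`, parents by parent id.
#' @export
simulate_colony_data <- function(panel, crosses, model,
                                 n_replicates_hybrid = 6,
                                 n_replicates_parent = 54,
                                 condition = "trait", baseline = 1,
                                 noise = c("gaussian", "t4"), seed = 1) {
  stopifnot(inherits(panel, "founder_panel"), inherits(model, "trait_model"))
  noise <- match.arg(noise)
  if (is.null(crosses$hybrid_genotypes)) {
    crosses <- synthesize_hybrid_genotypes(panel, crosses)
  }
  unknown <- setdiff(unique(c(crosses$crosses$parent1,
                              crosses$crosses$parent2)),
                     panel$parent_ids)
  if (length(unknown)) {
    stop("crosses reference unknown parents: ",
         paste(unknown, collapse = ", "))
  }
  set.seed(seed)
  hyb_val <- baseline + genotypic_values(model, crosses$hybrid_genotypes)
  par_val <- baseline + genotypic_values(model, panel$genotypes)
  ids <- c(rep(rownames(crosses$hybrid_genotypes),
               each = n_replicates_hybrid),
           rep(panel$parent_ids, each = n_replicates_parent))
  mu <- c(rep(hyb_val, each = n_replicates_hybrid),
          rep(par_val, each = n_replicates_parent))
  repl <- c(rep(seq_len(n_replicates_hybrid),
                times = nrow(crosses$hybrid_genotypes)),
            rep(seq_len(n_replicates_parent), times = n_parents(panel)))
  eps <- switch(noise,
    gaussian = stats::rnorm(length(mu), 0, model$env_sd),
    # t with 4 df rescaled to sd env_sd
    t4 = stats::rt(length(mu), df = 4) * model$env_sd / sqrt(2))
  data.frame(individual_id = ids, condition = condition,
             replicate = repl, value = mu + eps,
             stringsAsFactors = FALSE)
}
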
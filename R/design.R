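#' Founder panel of homozygous parental genotypes
#'
#' Container for the genotypes of a set of (intendedly) homozygous diploid
#' founders at biallelic sites. Genotypes are stored as alt-allele dosage:
#' 0 = homozygous reference, 1 = heterozygous (flagged and removed by
#' [filter_sites()]), 2 = homozygous alternate, `NA` = missing call.
#'
#' @param genotypes integer matrix, founders in rows, sites in columns,
#'   values in `{0, 1, 2, NA}`.
#' @param sites data.frame with one row per site and columns `chrom`,
#'   `pos` (1-based), `ref`, `alt`, and optionally `maf_source`, the
#'   minor-allele frequency of the site in a larger source population
#'   (e.g. the 1011-isolate collection the founders were drawn from).
#' @param parent_ids character vector of founder labels; defaults to
#'   `rownames(genotypes)`.
#'
#' @return An object of class `founder_panel`: a list with elements
#'   `parent_ids`, `sites`, `genotypes`. Sites are stored sorted by
#'   `(chrom, pos)`; positions must be unique within a chromosome.
#' @export
founder_panel <- function(genotypes, sites, parent_ids = rownames(genotypes)) {
  genotypes <- as.matrix(genotypes)
  if (is.null(parent_ids)) {
    parent_ids <- paste0("P", formatC(seq_len(nrow(genotypes)),
                                      width = 2, flag = "0"))
  }
  if (anyDuplicated(parent_ids)) stop("duplicate parent ids")
  if (nrow(genotypes) != length(parent_ids)) {
    stop("genotypes must have one row per parent")
  }
  if (ncol(genotypes) != nrow(sites)) {
    stop("genotypes must have one column per site")
  }
  bad <- !(genotypes %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  sites <- as.data.frame(sites)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(sites))) {
    stop("sites needs columns: ", paste(need, collapse = ", "))
  }
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  genotypes <- genotypes[, ord, drop = FALSE]
  if (any(unlist(tapply(sites$pos, sites$chrom, function(p) duplicated(p))))) {
    stop("positions must be unique within a chromosome")
  }
  site_id <- paste(sites$chrom, sites$pos, sep = "_")
  rownames(sites) <- NULL
  sites$site_id <- site_id
  dimnames(genotypes) <- list(parent_ids, site_id)
  storage.mode(genotypes) <- "integer"
  structure(list(parent_ids = as.character(parent_ids),
                 sites = sites,
                 genotypes = genotypes),
            class = "founder_panel")
}

#' @export
print.founder_panel <- function(x, ...) {
  cat("founder_panel:", length(x$parent_ids), "parents,",
      nrow(x$sites), "sites on",
      length(unique(x$sites$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Number of parents and sites of a founder panel
#' @param panel a `founder_panel`
#' @return integer
#' @export
n_parents <- function(panel) length(panel$parent_ids)

#' @rdname n_parents
#' @export
n_sites <- function(panel) nrow(panel$sites)

cross_id <- function(p1, p2) paste(p1, p2, sep = "x")

new_diallel_panel <- function(scheme, crosses, hybrid_genotypes = NULL) {
  crosses$hybrid_id <- cross_id(crosses$parent1, crosses$parent2)
  crosses$homozygous <- crosses$parent1 == crosses$parent2
  rownames(crosses) <- NULL
  structure(list(scheme = scheme, crosses = crosses,
                 hybrid_genotypes = hybrid_genotypes),
            class = "diallel_panel")
}

#' @export
print.diallel_panel <- function(x, ...) {
  cat("diallel_panel (", x$scheme, "): ", nrow(x$crosses), " crosses (",
      sum(!x$crosses$homozygous), " heterozygous, ",
      sum(x$crosses$homozygous), " homozygous)",
      if (is.null(x$hybrid_genotypes)) "; genotypes not synthesized yet",
      "\n", sep = "")
  invisible(x)
}

#' Enumerate a full diallel cross design
#'
#' All N^2 ordered (MATa x MATalpha) parent pairs, reciprocals included;
#' diagonal pairs are flagged homozygous. With 55 parents this yields the
#' 3025-hybrid design (2970 heterozygous ordered pairs + 55 homozygous).
#' Downstream phenotype analysis treats reciprocal hybrids as replicate
#' measurements of the same unordered cross.
#'
#' @param parent_ids character vector of distinct parent labels.
#' @return A `diallel_panel` with `scheme = "full_matrix"` and a `crosses`
#'   data.frame (columns `parent1`, `parent2`, `hybrid_id`, `homozygous`);
#'   hybrid genotypes are filled in by [synthesize_hybrid_genotypes()].
#' @seealso [enumerate_half_diallel()]
#' @export
enumerate_full_diallel <- function(parent_ids) {
  parent_ids <- as.character(parent_ids)
  if (length(parent_ids) < 1) stop("need at least one parent")
  if (anyDuplicated(parent_ids)) stop("duplicate parent ids")
  crosses <- expand.grid(parent2 = parent_ids, parent1 = parent_ids,
                         stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)[, c("parent1", "parent2")]
  new_diallel_panel("full_matrix", crosses)
}

#' Enumerate a half diallel (unordered parent pairs)
#'
#' C(N,2) unordered pairs, optionally plus the N homozygous diagonal
#' crosses. With 34 parents and the diagonal this is the 595-hybrid GWAS
#' panel.
#'
#' @param parent_ids character vector of distinct parent labels (>= 2).
#' @param include_diagonal include the N selfing crosses?
#' @return A `diallel_panel` with scheme `"half_matrix"` or
#'   `"half_matrix_with_diagonal"`.
#' @export
enumerate_half_diallel <- function(parent_ids, include_diagonal = FALSE) {
  parent_ids <- as.character(parent_ids)
  if (length(parent_ids) < 2) stop("need at least two parents")
  if (anyDuplicated(parent_ids)) stop("duplicate parent ids")
  cmb <- utils::combn(parent_ids, 2)
  crosses <- data.frame(parent1 = cmb[1, ], parent2 = cmb[2, ],
                        stringsAsFactors = FALSE)
  if (include_diagonal) {
    crosses <- rbind(data.frame(parent1 = parent_ids, parent2 = parent_ids,
                                stringsAsFactors = FALSE),
                     crosses)
  }
  new_diallel_panel(
    if (include_diagonal) "half_matrix_with_diagonal" else "half_matrix",
    crosses)
}

#' Construct hybrid genotypes in silico
#'
#' Combines the two homozygous parental genomes of each cross: the hybrid
#' is homozygous where both parents carry the same allele and heterozygous
#' where they differ. Sites must be clean (no missing, no heterozygous
#' founder call) — run [filter_sites()] first.
#'
#' @param panel a `founder_panel`.
#' @param crosses a `diallel_panel` (genotypes ignored if present) or a
#'   data.frame with columns `parent1`, `parent2`.
#' @return The `diallel_panel` with `hybrid_genotypes` filled in: an
#'   integer matrix (hybrids x sites) of alt-allele dosages 0/1/2.
#' @export
synthesize_hybrid_genotypes <- function(panel, crosses) {
  stopifnot(inherits(panel, "founder_panel"))
  dp <- if (inherits(crosses, "diallel_panel")) crosses else
    new_diallel_panel("custom", as.data.frame(crosses))
  cr <- dp$crosses
  unknown <- setdiff(unique(c(cr$parent1, cr$parent2)), panel$parent_ids)
  if (length(unknown)) {
    stop("crosses reference unknown parents: ",
         paste(unknown, collapse = ", "))
  }
  g <- panel$genotypes
  if (anyNA(g) || any(g == 1L)) {
    stop("founder panel has missing or heterozygous calls; ",
         "run filter_sites() before synthesizing hybrids")
  }
  h <- (g[cr$parent1, , drop = FALSE] + g[cr$parent2, , drop = FALSE]) %/% 2L
  rownames(h) <- cross_id(cr$parent1, cr$parent2)
  dp$hybrid_genotypes <- h
  dp$sites <- panel$sites
  dp
}

#' Filter founder sites to clean biallelic calls
#'
#' Drops sites that are monomorphic across the founders, contain any
#' missing call, or contain any heterozygous founder call (founders are
#' expected to be fully homozygous). Counting priority per site:
#' missing > heterozygous > monomorphic.
#'
#' @param panel a `founder_panel`.
#' @return list with `panel` (the filtered `founder_panel`) and `report`,
#'   a data.frame of per-reason removed-site counts.
#' @export
filter_sites <- function(panel) {
  stopifnot(inherits(panel, "founder_panel"))
  g <- panel$genotypes
  has_missing <- apply(g, 2, anyNA)
  has_het <- apply(g == 1L, 2, any, na.rm = TRUE) & !has_missing
  mono <- !has_missing & !has_het &
    apply(g, 2, function(x) length(unique(x)) == 1L)
  keep <- !(has_missing | has_het | mono)
  out <- panel
  out$sites <- panel$sites[keep, , drop = FALSE]
  rownames(out$sites) <- NULL
  out$genotypes <- panel$genotypes[, keep, drop = FALSE]
  report <- data.frame(
    reason = c("missing", "heterozygous_founder", "monomorphic"),
    n_removed = c(sum(has_missing), sum(has_het), sum(mono)))
  list(panel = out, report = report)
}

#' Prune long-range linkage disequilibrium
#'
#' With few founders, distant sites frequently share an identical founder
#' genotype pattern (perfect LD) by chance, which inflates long-range LD in
#' the hybrid panel. Sites are grouped into perfect-LD classes (identical
#' genotype column); within a class, consecutive sites at most
#' `max_block_gap` bp apart on the same chromosome form a haplotype block.
#' A class spanning more than `max_shared_blocks` blocks keeps only the
#' sites of its first `max_shared_blocks` blocks in genomic order.
#'
#' @param panel a `founder_panel` (sites sorted, as the constructor
#'   guarantees).
#' @param max_block_gap maximum within-block gap in bp (default 25 kb).
#' @param max_shared_blocks maximum number of blocks a pattern may occupy
#'   before the surplus is removed (default 2: patterns shared more than
#'   twice across the genome are pruned).
#' @return list with `panel` (pruned) and `report`, a data.frame of the
#'   classes that lost sites (`pattern_class`, `n_blocks`, `n_removed`).
#' @export
prune_long_range_ld <- function(panel, max_block_gap = 25000,
                                max_shared_blocks = 2) {
  stopifnot(inherits(panel, "founder_panel"))
  g <- panel$genotypes
  st <- panel$sites
  if (is.unsorted(order(st$chrom, st$pos))) stop("sites must be sorted")
  key <- apply(g, 2, paste, collapse = "")
  keep <- rep(TRUE, ncol(g))
  rep_class <- character(0); rep_blocks <- integer(0); rep_rm <- integer(0)
  for (cls in unique(key)) {
    idx <- which(key == cls)
    if (length(idx) < 2) next
    # block id: increments at chromosome change or gap > max_block_gap
    ch <- st$chrom[idx]; po <- st$pos[idx]
    newblk <- c(TRUE, ch[-1] != ch[-length(ch)] |
                  (po[-1] - po[-length(po)]) > max_block_gap)
    blk <- cumsum(newblk)
    nblk <- max(blk)
    if (nblk > max_shared_blocks) {
      drop <- idx[blk > max_shared_blocks]
      keep[drop] <- FALSE
      rep_class <- c(rep_class, cls)
      rep_blocks <- c(rep_blocks, nblk)
      rep_rm <- c(rep_rm, length(drop))
    }
  }
  out <- panel
  out$sites <- st[keep, , drop = FALSE]
  rownames(out$sites) <- NULL
  out$genotypes <- g[, keep, drop = FALSE]
  list(panel = out,
       report = data.frame(pattern_class = rep_class, n_blocks = rep_blocks,
                           n_removed = rep_rm))
}
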
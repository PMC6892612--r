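#' Write founder genotypes as VCF
#'
#' One sample per founder; homozygous calls are written as `0/0` / `1/1`,
#' heterozygous as `0/1`, missing as `./.`. The source-population MAF
#' annotation, when present, is stored in the INFO field as `SMAF=`.
#' Output is bgzip/gzip-compressed (`.vcf.gz`), per vcfR conventions.
#'
#' @param panel a `founder_panel`.
#' @param file output path (a `.gz` suffix is appended by vcfR if
#'   missing).
#' @return the path written, invisibly.
#' @export
write_founder_vcf <- function(panel, file) {
  stopifnot(inherits(panel, "founder_panel"))
  st <- panel$sites
  info <- if ("maf_source" %in% names(st)) {
    sprintf("SMAF=%.6g", st$maf_source)
  } else rep(".", nrow(st))
  fix <- cbind(CHROM = as.character(st$chrom), POS = as.character(st$pos),
               ID = st$site_id, REF = st$ref, ALT = st$alt,
               QUAL = ".", FILTER = "PASS", INFO = info)
  gtcode <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  g <- panel$genotypes
  gt <- matrix(gtcode[as.character(t(g))], nrow = ncol(g),
               dimnames = list(NULL, panel$parent_ids))
  gt[is.na(gt)] <- "./."
  gt <- cbind(FORMAT = "GT", gt)
  vcf <- methods::new(methods::getClass("vcfR",
                                        where = asNamespace("vcfR")),
    meta = c("##fileformat=VCFv4.2",
             "##INFO=<ID=SMAF,Number=1,Type=Float,Description=\"Source population minor allele frequency\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
    fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = file)
  invisible(file)
}

#' Read founder genotypes from a VCF
#'
#' Expects one sample per founder with GT calls; `0/0`, `1/1`, `0/1`
#' (or `|`-phased equivalents) map to dosages 0/2/1, anything else to
#' missing. An `SMAF` INFO field is recovered as the `maf_source`
#' annotation.
#'
#' @param file VCF path (plain or gzipped).
#' @return a `founder_panel`.
#' @export
read_founder_vcf <- function(file) {
  vcf <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt == "0/0"] <- 0L
  dos[gt %in% c("0/1", "1/0")] <- 1L
  dos[gt == "1/1"] <- 2L
  fix <- vcfR::getFIX(vcf)
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  smaf <- suppressWarnings(vcfR::extract.info(vcf, "SMAF", as.numeric = TRUE))
  if (!all(is.na(smaf))) sites$maf_source <- smaf
  founder_panel(t(dos), sites, parent_ids = colnames(gt))
}

#' Write genotypes as PLINK PED/MAP (recode12 dialect)
#'
#' Alleles are recoded 1 (reference) / 2 (alternate); genotype columns in
#' the PED are space-separated allele pairs (`1 1`, `1 2`, `2 2`, missing
#' `0 0`). The MAP holds chromosome, site id, a zero genetic distance and
#' the physical position. No pre-installed R package parses this dialect,
#' so the (trivial, whitespace-tabular) reader/writer is implemented here.
#'
#' @param genotypes integer dosage matrix (individuals x sites, 0/1/2/NA).
#' @param sites data.frame with `chrom`, `pos` and (optionally) `site_id`.
#' @param ids individual labels.
#' @param prefix output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return the prefix, invisibly.
#' @export
write_ped_map <- function(genotypes, sites, ids, prefix) {
  if (is.null(sites$site_id)) {
    sites$site_id <- paste(sites$chrom, sites$pos, sep = "_")
  }
  map <- data.frame(sites$chrom, sites$site_id, 0L, sites$pos)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  code <- c(`0` = "1 1", `1` = "1 2", `2` = "2 2")
  gcols <- matrix(code[as.character(genotypes)], nrow = nrow(genotypes))
  gcols[is.na(gcols)] <- "0 0"
  ped <- cbind(ids, ids, "0", "0", "0", "-9", gcols)
  utils::write.table(ped, paste0(prefix, ".ped"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK PED/MAP (recode12 dialect)
#'
#' @param prefix path prefix of `<prefix>.ped` / `<prefix>.map`.
#' @return list with `genotypes` (dosage matrix), `sites`, `ids`.
#' @export
read_ped_map <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), sep = "\t",
                           stringsAsFactors = FALSE)
  names(map) <- c("chrom", "site_id", "cm", "pos")
  ped <- utils::read.table(paste0(prefix, ".ped"), sep = "\t",
                           stringsAsFactors = FALSE)
  ids <- ped[, 2]
  gcols <- as.matrix(ped[, -(1:6), drop = FALSE])
  dos <- matrix(NA_integer_, nrow(gcols), ncol(gcols))
  dos[gcols %in% c("1 1")] <- 0L
  dos[gcols %in% c("1 2", "2 1")] <- 1L
  dos[gcols %in% c("2 2")] <- 2L
  dimnames(dos) <- list(ids, map$site_id)
  list(genotypes = dos,
       sites = map[, c("chrom", "pos", "site_id")], ids = ids)
}

#' Read / write replicate-level phenotype tables
#'
#' TSV with columns `individual_id`, `condition`, `replicate`, `value`.
#'
#' @param file path.
#' @return data.frame.
#' @export
read_replicates_tsv <- function(file) {
  if (!file.exists(file)) stop("phenotype file not found: ", file)
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("individual_id", "condition", "replicate", "value")
  if (!all(need %in% names(df))) {
    stop("replicate table needs columns: ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_replicates_tsv
#' @param df data.frame to write.
#' @export
write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
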
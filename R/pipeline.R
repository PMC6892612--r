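#' Pipeline configuration
#'
#' Assembles (and validates) the configuration driving [run_pipeline()].
#' Either simulation parameters are given (the default) or paths to a
#' founder VCF (`genotype_file`) and a replicate-level phenotype TSV
#' (`phenotype_file`).
#'
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param scheme crossing scheme: `"full"`, `"half"` or `"half+diag"`.
#' @param n_founders,n_sites,n_conditions simulation sizes.
#' @param n_causal,additive_sd,dominance_fraction,overdominant_fraction,env_sd
#'   trait-architecture parameters ([simulate_trait_model()]).
#' @param n_replicates_hybrid,n_replicates_parent replicate counts.
#' @param genotype_file,phenotype_file optional input paths (disable
#'   simulation).
#' @param encodings GWAS encodings to run.
#' @param n_perm,alpha permutation-threshold parameters.
#' @param maf_low,maf_rare source-MAF class thresholds.
#' @param max_block_gap LD-pruning block gap (bp).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, scheme = c("half+diag", "half",
                                                 "full"),
                            n_founders = 10, n_sites = 500,
                            n_conditions = 3, n_causal = 10,
                            additive_sd = 0.1, dominance_fraction = 0.2,
                            overdominant_fraction = 0.05, env_sd = 0.05,
                            n_replicates_hybrid = 6,
                            n_replicates_parent = 54,
                            genotype_file = NULL, phenotype_file = NULL,
                            encodings = c("additive", "overdominant"),
                            n_perm = 100, alpha = 0.05,
                            maf_low = 0.05, maf_rare = 0.01,
                            max_block_gap = 25000) {
  cfg <- list(seed = as.integer(seed), scheme = match.arg(scheme),
              n_founders = n_founders, n_sites = n_sites,
              n_conditions = n_conditions, n_causal = n_causal,
              additive_sd = additive_sd,
              dominance_fraction = dominance_fraction,
              overdominant_fraction = overdominant_fraction,
              env_sd = env_sd,
              n_replicates_hybrid = n_replicates_hybrid,
              n_replicates_parent = n_replicates_parent,
              genotype_file = genotype_file,
              phenotype_file = phenotype_file,
              encodings = match.arg(encodings, several.ok = TRUE),
              n_perm = n_perm, alpha = alpha,
              maf_low = maf_low, maf_rare = maf_rare,
              max_block_gap = max_block_gap)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' The file representation round-trips losslessly.
#' @param file YAML path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(file) {
  raw <- yaml::read_yaml(file)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' Run the full diallel analysis pipeline
#'
#' Executes the stages in order — simulate (or load) founders and
#' replicate phenotypes, enumerate crosses and synthesize hybrid
#' genotypes (with site filtering and long-range LD pruning), aggregate
#' replicates, Griffing combining-ability/heritability analysis,
#' inheritance-mode classification, and mixed-model GWAS with permutation
#' thresholds and MAF enrichment — writing each stage's tables to
#' `out_dir` plus a JSON manifest with seeds and output checksums. The
#' run is deterministic under a fixed configuration.
#'
#' @param config a `pipeline_config` (or YAML path).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest. On stage failure an error is raised naming the stage (and
#'   recorded in `pipeline.log`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "pipeline.log")
  cat("", file = logfile)
  logmsg <- function(...) {
    line <- paste0(...)
    message(line)
    cat(line, "\n", file = logfile, append = TRUE)
  }
  stage <- function(name, expr) {
    logmsg("stage ", name, ": start")
    tryCatch(expr, error = function(e) {
      logmsg("stage ", name, ": FAILED: ", conditionMessage(e))
      stop("pipeline failed at stage '", name, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv(df, path)
    outputs <<- c(outputs, path)
    path
  }

  sim <- is.null(config$genotype_file)
  founders <- stage("simulate", {
    if (sim) {
      simulate_founders(config$n_founders, config$n_sites,
                        seed = config$seed)
    } else {
      read_founder_vcf(config$genotype_file)
    }
  })

  des <- stage("design", {
    flt <- filter_sites(founders)
    prn <- prune_long_range_ld(flt$panel,
                               max_block_gap = config$max_block_gap)
    crosses <- switch(config$scheme,
      full = enumerate_full_diallel(prn$panel$parent_ids),
      half = enumerate_half_diallel(prn$panel$parent_ids, FALSE),
      `half+diag` = enumerate_half_diallel(prn$panel$parent_ids, TRUE))
    dp <- synthesize_hybrid_genotypes(prn$panel, crosses)
    emit(flt$report, "filter_report.tsv")
    emit(prn$report, "prune_report.tsv")
    emit(dp$crosses, "crosses.tsv")
    list(panel = prn$panel, diallel = dp)
  })

  replicates <- stage("pheno", {
    if (!sim || !is.null(config$phenotype_file)) {
      read_replicates_tsv(config$phenotype_file)
    } else {
      conds <- sprintf("cond%02d", seq_len(config$n_conditions))
      do.call(rbind, lapply(seq_along(conds), function(i) {
        model <- simulate_trait_model(
          des$panel, n_causal = min(config$n_causal, n_sites(des$panel)),
          additive_sd = config$additive_sd,
          dominance_fraction = config$dominance_fraction,
          overdominant_fraction = config$overdominant_fraction,
          env_sd = config$env_sd, seed = config$seed + 101L * i)
        simulate_colony_data(
          des$panel, des$diallel, model,
          n_replicates_hybrid = config$n_replicates_hybrid,
          n_replicates_parent = config$n_replicates_parent,
          condition = conds[i], seed = config$seed + 101L * i + 50L)
      }))
    }
  })
  phenotypes <- stage("pheno", {
    ph <- aggregate_replicates(replicates)
    emit(ph, "phenotypes.tsv")
    ph
  })

  griffing <- stage("griffing", {
    gr <- griffing_analysis(phenotypes, des$diallel)
    emit(gr$summary, "griffing_summary.tsv")
    gca_tab <- do.call(rbind, lapply(gr$per_condition, function(r) {
      data.frame(condition = r$condition, parent = r$parents,
                 gca = as.numeric(r$gca),
                 e_gca = as.numeric(r$e_gca), stringsAsFactors = FALSE)
    }))
    emit(gca_tab, "griffing_gca.tsv")
    gr
  })

  calls <- stage("inheritance", {
    cl <- classify_inheritance(phenotypes, des$diallel)
    emit(cl, "inheritance_calls.tsv")
    emit(summarize_inheritance(cl), "inheritance_summary.tsv")
    cl
  })

  gwas <- stage("assoc", {
    # the association panel is the half matrix plus diagonal; diagonal
    # hybrids missing from the phenotypes are stood in by their parent
    ap <- enumerate_half_diallel(des$panel$parent_ids, TRUE)
    ap <- synthesize_hybrid_genotypes(des$panel, ap)
    ph <- phenotypes
    diag_ids <- cross_id(des$panel$parent_ids, des$panel$parent_ids)
    need <- !(diag_ids %in% ph$individual_id)
    if (any(need)) {
      sub <- ph[ph$individual_id %in% des$panel$parent_ids[need], ,
                drop = FALSE]
      sub$individual_id <- cross_id(sub$individual_id, sub$individual_id)
      ph <- rbind(ph, sub)
    }
    res <- run_gwas(ph, ap, encodings = config$encodings,
                    n_perm = config$n_perm, alpha = config$alpha,
                    seed = config$seed)
    emit(res, "gwas_results.tsv")
    enr <- maf_enrichment(res, thresholds = c(low = config$maf_low,
                                              rare = config$maf_rare))
    emit(enr$maf_table, "maf_table.tsv")
    list(results = res, enrichment = enr)
  })

  manifest <- list(
    package = "diallelkit",
    version = as.character(utils::packageVersion("diallelkit")),
    seed = config$seed,
    config = unclass(config),
    outputs = as.list(stats::setNames(
      as.character(tools::md5sum(outputs)), basename(outputs))))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  logmsg("pipeline complete: ", length(outputs), " output files")
  invisible(list(founders = founders, design = des,
                 phenotypes = phenotypes, griffing = griffing,
                 inheritance = calls, gwas = gwas, manifest = manifest))
}
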
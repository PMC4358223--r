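#' Run the full simulation-to-evaluation pipeline
#'
#' Orchestrates the stages end to end: cohort simulation, marker QC,
#' pedigree REML for variance components, cross-validated prediction with
#' the requested methods, and (optionally) the marker-density experiment.
#' Every stage writes its outputs under `config$out_dir` in plain-text
#' formats (pedigree CSV, PLINK PED/MAP, TSV tables, JSON reports) and the
#' run closes with a manifest recording parameters, seeds and file
#' checksums, so reruns with the same configuration are reproducible.
#'
#' @param config a named list (see [default_config()]) or the path to a YAML
#'   file with the same fields.
#' @return the manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @examples
#' \donttest{
#' cfg <- default_config(out_dir = tempfile("run"))
#' cfg$n_founders <- 80; cfg$n_snps <- 100
#' cfg$methods <- "gblup"
#' man <- run_pipeline(cfg)
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml_config(config)
  config <- utils::modifyList(default_config(), config)
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")),
                                     sprintf(...))
  t0 <- proc.time()[["elapsed"]]

  log_stage("simulate: %d founders x %d generations, %d SNPs",
            config$n_founders, config$n_generations, config$n_snps)
  arch <- trait_architecture(n_qtl = config$n_qtl,
                             sigma2_a = config$sigma2_a,
                             sigma2_e = config$sigma2_e)
  co <- sim_chd_cohort(config$n_founders, config$n_generations,
                       n_snps = config$n_snps, arch = arch,
                       seed = config$seed)
  write_pedigree(co$pedigree, file.path(config$out_dir, "pedigree.csv"))
  sex <- co$pedigree$sex[match(rownames(co$genotypes),
                               as.character(co$pedigree$id))]
  write_plink(co$genotypes, file.path(config$out_dir, "geno"), sex = sex)
  write.table(co$phenotypes, file.path(config$out_dir, "phenotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  log_stage("qc: sample CR >= %.2f, SNP CR >= %.2f, MAF >= %.3f",
            config$min_sample_cr, config$min_snp_cr, config$min_maf)
  qs <- filter_samples(co$genotypes, config$min_sample_cr)
  qm <- filter_snps(qs$geno, config$min_snp_cr, config$min_maf,
                    hwe_alpha = config$hwe_alpha)
  co$genotypes <- qm$geno
  co$genotyped_ids <- intersect(co$genotyped_ids,
                                as.integer(rownames(qm$geno)))
  writeLines(format(qm$report), file.path(config$out_dir, "qc_report.json"))

  results <- list()
  for (trait in config$traits) {
    log_stage("reml: trait %s", trait)
    A <- a_matrix(co$pedigree)
    vc <- reml_fit(stats::as.formula(
      paste(trait, "~ sex + age_spline(age_days)")), co$phenotypes, A)
    jsonlite::write_json(
      list(trait = trait, sigma2_a = vc$sigma2_a, sigma2_e = vc$sigma2_e,
           h2 = vc$h2, se = as.list(vc$se)),
      file.path(config$out_dir, paste0("reml_", trait, ".json")),
      auto_unbox = TRUE, digits = NA)
    for (m in config$methods) {
      log_stage("cv: %s / %s", trait, m)
      cv <- cross_validate(co, m, trait = trait, k = config$k,
                           seed = config$seed, varcomp = vc,
                           chain = chain_settings(config$burn_in,
                                                  config$n_samples,
                                                  config$thin,
                                                  seed = config$seed))
      results[[length(results) + 1L]] <-
        cbind(trait = trait, method = m, cv$per_fold,
              mean_r = cv$mean_r, mean_pa = cv$mean_pa, h2 = cv$h2)
    }
    if (isTRUE(config$density)) {
      log_stage("density experiment: trait %s", trait)
      dens <- density_experiment(co, fractions = config$density_fractions,
                                 modes = config$density_modes, trait = trait,
                                 k = config$k, seed = config$seed,
                                 varcomp = vc)
      write.table(dens, file.path(config$out_dir,
                                  paste0("density_", trait, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  res <- do.call(rbind, results)
  write.table(res, file.path(config$out_dir, "cv_results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("caninegp")),
    config = config[setdiff(names(config), "out_dir")],
    elapsed_seconds = round(proc.time()[["elapsed"]] - t0, 2),
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @rdname run_pipeline
#' @param ... fields overriding the defaults.
#' @export
default_config <- function(...) {
  cfg <- list(
    n_founders = 300L, n_generations = 3L, n_snps = 2000L, n_qtl = 0L,
    sigma2_a = 0.11, sigma2_e = 0.29,
    min_sample_cr = 0.90, min_snp_cr = 0.98, min_maf = 0.01,
    hwe_alpha = 0.05,
    traits = "THS",
    methods = c("blup", "gblup", "bayes_c", "single_step"),
    k = 5L, seed = 1L,
    burn_in = 2000L, n_samples = 500L, thin = 4L,
    density = FALSE,
    density_fractions = c(0.01, 0.1, 0.2, 0.5, 0.75, 1),
    density_modes = c("random", "top_gwas", "biased"),
    out_dir = file.path(tempdir(), "caninegp_run"))
  utils::modifyList(cfg, list(...))
}

validate_config <- function(config) {
  known <- c("blup", "gblup", "bayes_c", "single_step")
  bad <- setdiff(config$methods, known)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "),
                        " (choose from ", paste(known, collapse = ", "), ")")
  if (config$seed %% 1 != 0) stop("seed must be an integer")
  if (!is.numeric(config$k) || config$k < 2) stop("k must be >= 2")
  invisible(config)
}

## minimal YAML-subset reader (flat key: value pairs and inline vectors)
yaml_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("cannot parse config line: ", ln)
    val <- trimws(kv[3])
    if (grepl("^\\[.*\\]$", val)) {
      val <- trimws(strsplit(gsub("^\\[|\\]$", "", val), ",")[[1]])
    }
    num <- suppressWarnings(as.numeric(val))
    if (!anyNA(num)) val <- num
    if (identical(val, "true")) val <- TRUE
    if (identical(val, "false")) val <- FALSE
    cfg[[kv[2]]] <- val
  }
  cfg
}
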
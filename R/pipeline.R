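#' Simulate a cohort and run the full in-memory analysis
#'
#' Convenience driver used by the replication experiments: simulates
#' genotypes, annotation, libraries and phenotypes from one configuration,
#' then runs (i) the two-stage age-corrected epidemiological regression,
#' (ii) a linear GWAS of the balding pattern among males (age-adjusted),
#' (iii) genome-wide polygenic score associations per sex and threshold,
#' and (iv) the pathway PRS scan with per-iteration FDR.
#'
#' @param config A [sim_config()].
#' @param thresholds P-value cut-offs for variant selection.
#' @param clump Apply LD clumping genome-wide before scoring.
#' @param run_pprs Run the pathway scan (the most expensive stage).
#' @param sexes Sex strata for the polygenic score associations.
#' @return List with `summary`, `epi`, `sumstats_aga`, `prs_assoc`,
#'   `pprs` (or `NULL`), `phenotypes`, `true_effects`.
#' @export
run_cohort_analysis <- function(config, thresholds = c(5e-8, 5e-5),
                                clump = TRUE, run_pprs = TRUE,
                                sexes = c("male", "female")) {
  geno <- simulate_genotypes(config)
  ann <- simulate_annotation(config)
  sim <- simulate_phenotypes(geno, ann$annotation, ann$libraries, config)
  phen <- sim$phenotypes

  summary <- summarize_cohort(phen)
  res <- residualize_aga_on_age(phen)
  epi <- regress_severity_on_aga(phen, res)

  males <- phen$sex == "male"
  ss <- run_gwas(geno, phen$aga_pattern, covariates = phen$age_at_assessment,
                 model = "linear", subset = males)

  prs_assoc <- list()
  for (thr in thresholds) {
    sel <- suppressWarnings(select_variants(ss, thr))
    if (clump && nrow(sel) > 1L) sel <- ld_clump(sel, geno)
    prs <- compute_prs(geno, sel[, c("id", "beta")])
    for (sx in sexes) {
      prs_assoc[[length(prs_assoc) + 1L]] <-
        suppressWarnings(associate_prs(prs, phen, sx, label = thr))
    }
  }
  prs_assoc <- do.call(rbind, prs_assoc)

  pprs <- NULL
  if (run_pprs) {
    pprs <- run_pprs_scan(geno, ss, phen, ann$annotation, ann$libraries,
                          thresholds = thresholds, sexes = sexes,
                          clump = clump,
                          window_bp = config$mapping_window_bp)
  }
  list(summary = summary, epi = epi, sumstats_aga = ss,
       prs_assoc = prs_assoc, pprs = pprs, phenotypes = phen,
       true_effects = sim$true_effects)
}

#' Run the end-to-end pipeline, writing all stage outputs to disk
#'
#' Executes simulate, epidemiological analysis, GWAS of both traits, LD
#' score regression, genome-wide PRS and the pathway PRS scan, writing every
#' stage's output (VCF, TSVs, GMT libraries, BED annotation) plus a JSON run
#' manifest with the seed, configuration hash and per-file MD5 checksums.
#' Any stage failure halts the run with the stage named; files written
#' before the failure stay in place and the manifest flags the run
#' incomplete.
#'
#' @param config A [sim_config()] (or path to a YAML file readable by
#'   [read_pipeline_config()]).
#' @param out_dir Output directory (created if needed).
#' @param thresholds P-value cut-offs for the PRS stages.
#' @param seed Optional override of `config$seed`.
#' @param quiet Suppress per-stage progress messages.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, thresholds = c(5e-8, 5e-5),
                         seed = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_sim_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  outputs <- character(0)
  stage_status <- list()
  t0 <- Sys.time()

  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      stage_status[[name]] <<- "failed"
      write_manifest(out_dir, config, outputs, stage_status, t0, complete = FALSE)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(res))
    }
    stage_status[[name]] <<- "ok"
    res
  }
  emit <- function(file) outputs <<- c(outputs, file)

  sim <- run_stage("simulate", function() {
    geno <- simulate_genotypes(config)
    ann <- simulate_annotation(config)
    ph <- simulate_phenotypes(geno, ann$annotation, ann$libraries, config)
    say("simulate: %d individuals x %d variants, %d genes",
        nrow(geno$dosages), ncol(geno$dosages), nrow(ann$annotation))
    write_vcf(geno, file.path(out_dir, "genotypes.vcf")); emit("genotypes.vcf")
    write_dosage_tsv(geno, file.path(out_dir, "genotypes_dosage.tsv"))
    emit("genotypes_dosage.tsv")
    write_phenotypes(ph$phenotypes, file.path(out_dir, "phenotypes.tsv"))
    emit("phenotypes.tsv")
    write_annotation_bed(ann$annotation, file.path(out_dir, "annotation.bed"))
    emit("annotation.bed")
    for (lib in ann$libraries) {
      f <- sprintf("library_%s.gmt", lib$library_name)
      write_gmt(lib, file.path(out_dir, f)); emit(f)
    }
    list(geno = geno, ann = ann, phen = ph$phenotypes, truth = ph$true_effects)
  })

  epi <- run_stage("epi", function() {
    cs <- summarize_cohort(sim$phen)
    res <- residualize_aga_on_age(sim$phen)
    full <- regress_severity_on_aga(sim$phen, res)
    say("epi: beta = %.3f (se %.3f, p = %.3g) on %d males", full$beta,
        full$se, full$p, full$n)
    d <- data.frame(age_window = "full", beta = full$beta, se = full$se,
                    p = full$p, n = full$n)
    utils::write.table(d, file.path(out_dir, "epi_regression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("epi_regression.tsv")
    list(summary = cs, regression = full)
  })

  gwas <- run_stage("gwas", function() {
    males <- sim$phen$sex == "male"
    ss_aga <- run_gwas(sim$geno, sim$phen$aga_pattern,
                       covariates = sim$phen$age_at_assessment,
                       model = "linear", subset = males)
    ss_cov <- run_gwas(sim$geno, sim$phen$hospitalized,
                       covariates = sim$phen$age_at_event,
                       model = "logistic")
    say("gwas: %d variants; min p (AGA) = %.3g", nrow(ss_aga),
        min(ss_aga$p, na.rm = TRUE))
    write_sumstats(ss_aga, file.path(out_dir, "sumstats_aga.tsv"))
    emit("sumstats_aga.tsv")
    write_sumstats(ss_cov, file.path(out_dir, "sumstats_covid.tsv"))
    emit("sumstats_covid.tsv")
    list(aga = ss_aga, covid = ss_cov)
  })

  ldsc <- run_stage("ldsc", function() {
    ld <- compute_ld_scores(sim$geno, window_bp = 1e6)
    write_ld_scores(ld, file.path(out_dir, "ld_scores.tsv"))
    emit("ld_scores.tsv")
    rg <- estimate_rg(harmonize(gwas$aga, sim$geno),
                      harmonize(gwas$covid, sim$geno), ld)
    say("ldsc: rg = %.3f (se %.3f)", rg$rg, rg$se_rg)
    d <- data.frame(rg = rg$rg, se_rg = rg$se_rg, p = rg$p,
                    h2_aga = rg$h2_trait1, h2_covid = rg$h2_trait2,
                    gencov = rg$gencov, M = rg$M, n_blocks = rg$n_blocks)
    utils::write.table(d, file.path(out_dir, "ldsc_rg.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit("ldsc_rg.tsv")
    rg
  })

  prs <- run_stage("prs", function() {
    rows <- list()
    score_rows <- list()
    for (thr in thresholds) {
      sel <- suppressWarnings(select_variants(gwas$aga, thr))
      if (nrow(sel) > 1L) sel <- ld_clump(sel, sim$geno)
      pr <- compute_prs(sim$geno, sel[, c("id", "beta")])
      score_rows[[length(score_rows) + 1L]] <-
        data.frame(IID = pr$individual_id, threshold = thr,
                   score = pr$score,
                   n_variants = attr(pr, "n_variants_used"))
      for (sx in c("male", "female")) {
        rows[[length(rows) + 1L]] <-
          suppressWarnings(associate_prs(pr, sim$phen, sx, label = thr))
      }
    }
    assoc <- do.call(rbind, rows)
    say("prs: %d associations, min p = %.3g", nrow(assoc), min(assoc$p, na.rm = TRUE))
    utils::write.table(do.call(rbind, score_rows),
                       file.path(out_dir, "prs_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("prs_scores.tsv")
    utils::write.table(assoc, file.path(out_dir, "prs_association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("prs_association.tsv")
    assoc
  })

  pprs <- run_stage("pprs", function() {
    tab <- run_pprs_scan(sim$geno, gwas$aga, sim$phen, sim$ann$annotation,
                         sim$ann$libraries, thresholds = thresholds,
                         window_bp = config$mapping_window_bp)
    say("pprs: %d rows, min p_fdr = %.3g", nrow(tab), min(tab$p_fdr, na.rm = TRUE))
    utils::write.table(as.data.frame(tab), file.path(out_dir, "pprs_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("pprs_table.tsv")
    tab
  })

  report <- data.frame(
    stage = c("epi", "ldsc", "prs_min_p", "pprs_min_p_fdr"),
    value = c(epi$regression$beta, ldsc$rg, min(prs$p, na.rm = TRUE),
              min(pprs$p_fdr, na.rm = TRUE))
  )
  utils::write.table(report, file.path(out_dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  emit("report.tsv")

  manifest <- write_manifest(out_dir, config, outputs, stage_status, t0,
                             complete = TRUE)
  invisible(manifest)
}

write_manifest <- function(out_dir, config, outputs, stage_status, t0,
                           complete) {
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  files <- file.path(out_dir, outputs)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pathprs")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    complete = complete,
    stages = stage_status,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(stats::setNames(unname(tools::md5sum(files)), outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys are exactly the arguments of [sim_config()]; unknown keys
#' are rejected with the offending name, so typos never silently fall back
#' to defaults.
#'
#' @param path YAML file.
#' @return A validated `sim_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(sim_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0L) {
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(sim_config, raw)
}
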
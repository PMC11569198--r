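# Pipeline orchestration: a validated YAML configuration drives
# simulate -> qc -> score -> associate, with per-stage input/output
# digests recorded in a run manifest so unchanged stages are skipped and
# corrupted intermediates trigger recomputation of their stage only.

config_sections <- list(
  simulation = names(formals(sim_config)),
  qc = names(formals(qc_thresholds)),
  analysis = names(formals(analysis_config)))

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes an equivalent nested list) with optional
#' sections `simulation`, `qc` and `analysis`, fills every documented
#' default (the QC defaults are the published thresholds), and rejects
#' unknown sections or keys by name and out-of-range values with
#' field-named messages.  An empty configuration yields the full
#' default set.
#'
#' @param config Path to a YAML file, a nested list, or `NULL` for all
#'   defaults.
#' @return List with validated `simulation`, `qc` and `analysis`
#'   configuration objects.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_structural("config file not found: ", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  config <- config %||% list()
  unknown_sec <- setdiff(names(config), names(config_sections))
  if (length(unknown_sec))
    stop_invalid("unknown config sections: ",
                 paste(unknown_sec, collapse = ", "))
  built <- list()
  ctors <- list(simulation = sim_config, qc = qc_thresholds,
                analysis = analysis_config)
  for (sec in names(config_sections)) {
    given <- config[[sec]] %||% list()
    unknown <- setdiff(names(given), config_sections[[sec]])
    if (length(unknown))
      stop_invalid("unknown keys in section '", sec, "': ",
                   paste(unknown, collapse = ", "))
    given <- lapply(given, function(v) if (is.list(v)) unlist(v) else v)
    built[[sec]] <- do.call(ctors[[sec]], given)
  }
  built
}

digest_of <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

file_digests <- function(paths) {
  ok <- file.exists(paths)
  d <- rep(NA_character_, length(paths))
  d[ok] <- unname(tools::md5sum(paths[ok]))
  stats::setNames(d, basename(paths))
}

stage_current <- function(manifest, stage, input_digest, outputs) {
  st <- manifest$stages[[stage]]
  if (is.null(st)) return(FALSE)
  if (!identical(st$input_digest, input_digest)) return(FALSE)
  cur <- file_digests(outputs)
  identical(as.list(cur), as.list(st$outputs))
}

#' Run the full synthetic-study pipeline
#'
#' Executes simulate, qc, score and associate in order under a validated
#' configuration, writing every interchange file plus a human-readable
#' report into `out_dir` and a run manifest
#' (`run_manifest.json`) with per-stage digests.  A rerun with unchanged
#' configuration and intact files performs zero recomputation; a
#' corrupted intermediate is detected by digest mismatch and only its
#' stage is redone.
#'
#' @param config Path to a YAML config, a nested list, or `NULL`.
#' @param out_dir Artifact directory.
#' @param seed Optional override of the simulation seed.
#' @param force Recompute all stages regardless of digests.
#' @param quiet Suppress per-stage log lines.
#' @param upto Last stage to execute (`"simulate"`, `"qc"`, `"score"` or
#'   `"associate"`).
#' @return The run manifest, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL, force = FALSE,
                         quiet = FALSE,
                         upto = c("associate", "simulate", "qc", "score")) {
  upto <- match.arg(upto)
  stage_rank <- c(simulate = 1L, qc = 2L, score = 3L, associate = 4L)
  upto_rank <- stage_rank[[upto]]
  cfg <- validate_config(config)
  if (!is.null(seed)) {
    sim <- unclass(cfg$simulation)
    sim$seed <- as.integer(seed)
    cfg$simulation <- do.call(sim_config, sim[names(formals(sim_config))])
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  mpath <- file.path(out_dir, "run_manifest.json")
  manifest <- if (file.exists(mpath) && !force)
    jsonlite::read_json(mpath, simplifyVector = FALSE)
  else list(stages = list())
  manifest$package_version <- as.character(utils::packageVersion("crossprs"))
  manifest$seed <- cfg$simulation$seed
  manifest$config <- lapply(cfg, unclass)
  log_line <- function(...) if (!quiet) message(sprintf(...))
  recomputed <- character()

  run_stage <- function(stage, input_digest, outputs, fn) {
    if (stage_rank[[stage]] > upto_rank) return(invisible(NULL))
    if (!force && stage_current(manifest, stage, input_digest, outputs)) {
      log_line("[%s] up to date, skipped", stage)
      return(invisible(NULL))
    }
    log_line("[%s] running", stage)
    fn()
    manifest$stages[[stage]] <<- list(
      input_digest = input_digest,
      outputs = as.list(file_digests(outputs)),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    recomputed <<- c(recomputed, stage)
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }

  fx <- function(...) file.path(out_dir, ...)
  fixture_files <- fx(c("genotypes.vcf", "genotypes.dosage.tsv",
                        "variants.bim", "phenotypes.tsv", "manifest.json",
                        "sumstats_SCZ.tsv", "sumstats_BPD.tsv",
                        "sumstats_SCZplusBPD.tsv", "sumstats_SCZvsBPD.tsv"))
  run_stage("simulate", digest_of(unclass(cfg$simulation)), fixture_files,
            function() {
              study <- simulate_study(cfg$simulation)
              write_fixture(study, out_dir)
              log_line("[simulate] n = %d samples, m = %d variants",
                       cfg$simulation$n_target, cfg$simulation$m_variants)
            })

  qc_out <- fx(c("kept_variants.txt", "kept_samples.txt", "ibd.tsv",
                 "qc_ledger.json"))
  qc_in <- digest_of(list(th = unclass(cfg$qc),
                          files = file_digests(fixture_files[2:4])))
  run_stage("qc", qc_in, qc_out, function() {
    fixture <- read_fixture(out_dir)
    qc <- run_qc(fixture$genotypes, cfg$qc)
    writeLines(qc$kept_variants, fx("kept_variants.txt"))
    writeLines(qc$kept_samples, fx("kept_samples.txt"))
    if (!is.null(qc$ibd)) {
      data.table::fwrite(qc$ibd, fx("ibd.tsv"), sep = "\t")
    } else writeLines("ID1\tID2\tZ0\tZ1\tZ2\tPI_HAT", fx("ibd.tsv"))
    write_ledger_json(qc$ledgers, fx("qc_ledger.json"))
    for (sc in c("variant", "sample")) {
      e <- qc$ledgers[[sc]]$entries
      for (i in seq_len(nrow(e)))
        log_line("[qc] %s %-18s removed %6d, remaining %d", sc,
                 e$filter[i], e$removed[i], e$remaining[i])
    }
  })

  score_out <- fx(c("scores.tsv", "split_SCZ.tsv", "split_BPD.tsv"))
  score_in <- digest_of(list(files = file_digests(c(fixture_files[c(2, 3, 6:9)],
                                                    qc_out[1:2]))))
  run_stage("score", score_in, score_out, function() {
    fixture <- read_fixture(out_dir)
    kept_v <- readLines(fx("kept_variants.txt"))
    kept_s <- readLines(fx("kept_samples.txt"))
    geno <- fixture$genotypes
    jj <- match(kept_v, geno$variants$id)
    geno$dosage <- geno$dosage[kept_s, jj, drop = FALSE]
    geno$variants <- geno$variants[jj, , drop = FALSE]
    ws <- lapply(fixture$sumstats, derive_weights)
    aligned <- lapply(ws, function(w) align_weights(w, geno$variants)$weights)
    profile <- build_all_profiles(geno, aligned[["SCZ"]], aligned[["BPD"]],
                                  aligned[["SCZ+BPD"]],
                                  aligned[["SCZvsBPD"]])
    write_scores(profile, fx("scores.tsv"))
    write_split_report(profile$splits$SCZ, fx("split_SCZ.tsv"))
    write_split_report(profile$splits$BPD, fx("split_BPD.tsv"))
    log_line("[score] %d samples scored on %s",
             nrow(profile$raw),
             paste(profile$n_variants, collapse = "/"))
  })

  assoc_out <- fx(c("results.tsv", "correlations.tsv", "disease_table.tsv",
                    "analysis_ledger.json", "report.md"))
  assoc_in <- digest_of(list(an = unclass(cfg$analysis),
                             files = file_digests(c(fixture_files[4],
                                                    qc_out[2],
                                                    score_out[1]))))
  run_stage("associate", assoc_in, assoc_out, function() {
    kept_s <- readLines(fx("kept_samples.txt"))
    cohort <- read_tsv_checked(fx("phenotypes.tsv"))
    cohort <- cohort[cohort$IID %in% kept_s, , drop = FALSE]
    profile <- read_scores(fx("scores.tsv"))
    suite <- run_model_suite(profile, cohort, cfg$analysis)
    cmat <- prs_correlations(profile, cohort)
    dtab <- disease_prs_table(profile, cohort, cfg$analysis)
    write_results(suite$results, fx("results.tsv"))
    write_correlations(cmat, fx("correlations.tsv"))
    write_results(dtab, fx("disease_table.tsv"))
    write_ledger_json(suite$ledgers, fx("analysis_ledger.json"))
    write_report(fx("report.md"), cfg, suite, cmat, dtab)
    log_line("[associate] %d result rows across %d outcomes",
             nrow(suite$results), length(unique(suite$results$OUTCOME)))
  })

  manifest$recomputed_stages <- recomputed
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read a score TSV back into a `prs_profile`
#'
#' @param path Path written by [write_scores()].
#' @return A `prs_profile` (raw/z matrices, variant counts).
#' @export
read_scores <- function(path) {
  long <- read_tsv_checked(path)
  labs <- unique(long$LABEL)
  ids <- unique(long$IID)
  raw <- z <- matrix(NA_real_, length(ids), length(labs),
                     dimnames = list(ids, labs))
  for (lab in labs) {
    sub <- long[long$LABEL == lab, ]
    raw[sub$IID, lab] <- sub$RAW
    z[sub$IID, lab] <- sub$Z
  }
  nv <- vapply(labs, function(lab)
    long$N_VARIANTS[match(lab, long$LABEL)], 0L)
  structure(list(raw = raw, z = z,
                 n_variants = stats::setNames(as.integer(nv), labs),
                 norms = NULL, splits = NULL),
            class = "prs_profile")
}

fmt_or <- function(e, lo, hi) {
  ifelse(is.na(e), "-", sprintf("%.3f (%.3f-%.3f)", e, lo, hi))
}

write_report <- function(path, cfg, suite, cmat, dtab) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  an <- cfg$analysis
  w("# Synthetic cross-disorder PRS study report\n")
  w("Seed %d; %d target samples, %d variants.\n",
    cfg$simulation$seed, cfg$simulation$n_target, cfg$simulation$m_variants)
  w("QC thresholds: variant missingness > %.3g, MAF < %.3g, HWE p < %.3g, info < %.2g; sample missingness > %.3g, heterozygosity +/- %g SD, PI-HAT > %.4g.\n",
    cfg$qc$variant_missing_max, cfg$qc$maf_min, cfg$qc$hwe_p_min,
    cfg$qc$info_min, cfg$qc$sample_missing_max, cfg$qc$het_sd_bound,
    cfg$qc$pihat_max)
  w("Significance: overall alpha %.3g over %d model families; Bonferroni-corrected level %.3g/%d = %.4g.\n",
    an$alpha_overall, an$n_models, an$alpha_overall, an$n_models,
    an$alpha_bonferroni)
  w("## Disease prediction (per score)\n")
  w("| Outcome | PRS | OR | p | delta Nagelkerke R2 |")
  w("|---|---|---|---|---|")
  for (i in seq_len(nrow(dtab))) {
    r <- dtab[i, ]
    w("| %s | %s | %s | %.3g | %.4f%% |", r$OUTCOME, r$MODEL,
      fmt_or(r$EFFECT, r$CI_LO, r$CI_HI), r$P,
      100 * r$DELTA_R2_NAGELKERKE)
  }
  w("\n## Model suite\n")
  w("| Outcome | Model | Predictor | N | Effect (95%% CI) | p | Tier |")
  w("|---|---|---|---|---|---|---|")
  res <- suite$results
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    w("| %s | %s | %s | %d | %s | %.3g | %s |", r$OUTCOME, r$MODEL,
      r$PREDICTOR, r$N, fmt_or(r$EFFECT, r$CI_LO, r$CI_HI), r$P, r$TIER)
  }
  w("\n## Inter-PRS correlations (no SCZ / no BPD subsample)\n")
  w("| | %s |", paste(colnames(cmat), collapse = " | "))
  w("|%s|", paste(rep("---", ncol(cmat) + 1L), collapse = "|"))
  for (i in seq_len(nrow(cmat))) {
    w("| %s | %s |", rownames(cmat)[i],
      paste(sprintf("%.2f", cmat[i, ]), collapse = " | "))
  }
  invisible(path)
}
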
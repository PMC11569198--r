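#' Simulation configuration
#'
#' Parameters of the synthetic study: a target cohort genotyped at
#' `m_variants` independent biallelic variants, two liability-threshold
#' disorders (SCZ and BPD) with a shared polygenic component inducing a
#' positive genetic correlation, four discovery GWAS designs producing
#' summary statistics with sampling noise, and downstream phenotypes
#' (5-level ordinal education, baseline MMSE in the over-60 subsample,
#' MMSE change at follow-up) loaded on the shared and disorder-specific
#' genetic components.
#'
#' Discovery sample sizes default to the published discovery-GWAS
#' designs: SCZ
#' 67,390 cases / 94,015 controls; BPD 41,917 / 371,549; combined-phenotype
#' SCZ+BPD 53,555 cases / 54,065 controls; case-only contrast 23,585 SCZ
#' vs 15,270 BPD cases.  Disorder prevalences default to roughly the
#' self-reported rates in a community biobank (0.2% SCZ, 0.7% BPD).
#'
#' @param n_target Target-cohort sample count.
#' @param n_discovery_scz,n_discovery_bpd,n_discovery_combined Length-2
#'   vectors `c(cases, controls)` for the case-control discovery designs.
#' @param n_discovery_caseonly Length-2 vector `c(n_scz_cases, n_bpd_cases)`
#'   for the SCZ-vs-BPD case-only contrast.
#' @param m_variants Number of biallelic variants.
#' @param maf_range Allele-frequency bounds, within (0, 0.5].
#' @param h2_shared,h2_scz_specific,h2_bpd_specific Liability-scale variance
#'   fractions of the shared and disorder-specific polygenic components.
#' @param prevalence_scz,prevalence_bpd Population prevalences, in (0, 0.5).
#' @param causal_fraction Fraction of variants with nonzero effects.
#' @param missing_rate Genotype missingness injected per entry (imputed
#'   dosage data are complete, so the default is 0; QC tests raise it).
#' @param edu_loadings,mmse_loadings,mmse_change_loadings Signed weights of
#'   the standardized (shared, SCZ-specific, BPD-specific) genetic
#'   components on each phenotype's latent scale.
#' @param edu_props Marginal proportions of the five retained education
#'   levels (elementary ... master and above).
#' @param edu_special_probs Probabilities of the illiterate / self-study /
#'   missing education codes, assigned independently of the latent scale.
#' @param noise_sds Named residual SDs: `edu` (latent-scale), `mmse`
#'   (points), `mmse_change` (points).
#' @param mmse_mean Baseline MMSE latent mean before clamping to 0-30.
#' @param followup_fraction Fraction of the MMSE subsample with a
#'   follow-up measurement.
#' @param followup_years Mean and SD of follow-up duration in years
#'   (normal truncated at zero).
#' @param prop_female,prop_batch1 Covariate mixture proportions.
#' @param seed Integer master seed; identical configuration and seed
#'   reproduce byte-identical output.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_target = 50000L,
                       n_discovery_scz = c(67390L, 94015L),
                       n_discovery_bpd = c(41917L, 371549L),
                       n_discovery_combined = c(53555L, 54065L),
                       n_discovery_caseonly = c(23585L, 15270L),
                       m_variants = 1000L,
                       maf_range = c(0.01, 0.5),
                       h2_shared = 0.3,
                       h2_scz_specific = 0.1,
                       h2_bpd_specific = 0.1,
                       prevalence_scz = 0.002,
                       prevalence_bpd = 0.007,
                       causal_fraction = 1.0,
                       missing_rate = 0,
                       edu_loadings = c(shared = 0.10, scz = -0.06, bpd = 0.02),
                       mmse_loadings = c(shared = -0.02, scz = -0.10, bpd = 0.10),
                       mmse_change_loadings = c(shared = 0, scz = -0.25, bpd = 0),
                       edu_props = c(0.044, 0.071, 0.291, 0.481, 0.113),
                       edu_special_probs = c(illiterate = 124 / 105919,
                                             self_study = 56 / 105919,
                                             missing = 29 / 105919),
                       noise_sds = c(edu = 1, mmse = 3.8, mmse_change = 3.4),
                       mmse_mean = 27.6,
                       followup_fraction = 6194 / 27005,
                       followup_years = c(mean = 3.9, sd = 1.1),
                       prop_female = 0.635,
                       prop_batch1 = 27716 / 131048,
                       seed = 42L) {
  cfg <- list(
    n_target = as.integer(n_target),
    n_discovery_scz = as.integer(n_discovery_scz),
    n_discovery_bpd = as.integer(n_discovery_bpd),
    n_discovery_combined = as.integer(n_discovery_combined),
    n_discovery_caseonly = as.integer(n_discovery_caseonly),
    m_variants = as.integer(m_variants),
    maf_range = as.numeric(maf_range),
    h2_shared = h2_shared,
    h2_scz_specific = h2_scz_specific,
    h2_bpd_specific = h2_bpd_specific,
    prevalence_scz = prevalence_scz,
    prevalence_bpd = prevalence_bpd,
    causal_fraction = causal_fraction,
    missing_rate = missing_rate,
    edu_loadings = edu_loadings,
    mmse_loadings = mmse_loadings,
    mmse_change_loadings = mmse_change_loadings,
    edu_props = edu_props,
    edu_special_probs = edu_special_probs,
    noise_sds = noise_sds,
    mmse_mean = mmse_mean,
    followup_fraction = followup_fraction,
    followup_years = followup_years,
    prop_female = prop_female,
    prop_batch1 = prop_batch1,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_target < 2L) stop_invalid("n_target must be >= 2")
  if (cfg$m_variants < 1L) stop_invalid("m_variants must be >= 1")
  for (f in c("n_discovery_scz", "n_discovery_bpd", "n_discovery_combined",
              "n_discovery_caseonly")) {
    if (length(cfg[[f]]) != 2L || any(cfg[[f]] <= 0L))
      stop_invalid(f, " must be two positive counts")
  }
  mr <- cfg$maf_range
  if (length(mr) != 2L || mr[1] > mr[2] || mr[1] <= 0 || mr[2] > 0.5)
    stop_invalid("maf_range must be ordered bounds within (0, 0.5]")
  h2 <- c(cfg$h2_shared, cfg$h2_scz_specific, cfg$h2_bpd_specific)
  if (any(h2 < 0) || any(h2 > 1))
    stop_invalid("heritability fractions must lie in [0, 1]")
  if (cfg$h2_shared + cfg$h2_scz_specific > 1 ||
      cfg$h2_shared + cfg$h2_bpd_specific > 1)
    stop_invalid("h2_shared + disorder-specific h2 must not exceed 1")
  for (f in c("prevalence_scz", "prevalence_bpd")) {
    if (cfg[[f]] <= 0 || cfg[[f]] >= 0.5)
      stop_invalid(f, " must lie in (0, 0.5)")
  }
  if (cfg$causal_fraction < 0 || cfg$causal_fraction > 1)
    stop_invalid("causal_fraction must lie in [0, 1]")
  if (cfg$causal_fraction == 0 && sum(h2) > 0)
    stop_invalid("causal_fraction = 0 is incompatible with nonzero h2")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop_invalid("missing_rate must lie in [0, 1)")
  for (f in c("edu_loadings", "mmse_loadings", "mmse_change_loadings")) {
    if (length(cfg[[f]]) != 3L)
      stop_invalid(f, " must have 3 entries (shared, scz, bpd)")
  }
  if (length(cfg$edu_props) != 5L || any(cfg$edu_props <= 0) ||
      abs(sum(cfg$edu_props) - 1) > 0.02)
    stop_invalid("edu_props must be 5 positive proportions summing to ~1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  target cohort: n = %d, m = %d variants, MAF in [%.3g, %.3g]\n",
              x$n_target, x$m_variants, x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  architecture: h2 shared %.2f, SCZ-specific %.2f, BPD-specific %.2f, causal fraction %.2f\n",
              x$h2_shared, x$h2_scz_specific, x$h2_bpd_specific, x$causal_fraction))
  cat(sprintf("  prevalence: SCZ %.3g, BPD %.3g; seed %d\n",
              x$prevalence_scz, x$prevalence_bpd, x$seed))
  invisible(x)
}

#' Quality-control thresholds
#'
#' Defaults are the thresholds applied to the study cohort: variant call
#' rate (variants with a missing fraction above 5% are dropped), minor
#' allele frequency below 0.001, Hardy-Weinberg exact-test p below 1e-5,
#' imputation info below 0.7, per-sample missing rate above 2%,
#' heterozygosity beyond 5 SD of the cohort mean, and PI-HAT above 0.1875
#' (the midpoint between second- and third-degree relative expectations)
#' for relatedness pruning.  Duplicate detection uses PI-HAT > `dup_pihat`.
#'
#' @param variant_missing_max,maf_min,hwe_p_min,info_min Variant filters.
#' @param sample_missing_max,het_sd_bound Sample filters.
#' @param pihat_max Relatedness pruning threshold.
#' @param dup_pihat PI-HAT above which a pair is booked as a duplicate.
#' @return Object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(variant_missing_max = 0.05,
                          maf_min = 0.001,
                          hwe_p_min = 1e-5,
                          info_min = 0.7,
                          sample_missing_max = 0.02,
                          het_sd_bound = 5,
                          pihat_max = 0.1875,
                          dup_pihat = 0.95) {
  th <- list(variant_missing_max = variant_missing_max, maf_min = maf_min,
             hwe_p_min = hwe_p_min, info_min = info_min,
             sample_missing_max = sample_missing_max,
             het_sd_bound = het_sd_bound, pihat_max = pihat_max,
             dup_pihat = dup_pihat)
  for (f in c("variant_missing_max", "sample_missing_max")) {
    if (th[[f]] < 0 || th[[f]] > 1) stop_invalid(f, " must lie in [0, 1]")
  }
  if (th$maf_min < 0 || th$maf_min > 0.5)
    stop_invalid("maf_min must lie in [0, 0.5]")
  if (th$hwe_p_min < 0 || th$hwe_p_min > 1)
    stop_invalid("hwe_p_min must lie in [0, 1]")
  if (th$info_min < 0 || th$info_min > 1)
    stop_invalid("info_min must lie in [0, 1]")
  if (th$het_sd_bound <= 0) stop_invalid("het_sd_bound must be positive")
  if (th$pihat_max < 0 || th$pihat_max > 1)
    stop_invalid("pihat_max must lie in [0, 1]")
  if (th$dup_pihat < th$pihat_max || th$dup_pihat > 1)
    stop_invalid("dup_pihat must lie in [pihat_max, 1]")
  structure(th, class = "qc_thresholds")
}

#' Association analysis configuration
#'
#' The overall significance level is split over the four model families
#' (independent, shared, SCZ-specific, split), so the Bonferroni-corrected
#' level is `alpha_overall / 4`.  Cognitive deficit is defined as MMSE
#' strictly below `mmse_deficit_cutoff`.
#'
#' @param alpha_overall Family-wise significance level.
#' @param n_models Number of model families tested.
#' @param mmse_deficit_cutoff MMSE cutoff; scores strictly below count as
#'   cognitive deficit.
#' @param model1_joint Fit the SCZ and BPD scores jointly in Model 1
#'   (`TRUE`, the default) or in separate regressions.
#' @param n_pcs Number of population-stratification covariates.
#' @return Object of class `analysis_config`; `alpha_bonferroni` is
#'   derived as `alpha_overall / n_models`.
#' @export
analysis_config <- function(alpha_overall = 0.05, n_models = 4L,
                            mmse_deficit_cutoff = 24,
                            model1_joint = TRUE, n_pcs = 20L) {
  if (alpha_overall <= 0 || alpha_overall >= 1)
    stop_invalid("alpha_overall must lie in (0, 1)")
  if (n_models < 1L) stop_invalid("n_models must be >= 1")
  structure(list(alpha_overall = alpha_overall,
                 n_models = as.integer(n_models),
                 alpha_bonferroni = alpha_overall / n_models,
                 mmse_deficit_cutoff = mmse_deficit_cutoff,
                 model1_joint = isTRUE(model1_joint),
                 n_pcs = as.integer(n_pcs)),
            class = "analysis_config")
}
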
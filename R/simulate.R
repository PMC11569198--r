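# Synthetic-study generator: independent biallelic variants, a bivariate
# shared/specific polygenic architecture on the liability scale, discovery
# summary statistics with first-two-moment-correct sampling noise, and
# downstream cohort phenotypes.  No linkage disequilibrium is simulated:
# additive per-variant scoring makes all oracles closed-form without it.

# Strand-unambiguous allele pairs only (A/T and C/G never emitted), so the
# generator mirrors a post-QC imputation panel and alignment never has to
# discard its own fixtures.
.allele_pairs <- matrix(c("A","C", "A","G", "C","A", "C","T",
                          "G","A", "G","T", "T","C", "T","G"),
                        ncol = 2L, byrow = TRUE)

# Variant panel shared by every cohort drawn from one configuration:
# chromosome, position, id, alleles and true allele frequency are all
# deterministic functions of the config seed.
simulate_variant_panel <- function(config) {
  m <- config$m_variants
  with_seed(seed_for(config$seed, "panel"), {
    freq <- runif(m, config$maf_range[1], config$maf_range[2])
    chrom <- sort(sample(1:22, m, replace = TRUE))
    pos <- unlist(lapply(split(seq_len(m), chrom), function(ix) {
      cumsum(sample(1000:20000, length(ix), replace = TRUE))
    }), use.names = FALSE)
    pair <- sample(nrow(.allele_pairs), m, replace = TRUE)
    data.frame(chrom = chrom, id = paste0("v", seq_len(m)), cm = 0,
               pos = pos, a1 = .allele_pairs[pair, 1L],
               a2 = .allele_pairs[pair, 2L], freq = freq,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a genotype dosage matrix
#'
#' Dosages of the effect allele (A1) are drawn per variant as
#' binomial(2, freq) with the variant panel and its allele frequencies
#' synthesized deterministically from the configuration seed; optional
#' missingness is injected completely at random at `config$missing_rate`.
#'
#' @param config A [sim_config()].
#' @param n Number of samples (defaults to `config$n_target`).
#' @param label Cohort name; prefixes sample ids and seeds the cohort's
#'   RNG stream, so different labels give independent cohorts.
#' @return A `genotype_matrix`: list with `dosage` (samples x variants,
#'   `NA` for missing), `variants` (panel data frame) and `label`.
#' @export
simulate_genotypes <- function(config, n = config$n_target, label = "target") {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop_invalid("n must be >= 2")
  if (config$m_variants < 1L) stop_invalid("m_variants must be >= 1")
  panel <- simulate_variant_panel(config)
  m <- nrow(panel)
  dosage <- matrix(NA_real_, n, m)
  with_seed(seed_for(config$seed, paste0("geno:", label, ":", n)), {
    for (j in seq_len(m)) {
      g <- rbinom(n, 2L, panel$freq[j])
      if (config$missing_rate > 0) {
        g[runif(n) < config$missing_rate] <- NA_integer_
      }
      dosage[, j] <- g
    }
  })
  rownames(dosage) <- sprintf("%s_%06d", label, seq_len(n))
  colnames(dosage) <- panel$id
  new_genotype_matrix(dosage, panel, label)
}

new_genotype_matrix <- function(dosage, variants, label = "cohort") {
  stopifnot(ncol(dosage) == nrow(variants))
  structure(list(dosage = dosage, variants = variants, label = label),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix '%s': %d samples x %d variants (%.3g%% missing)\n",
              x$label, nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Simulate the true bivariate genetic architecture
#'
#' Causal variants receive shared, SCZ-specific and BPD-specific effects
#' drawn independently from zero-mean normals on the standardized-genotype
#' scale, scaled so the liability-scale variance contributed by each
#' component matches the configured fractions.  The per-variant trait
#' effects are exact sums: SCZ effect = shared + SCZ-specific, and
#' likewise for BPD; non-causal variants are exactly zero in every
#' component.
#'
#' @param config A [sim_config()].
#' @param replicate Integer; change to draw an independent architecture
#'   over the same variant panel.
#' @return A `true_architecture`: variant panel plus per-variant `shared`,
#'   `scz_specific`, `bpd_specific`, `beta_scz`, `beta_bpd` and the
#'   `causal` indicator.
#' @export
simulate_effects <- function(config, replicate = 1L) {
  validate_sim_config(config)
  panel <- simulate_variant_panel(config)
  m <- nrow(panel)
  m_causal <- max(0L, round(config$causal_fraction * m))
  h2 <- c(config$h2_shared, config$h2_scz_specific, config$h2_bpd_specific)
  if (m_causal == 0L && sum(h2) > 0)
    stop_invalid("causal_fraction = 0 is incompatible with nonzero h2")
  shared <- scz_spec <- bpd_spec <- numeric(m)
  with_seed(seed_for(config$seed, paste0("effects:", replicate)), {
    causal <- rep(FALSE, m)
    causal[sample(m, m_causal)] <- TRUE
    if (m_causal > 0L) {
      shared[causal]   <- rnorm(m_causal, 0, sqrt(config$h2_shared / m_causal))
      scz_spec[causal] <- rnorm(m_causal, 0, sqrt(config$h2_scz_specific / m_causal))
      bpd_spec[causal] <- rnorm(m_causal, 0, sqrt(config$h2_bpd_specific / m_causal))
    }
    structure(list(variants = panel, causal = causal, shared = shared,
                   scz_specific = scz_spec, bpd_specific = bpd_spec,
                   beta_scz = shared + scz_spec,
                   beta_bpd = shared + bpd_spec,
                   config = config),
              class = "true_architecture")
  })
}

#' @export
print.true_architecture <- function(x, ...) {
  cat(sprintf("true_architecture: %d variants (%d causal), h2 shared %.2f / SCZ %.2f / BPD %.2f\n",
              nrow(x$variants), sum(x$causal), x$config$h2_shared,
              x$config$h2_scz_specific, x$config$h2_bpd_specific))
  invisible(x)
}

# Per-sample genetic component values G_std %*% effects, computed without
# materializing a standardized copy of the dosage matrix.  Missing dosages
# are replaced by their expectation 2f.
genetic_components <- function(geno, arch) {
  if (!identical(geno$variants$id, arch$variants$id))
    stop_structural("genotype and architecture variant sets differ")
  f <- arch$variants$freq
  s <- sqrt(2 * f * (1 - f))
  X <- geno$dosage
  w <- cbind(shared = arch$shared / s,
             scz_specific = arch$scz_specific / s,
             bpd_specific = arch$bpd_specific / s)
  if (anyNA(X)) {
    # column-wise mean imputation restricted to columns with missingness
    X <- X[, , drop = FALSE]
    nas <- which(colSums(is.na(X)) > 0L)
    for (j in nas) X[is.na(X[, j]), j] <- 2 * f[j]
  }
  comp <- X %*% w
  offset <- colSums(2 * f * w)
  sweep(comp, 2L, offset, "-")
}

#' Simulate disease status under the liability-threshold model
#'
#' Liability is the genetic value (standardized genotypes times true
#' effects) plus an independent normal residual scaled so the total
#' liability variance is 1; a sample is a case iff its liability exceeds
#' the normal quantile implied by the configured prevalence.
#'
#' @param geno A `genotype_matrix`.
#' @param arch A `true_architecture` over the same variants.
#' @param config The [sim_config()].
#' @param replicate Integer; change for an independent residual draw.
#' @return List with logical `scz` and `bpd` case indicators, the two
#'   liabilities, and the per-sample genetic `components` matrix
#'   (shared, scz_specific, bpd_specific).
#' @export
simulate_disease <- function(geno, arch, config, replicate = 1L) {
  comp <- genetic_components(geno, arch)
  n <- nrow(comp)
  h2_scz <- config$h2_shared + config$h2_scz_specific
  h2_bpd <- config$h2_shared + config$h2_bpd_specific
  res_scz <- sqrt(max(0, 1 - h2_scz))
  res_bpd <- sqrt(max(0, 1 - h2_bpd))
  # rescale each realized genetic value to its configured liability-scale
  # SD so the total liability variance is 1 and the threshold quantile
  # yields the configured prevalence even at modest variant counts
  rescale <- function(g, h2) {
    s <- stats::sd(g)
    if (s > 0 && h2 > 0) (g - mean(g)) * sqrt(h2) / s else g * 0
  }
  g_scz <- rescale(comp[, "shared"] + comp[, "scz_specific"], h2_scz)
  g_bpd <- rescale(comp[, "shared"] + comp[, "bpd_specific"], h2_bpd)
  with_seed(seed_for(config$seed,
                     paste0("disease:", geno$label, ":", n, ":", replicate)), {
    liab_scz <- g_scz + rnorm(n, 0, res_scz)
    liab_bpd <- g_bpd + rnorm(n, 0, res_bpd)
    list(scz = liab_scz > qnorm(1 - config$prevalence_scz),
         bpd = liab_bpd > qnorm(1 - config$prevalence_bpd),
         liability_scz = liab_scz, liability_bpd = liab_bpd,
         components = comp)
  })
}

.contrast_labels <- c("SCZ", "BPD", "SCZ+BPD", "SCZvsBPD")

#' Simulate discovery GWAS summary statistics
#'
#' Per-variant effect estimates are the true contrast effect on the
#' per-allele log-odds scale plus normal noise with the standard error of
#' the contrast design: standard case-control GWAS for SCZ and BPD, a
#' combined-phenotype cases-vs-controls GWAS for SCZ+BPD, and a case-only
#' SCZ-vs-BPD difference (in which the shared component cancels exactly).
#' `se = 1/sqrt(2 f (1-f) N_eff)` with `N_eff = 4/(1/n1 + 1/n2)`, so
#' doubling both group sizes shrinks every standard error by exactly
#' `1/sqrt(2)`, and the estimates are unbiased by construction.
#'
#' @param arch A `true_architecture`.
#' @param config The [sim_config()].
#' @param contrast One of `"SCZ"`, `"BPD"`, `"SCZ+BPD"`, `"SCZvsBPD"`.
#' @param replicate Integer; change to draw an independent noise
#'   realization of the same discovery design.
#' @return A data.frame with columns CHR, POS, SNP, A1, A2, FRQ, BETA,
#'   SE, P, N and attribute `label` set to the contrast.
#' @export
simulate_discovery_sumstats <- function(arch, config, contrast,
                                        replicate = 1L) {
  if (!contrast %in% .contrast_labels)
    stop_invalid("unknown contrast label: ", contrast)
  panel <- arch$variants
  f <- panel$freq
  s <- sqrt(2 * f * (1 - f))
  sizes <- switch(contrast,
    "SCZ" = config$n_discovery_scz,
    "BPD" = config$n_discovery_bpd,
    "SCZ+BPD" = config$n_discovery_combined,
    "SCZvsBPD" = config$n_discovery_caseonly)
  if (any(sizes <= 0)) stop_invalid("discovery sample sizes must be positive")
  beta_std <- switch(contrast,
    "SCZ" = arch$beta_scz,
    "BPD" = arch$beta_bpd,
    # combined phenotype: case mixture of the two disorders, weighted by
    # each disorder's share of the combined case group
    "SCZ+BPD" = {
      wts <- config$n_discovery_caseonly / sum(config$n_discovery_caseonly)
      wts[1] * arch$beta_scz + wts[2] * arch$beta_bpd
    },
    "SCZvsBPD" = arch$beta_scz - arch$beta_bpd)
  b_allele <- beta_std / s
  n_eff <- 4 / (1 / sizes[1] + 1 / sizes[2])
  se <- 1 / sqrt(2 * f * (1 - f) * n_eff)
  est <- with_seed(
    seed_for(config$seed, paste0("sumstats:", contrast, ":", replicate)),
    b_allele + rnorm(length(se), 0, se))
  p <- pmax(2 * pnorm(-abs(est / se)), 1e-320)
  out <- data.frame(CHR = panel$chrom, POS = panel$pos, SNP = panel$id,
                    A1 = panel$a1, A2 = panel$a2, FRQ = f,
                    BETA = est, SE = se, P = p, N = sum(sizes),
                    stringsAsFactors = FALSE)
  attr(out, "label") <- contrast
  out
}

#' Simulate the target-cohort phenotype table
#'
#' Age is uniform on 30-70 (the biobank recruitment window); sex, chip
#' batch and 20 ancillary stratification covariates are synthesized.
#' Latent education is a linear function of the standardized (shared,
#' SCZ-specific, BPD-specific) genetic components plus noise, cut into 5
#' ordered levels at the configured marginal proportions, with small
#' independent probabilities of the illiterate / self-study / missing
#' codes.  Baseline MMSE is defined only for samples aged 60 or over, as
#' an integer clamped to 0-30; a configured subsample receives a
#' follow-up MMSE with duration normal(3.9, 1.1) truncated positive.
#'
#' @param geno,arch,disease,config As produced by the companion
#'   simulators.
#' @param replicate Integer; change for an independent phenotype draw.
#' @return A cohort data.frame keyed by `IID` with demographics, disease
#'   indicators, education, MMSE columns and PC covariates.
#' @export
simulate_phenotypes <- function(geno, arch, disease, config,
                                replicate = 1L) {
  comp <- disease$components
  n <- nrow(comp)
  if (length(disease$scz) != n) stop_structural("sample sets inconsistent")
  # standardize components empirically; a zero-variance component (h2 = 0)
  # stays identically zero so its loading is inert
  compz <- apply(comp, 2L, function(v) {
    s <- stats::sd(v)
    if (s > 0) (v - mean(v)) / s else v * 0
  })
  with_seed(seed_for(config$seed,
                     paste0("pheno:", geno$label, ":", n, ":", replicate)), {
    age <- runif(n, 30, 70)
    sex <- ifelse(runif(n) < config$prop_female, "F", "M")
    batch <- ifelse(runif(n) < config$prop_batch1, "v1", "v2")
    birth_year <- 2015 - age
    birth_cohort <- cut(birth_year, c(-Inf, 1950, 1960, 1970, 1980, Inf),
                        labels = c("<1950", "1950s", "1960s", "1970s", ">=1980"),
                        right = FALSE)
    pcs <- matrix(rnorm(n * 20L), n, 20L,
                  dimnames = list(NULL, paste0("PC", 1:20)))

    lat_edu <- drop(compz %*% config$edu_loadings) +
      rnorm(n, 0, config$noise_sds[["edu"]])
    cuts <- stats::quantile(lat_edu, cumsum(config$edu_props)[1:4], type = 1)
    edu <- as.character(cut(lat_edu, c(-Inf, cuts, Inf),
                            labels = c("elementary", "junior_high",
                                       "senior_high", "university", "master")))
    sp <- config$edu_special_probs
    u <- runif(n)
    edu[u < sp[["illiterate"]]] <- "illiterate"
    edu[u >= sp[["illiterate"]] & u < sp[["illiterate"]] + sp[["self_study"]]] <-
      "self_study"
    edu[u >= sp[["illiterate"]] + sp[["self_study"]] &
        u < sum(sp)] <- NA_character_

    mmse <- rep(NA_real_, n)
    old <- age >= 60
    lat_mmse <- config$mmse_mean + drop(compz %*% config$mmse_loadings) +
      rnorm(n, 0, config$noise_sds[["mmse"]])
    mmse[old] <- pmin(30, pmax(0, round(lat_mmse[old])))

    followup <- old & runif(n) < config$followup_fraction
    dur <- rep(NA_real_, n)
    d <- rnorm(sum(followup), config$followup_years[["mean"]],
               config$followup_years[["sd"]])
    while (any(d <= 0)) {
      d[d <= 0] <- rnorm(sum(d <= 0), config$followup_years[["mean"]],
                         config$followup_years[["sd"]])
    }
    dur[followup] <- d
    mmse_fu <- rep(NA_real_, n)
    delta <- drop(compz %*% config$mmse_change_loadings) +
      rnorm(n, 0, config$noise_sds[["mmse_change"]])
    mmse_fu[followup] <- pmin(30, pmax(0, round(mmse[followup] + delta[followup])))

    data.frame(IID = rownames(geno$dosage), age = age, sex = sex,
               batch = batch, birth_cohort = birth_cohort,
               scz = as.integer(disease$scz), bpd = as.integer(disease$bpd),
               education = edu, mmse = mmse, mmse_followup = mmse_fu,
               mmse_change = mmse_fu - mmse, followup_years = dur,
               pcs, stringsAsFactors = FALSE)
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running the whole generator: variant panel, target
#' genotypes, true architecture, disease status, the four discovery
#' summary-statistic sets and the cohort phenotype table.
#'
#' @param config A [sim_config()].
#' @return List with elements `config`, `genotypes`, `architecture`,
#'   `disease`, `sumstats` (named list over the four contrasts) and
#'   `cohort`.
#' @export
simulate_study <- function(config) {
  geno <- simulate_genotypes(config, config$n_target, "target")
  arch <- simulate_effects(config)
  disease <- simulate_disease(geno, arch, config)
  sumstats <- lapply(stats::setNames(.contrast_labels, .contrast_labels),
                     function(ct) simulate_discovery_sumstats(arch, config, ct))
  cohort <- simulate_phenotypes(geno, arch, disease, config)
  list(config = config, genotypes = geno, architecture = arch,
       disease = disease, sumstats = sumstats, cohort = cohort)
}
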
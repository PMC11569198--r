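test_that("genotype dosages follow binomial(2, freq) and are reproducible", {
  cfg <- sim_config(n_target = 10000, m_variants = 40,
                    maf_range = c(0.5, 0.5), seed = 3)
  g <- simulate_genotypes(cfg, 10000, "target")
  expect_true(all(abs(colMeans(g$dosage) - 1) < 0.03))
  expect_false(anyNA(g$dosage))
  g2 <- simulate_genotypes(cfg, 10000, "target")
  expect_identical(g$dosage, g2$dosage)
  expect_identical(g$variants, g2$variants)

  cfg_na <- sim_config(n_target = 2000, m_variants = 50,
                       missing_rate = 0.05, seed = 4)
  gna <- simulate_genotypes(cfg_na, 2000, "target")
  expect_gt(mean(is.na(gna$dosage)), 0.03)
  expect_lt(mean(is.na(gna$dosage)), 0.07)
  expect_error(simulate_genotypes(cfg, n = 1), class = "crossprs_invalid_config")
})

test_that("true architecture realizes the configured shared/specific structure", {
  cfg <- sim_config(m_variants = 20000, h2_shared = 0.3,
                    h2_scz_specific = 0.1, h2_bpd_specific = 0.1,
                    causal_fraction = 1, n_target = 10, seed = 11)
  arch <- simulate_effects(cfg)
  # corr(beta_scz, beta_bpd) = h2_shared / sqrt(0.4 * 0.4) = 0.75
  expect_lt(abs(cor(arch$beta_scz, arch$beta_bpd) - 0.75), 0.04)
  expect_identical(arch$beta_scz, arch$shared + arch$scz_specific)
  expect_identical(arch$beta_bpd, arch$shared + arch$bpd_specific)

  # sign-concordance fraction equals the bivariate-normal orthant
  # probability 1/2 + asin(rho)/pi, cross-checked by Monte-Carlo
  rho <- 0.75
  set.seed(42)
  z1 <- rnorm(2e6); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(2e6)
  mc <- mean(sign(z1) == sign(z2))
  closed <- 0.5 + asin(rho) / pi
  expect_lt(abs(mc - closed), 0.002)
  obs <- mean(sign(arch$beta_scz) == sign(arch$beta_bpd))
  expect_lt(abs(obs - closed), 0.02)

  null_cfg <- sim_config(m_variants = 500, h2_shared = 0,
                         h2_scz_specific = 0, h2_bpd_specific = 0, seed = 2)
  null_arch <- simulate_effects(null_cfg)
  expect_true(all(null_arch$beta_scz == 0) && all(null_arch$beta_bpd == 0))

  part <- simulate_effects(sim_config(m_variants = 4000,
                                      causal_fraction = 0.5, seed = 5))
  expect_true(all(part$shared[!part$causal] == 0))
  expect_true(all(part$beta_scz[!part$causal] == 0))
  expect_error(sim_config(causal_fraction = 0, h2_shared = 0.3),
               class = "crossprs_invalid_config")
})

test_that("orthant concordance tracks rho across the configured range", {
  for (rho_target in c(-0.5, 0, 0.5, 0.9)) {
    # choose h2 components so that shared/(shared+specific) gives |rho|;
    # negative rho via sign-flipped shared loading is emulated by
    # comparing SCZ against the negated BPD effects
    h2s <- abs(rho_target) * 0.4
    cfg <- sim_config(m_variants = 20000, h2_shared = h2s,
                      h2_scz_specific = 0.4 - h2s,
                      h2_bpd_specific = 0.4 - h2s,
                      causal_fraction = 1, seed = 19 + round(10 * rho_target))
    arch <- simulate_effects(cfg)
    b2 <- if (rho_target < 0) -arch$beta_bpd else arch$beta_bpd
    obs <- mean(sign(arch$beta_scz) == sign(b2))
    expect_lt(abs(obs - (0.5 + asin(rho_target) / pi)), 0.02)
  }
})

test_that("liability-threshold disease status matches prevalence and selection", {
  cfg <- sim_config(n_target = 100000, m_variants = 120, seed = 8)
  g <- simulate_genotypes(cfg, 100000, "target")
  arch <- simulate_effects(cfg)
  dis <- simulate_disease(g, arch, cfg)
  k <- cfg$prevalence_scz
  expect_lt(abs(sum(dis$scz) - 100000 * k), 3 * sqrt(100000 * k * (1 - k)))
  kb <- cfg$prevalence_bpd
  expect_lt(abs(sum(dis$bpd) - 100000 * kb), 3 * sqrt(100000 * kb * (1 - kb)))

  # liability-threshold selection: cases carry more of the shared
  # component, increasingly so at higher shared h2
  gap <- vapply(c(0.1, 0.4), function(h2) {
    cfg_h <- sim_config(n_target = 100000, m_variants = 120,
                        h2_shared = h2, prevalence_scz = 0.01, seed = 8)
    d <- simulate_disease(g, simulate_effects(cfg_h), cfg_h)
    mean(d$components[d$scz, "shared"]) -
      mean(d$components[!d$scz, "shared"])
  }, 0)
  expect_gt(gap[1], 0)
  expect_gt(gap[2], gap[1])
})

test_that("discovery summary statistics are unbiased with design-scaled noise", {
  cfg <- sim_config(m_variants = 50, seed = 13)
  arch <- simulate_effects(cfg)
  ests <- vapply(1:500, function(r)
    simulate_discovery_sumstats(arch, cfg, "SCZ", replicate = r)$BETA[1], 0)
  ss1 <- simulate_discovery_sumstats(arch, cfg, "SCZ")
  s <- sqrt(2 * arch$variants$freq[1] * (1 - arch$variants$freq[1]))
  true_b <- arch$beta_scz[1] / s
  expect_lt(abs(mean(ests) - true_b), 3 * ss1$SE[1] / sqrt(500))
  expect_true(all(ss1$SE > 0) && all(ss1$P > 0) && all(ss1$P <= 1))
  expect_true(all(ss1$A1 != ss1$A2))

  # the shared component cancels exactly in the case-only contrast
  shared_cfg <- sim_config(m_variants = 200, h2_scz_specific = 0,
                           h2_bpd_specific = 0, seed = 21)
  shared_arch <- simulate_effects(shared_cfg)
  expect_identical(shared_arch$beta_scz - shared_arch$beta_bpd,
                   rep(0, 200))

  # doubling discovery N shrinks every SE by 1/sqrt(2)
  cfg2 <- sim_config(m_variants = 50, n_discovery_scz = 2 * cfg$n_discovery_scz,
                     seed = 13)
  ss2 <- simulate_discovery_sumstats(simulate_effects(cfg2), cfg2, "SCZ")
  expect_true(all(abs(ss2$SE / ss1$SE - 1 / sqrt(2)) < 0.02 / sqrt(2)))
  expect_error(simulate_discovery_sumstats(arch, cfg, "nope"),
               class = "crossprs_invalid_config")
})

test_that("phenotypes respect construction invariants and the null", {
  cfg <- sim_config(n_target = 20000, m_variants = 150, seed = 17)
  st <- simulate_study(cfg)
  ph <- st$cohort
  expect_true(all(ph$age[!is.na(ph$mmse)] >= 60))
  expect_true(all(is.na(ph$mmse_change) | !is.na(ph$followup_years)))
  expect_true(all(ph$mmse >= 0 & ph$mmse <= 30, na.rm = TRUE))
  expect_true(all(ph$followup_years > 0, na.rm = TRUE))
  # marginal education proportions near the configured cut-points
  tab <- table(factor(ph$education,
                      levels = c("elementary", "junior_high", "senior_high",
                                 "university", "master")))
  expect_true(all(abs(tab / sum(tab) - cfg$edu_props) < 0.02))

  # all loadings zero: education is independent of the genetic components
  cfg0 <- sim_config(n_target = 50000, m_variants = 150,
                     edu_loadings = c(0, 0, 0), mmse_loadings = c(0, 0, 0),
                     mmse_change_loadings = c(0, 0, 0), seed = 23)
  g0 <- simulate_genotypes(cfg0, 50000, "target")
  a0 <- simulate_effects(cfg0)
  d0 <- simulate_disease(g0, a0, cfg0)
  p0 <- simulate_phenotypes(g0, a0, d0, cfg0)
  prep <- prepare_analysis_sample(p0, "education")
  comp <- d0$components[match(prep$data$IID, p0$IID), "shared"]
  r <- fit_ordinal(prep$data$education,
                   data.frame(shared = comp / sd(comp)),
                   data.frame(sex = factor(prep$data$sex),
                              age = prep$data$age))
  z <- qnorm(r$P / 2, lower.tail = FALSE)
  expect_lt(abs(z), 4)
})

test_that("fixtures round-trip losslessly and the VCF is sorted", {
  st <- small_study(n = 60, m = 50, seed = 31, missing_rate = 0.02)
  dir <- withr::local_tempdir()
  write_fixture(st, dir)
  back <- read_fixture(dir)
  expect_identical(back$genotypes$dosage, st$genotypes$dosage)
  expect_identical(back$genotypes$variants$id, st$genotypes$variants$id)
  expect_equal(back$genotypes$variants$freq, st$genotypes$variants$freq)
  expect_equal(back$sumstats[["SCZ"]]$BETA, st$sumstats[["SCZ"]]$BETA)
  expect_equal(back$cohort$IID, st$cohort$IID)
  expect_equal(back$cohort$mmse, st$cohort$mmse)

  vg <- read_vcf(file.path(dir, "genotypes.vcf"))
  ord <- order(st$genotypes$variants$chrom, st$genotypes$variants$pos)
  expect_identical(vg$variants$id, st$genotypes$variants$id[ord])
  expect_false(is.unsorted(order(vg$variants$chrom, vg$variants$pos)))
  expect_equal(unname(vg$dosage[, vg$variants$id]),
               unname(st$genotypes$dosage[, vg$variants$id]))

  # vcfR as an independent reader of the emitted VCF
  v <- vcfR::read.vcfR(file.path(dir, "genotypes.vcf"), verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  expect_equal(unname(t(ds)), unname(st$genotypes$dosage[, rownames(ds)]))

  # manifest/seed consistency is validated on read
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  mf$seed <- mf$seed + 1L
  jsonlite::write_json(mf, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(read_fixture(dir), class = "crossprs_invalid_config")
})
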
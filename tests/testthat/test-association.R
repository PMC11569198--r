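published_cohort <- function() {
  # status table with the published margins: 106,806 unrelated samples,
  # 192 SCZ reporters, 711 BPD reporters, 16 dual; among the 105,919
  # remaining, 29 missing / 124 illiterate / 56 self-study education
  n <- 106806L
  scz <- bpd <- integer(n)
  scz[1:192] <- 1L
  bpd[177:887] <- 1L            # 16 dual reporters in rows 177:192
  edu <- rep("university", n)
  edu[888:916] <- NA            # 29 missing
  edu[917:1040] <- "illiterate" # 124
  edu[1041:1096] <- "self_study"# 56
  data.frame(IID = sprintf("i%06d", 1:n), scz = scz, bpd = bpd,
             education = edu, age = 50, mmse = NA_real_,
             mmse_change = NA_real_, stringsAsFactors = FALSE)
}

test_that("analysis-sample exclusions reproduce the published bookkeeping", {
  co <- published_cohort()
  edu <- prepare_analysis_sample(co, "education")
  e <- edu$ledger$entries
  expect_equal(e$removed, c(887L, 29L, 124L, 56L))
  expect_equal(nrow(edu$data), 105710L)
  expect_true(crossprs:::ledger_conserved(edu$ledger))

  scz <- prepare_analysis_sample(co, "SCZ")
  expect_equal(scz$ledger$entries$removed[1], 711L)
  expect_equal(sum(scz$data$scz), 176L)
  expect_equal(sum(scz$data$scz == 0), 105919L)

  bpd <- prepare_analysis_sample(co, "BPD")
  expect_equal(sum(bpd$data$bpd), 695L)
  expect_equal(sum(bpd$data$bpd == 0), 105919L)

  # MMSE requires age >= 60 with a baseline score
  expect_error(prepare_analysis_sample(co, "MMSE"),
               class = "crossprs_structural_error")
  co2 <- co
  co2$age[2000:4000] <- 65
  co2$mmse[2000:3500] <- 28
  mm <- prepare_analysis_sample(co2, "MMSE")
  expect_equal(nrow(mm$data), 1501L)
  expect_true(all(mm$data$age >= 60 & !is.na(mm$data$mmse)))
  expect_error(prepare_analysis_sample(co, "nope"),
               class = "crossprs_invalid_config")
})

test_that("logistic fits recover simulated odds ratios with calibrated error", {
  set.seed(91)
  n <- 20000
  x <- rnorm(n)
  cv <- data.frame(sex = factor(rbinom(n, 1, 0.5)), age = runif(n, 30, 70))
  y <- rbinom(n, 1, plogis(qlogis(0.05) + log(1.5) * x))
  r <- fit_logistic(y, data.frame(PRS = x), cv)
  expect_true(r$CI_LO < 1.5 && r$CI_HI > 1.5)
  expect_equal(r$TIER, "bonferroni")
  expect_gt(r$EFFECT, 1)
  expect_error(fit_logistic(rep(1, 50), data.frame(PRS = rnorm(50))),
               class = "crossprs_invalid_config")

  # aliased predictor flagged, not silently dropped
  r2 <- fit_logistic(y, data.frame(A = x, B = x), cv)
  expect_equal(r2$NOTE[2], "predictor aliased")

  # type-I error of the Wald test under the null
  rej <- mean(vapply(1:300, function(i) {
    yi <- rbinom(4000, 1, 0.1)
    fit_logistic(yi, data.frame(PRS = rnorm(4000)))$P < 0.05
  }, TRUE))
  expect_gt(rej, 0.025)
  expect_lt(rej, 0.08)
})

test_that("Wald intervals attain near-nominal coverage", {
  set.seed(92)
  cover <- mean(vapply(1:100, function(i) {
    n <- 5000
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(qlogis(0.05) + log(1.5) * x))
    r <- fit_logistic(y, data.frame(PRS = x))
    r$CI_LO <= 1.5 && r$CI_HI >= 1.5
  }, TRUE))
  expect_gte(cover, 0.89)
})

test_that("Nagelkerke increment matches the written formula at the independent optimum", {
  set.seed(93)
  n <- 200
  x <- rnorm(n); z <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x + 0.3 * z))
  inc <- nagelkerke_r2_increment(y, data.frame(prs = x), data.frame(z = z))
  # oracle: independently maximized nested likelihoods (Newton to 1e-14)
  # pushed through R2_N = [1 - (L0/L)^(2/n)] / [1 - L0^(2/n)]
  ll0 <- newton_logistic_loglik(matrix(numeric(0), n, 0), y)
  llc <- newton_logistic_loglik(cbind(z), y)
  llf <- newton_logistic_loglik(cbind(z, x), y)
  r2 <- function(ll) (1 - exp((2 / n) * (ll0 - ll))) /
    (1 - exp((2 / n) * ll0))
  expect_lt(abs(inc - (r2(llf) - r2(llc))), 1e-10)

  expect_equal(nagelkerke_r2_increment(y, data.frame()[seq_len(n), , drop = FALSE],
                                       data.frame(z = z)), 0)

  # affine rescaling of covariates leaves the increment unchanged
  inc2 <- nagelkerke_r2_increment(y, data.frame(prs = x),
                                  data.frame(z = 1000 * z + 5))
  expect_lt(abs(inc - inc2), 1e-8)
})

test_that("Nagelkerke increment grows with the simulated effect size", {
  set.seed(94)
  n <- 20000
  x <- rnorm(n)
  incs <- vapply(c(0.2, 0.5, 0.9), function(b) {
    y <- rbinom(n, 1, plogis(qlogis(0.02) + b * x))
    nagelkerke_r2_increment(y, data.frame(prs = x), NULL)
  }, 0)
  expect_true(all(diff(incs) > 0))
})

test_that("two-level ordinal fits equal binary logistic regression", {
  set.seed(95)
  n <- 5000
  x <- rnorm(n)
  cv <- data.frame(sex = factor(rbinom(n, 1, 0.5)), age = runif(n, 30, 70))
  y <- rbinom(n, 1, plogis(-1 + 0.3 * x))
  ro <- fit_ordinal(factor(y, ordered = TRUE), data.frame(PRS = x), cv)
  rl <- fit_logistic(y, data.frame(PRS = x), cv)
  expect_lt(abs(ro$EFFECT - rl$EFFECT), 1e-6)
  expect_lt(abs(ro$CI_LO - rl$CI_LO), 1e-5)
  expect_lt(abs(ro$CI_HI - rl$CI_HI), 1e-5)
})

test_that("proportional-odds fits recover a simulated latent effect", {
  set.seed(96)
  n <- 20000
  beta <- 0.1
  cuts <- qlogis(c(0.044, 0.115, 0.406, 0.887))
  draw <- function() {
    x <- rnorm(n)
    u <- runif(n)
    # cumulative-logit generation: P(Y <= k) = plogis(cut_k - beta x)
    pk <- vapply(cuts, function(ck) plogis(ck - beta * x), numeric(n))
    y <- ordered(rowSums(u > pk) + 1L, levels = 1:5)
    list(x = x, y = y)
  }
  cover <- mean(vapply(1:40, function(i) {
    d <- draw()
    r <- fit_ordinal(d$y, data.frame(PRS = d$x))
    r$CI_LO <= exp(beta) && r$CI_HI >= exp(beta)
  }, TRUE))
  expect_gte(cover, 0.85)
  d <- draw()
  r <- fit_ordinal(d$y, data.frame(PRS = d$x))
  expect_gt(r$EFFECT, 1)  # OR > 1 means higher attainment
})

test_that("linear fits are exact without noise and unbiased at scale", {
  x <- rnorm(500)
  r <- fit_linear(2.5 * x + 1, data.frame(PRS = x))
  expect_lt(abs(r$EFFECT - 2.5), 1e-10)
  expect_lt(r$P, 1e-200)
  expect_error(fit_linear(rep(1, 10), data.frame(PRS = rnorm(10))),
               class = "crossprs_invalid_config")

  set.seed(97)
  ests <- vapply(1:200, function(i) {
    x <- rnorm(27000)
    y <- -0.07 * x + rnorm(27000, 0, 3.8)
    fit_linear(y, data.frame(PRS = x))$EFFECT
  }, 0)
  expect_lt(abs(mean(ests) + 0.07), 0.01)

  rej <- mean(vapply(1:200, function(i) {
    x <- rnorm(8000)
    fit_linear(rnorm(8000), data.frame(PRS = x))$P < 0.05
  }, TRUE))
  expect_gt(rej, 0.02); expect_lt(rej, 0.08)
})

test_that("the MMSE deficit indicator uses a strict cutoff at 24", {
  expect_equal(binary_mmse_outcome(c(23, 24, 30, NA)), c(1L, 0L, 0L, NA))
  expect_equal(binary_mmse_outcome(data.frame(mmse = 23.9)), 1L)
})

test_that("the model suite emits the four-family grid with per-outcome ledgers", {
  st <- small_study(n = 4000, m = 300, seed = 103)
  prof <- profiles_of(st)
  suite <- run_model_suite(prof, st$cohort, pcs = FALSE)
  res <- suite$results
  expect_setequal(unique(res$MODEL), c("1", "2", "3", "4"))
  expect_setequal(unique(res$OUTCOME),
                  c("SCZ", "BPD", "education", "MMSE", "MMSE<24",
                    "MMSE_change"))
  # model 1 carries two predictors, model 4 four
  expect_equal(sum(res$OUTCOME == "education" & res$MODEL == "1"), 2L)
  expect_equal(sum(res$OUTCOME == "education" & res$MODEL == "4"), 4L)
  # Nagelkerke increments only for the disease outcomes
  expect_true(all(is.na(res$DELTA_R2_NAGELKERKE[res$OUTCOME == "education"])))
  expect_true(all(res$TIER %in% c("bonferroni", "nominal", "ns")))
  expect_true(all(is.na(res$EFFECT) |
                    (res$CI_LO <= res$EFFECT & res$EFFECT <= res$CI_HI)))
  expect_equal(suite$ledgers$education$n_initial, nrow(st$cohort))

  sep <- run_model_suite(prof, st$cohort, analysis_config(model1_joint = FALSE),
                         outcomes = "education", pcs = FALSE)
  expect_equal(sum(sep$results$MODEL == "1"), 2L)
})

test_that("inter-PRS correlations are a proper matrix with the built-in signs", {
  st <- small_study(n = 2000, m = 400, seed = 107)
  prof <- profiles_of(st)
  cm <- prs_correlations(prof, st$cohort)
  expect_equal(dim(cm), c(8L, 8L))
  expect_equal(unname(diag(cm)), rep(1, 8))
  expect_equal(cm, t(cm))
  expect_true(all(cm >= -1 & cm <= 1))
  # shared architecture: discordant splits anti-correlate across disorders
  expect_lt(cm["SCZ_discordant", "BPD_discordant"], 0)
  expect_gt(cm["SCZ", "BPD"], 0)

  degen <- list(z = cbind(prof$z[, 1:7], const = 0))
  colnames(degen$z)[8] <- "BPD_discordant"
  expect_error(prs_correlations(degen, st$cohort),
               class = "crossprs_invalid_config")
})
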
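# The association model suite: analysis-sample preparation with an
# exclusion ledger, logistic disease models with incremental Nagelkerke
# pseudo-R2, proportional-odds models for 5-level education, linear and
# binary models for MMSE outcomes, Bonferroni tiering over the four model
# families, and the inter-PRS correlation matrix.

.outcomes <- c("SCZ", "BPD", "education", "MMSE", "MMSE<24", "MMSE_change")
.edu_levels <- c("elementary", "junior_high", "senior_high", "university",
                 "master")

#' Prepare the analysis subsample for an outcome
#'
#' Disease outcomes drop every reporter of the other disorder, dual
#' reporters included, so the cases analyzed for a disorder are its sole
#' reporters and the controls report neither disorder.
#' Education and MMSE outcomes drop all SCZ/BPD cases, then samples with
#' missing, illiterate or self-study education; MMSE outcomes are
#' additionally restricted to age >= 60 with a baseline MMSE, and the
#' MMSE-change outcome to samples with a follow-up measurement.  Every
#' stage is booked in the returned ledger.
#'
#' @param cohort Cohort table (QC-passed, unrelated).
#' @param outcome One of `"SCZ"`, `"BPD"`, `"education"`, `"MMSE"`,
#'   `"MMSE<24"`, `"MMSE_change"`.
#' @return List with `data` (subsample; education recoded as an ordered
#'   factor over the five retained levels) and `ledger`.
#' @export
prepare_analysis_sample <- function(cohort, outcome) {
  if (!outcome %in% .outcomes)
    stop_invalid("unknown outcome: ", outcome)
  led <- new_ledger(nrow(cohort), "sample", label = outcome)
  d <- cohort
  if (outcome %in% c("SCZ", "BPD")) {
    # the other disorder's reporters are excluded outright, dual reporters
    # included (cases of SCZ are then the SCZ-only reporters, etc.)
    other <- if (outcome == "SCZ") d$bpd == 1 else d$scz == 1
    led <- ledger_add(led, "other_disorder_cases", sum(other))
    d <- d[!other, , drop = FALSE]
  } else {
    case <- d$scz == 1 | d$bpd == 1
    led <- ledger_add(led, "scz_or_bpd", sum(case))
    d <- d[!case, , drop = FALSE]
    miss <- is.na(d$education)
    led <- ledger_add(led, "education_missing", sum(miss))
    d <- d[!miss, , drop = FALSE]
    illit <- d$education == "illiterate"
    led <- ledger_add(led, "illiterate", sum(illit))
    d <- d[!illit, , drop = FALSE]
    selfs <- d$education == "self_study"
    led <- ledger_add(led, "self_study", sum(selfs))
    d <- d[!selfs, , drop = FALSE]
    d$education <- factor(d$education, levels = .edu_levels, ordered = TRUE)
    if (outcome %in% c("MMSE", "MMSE<24", "MMSE_change")) {
      no_mmse <- !(d$age >= 60 & !is.na(d$mmse))
      led <- ledger_add(led, "no_baseline_mmse", sum(no_mmse))
      d <- d[!no_mmse, , drop = FALSE]
    }
    if (outcome == "MMSE_change") {
      no_fu <- is.na(d$mmse_change)
      led <- ledger_add(led, "no_followup", sum(no_fu))
      d <- d[!no_fu, , drop = FALSE]
    }
  }
  if (nrow(d) == 0L) {
    print(led)
    stop_structural("analysis sample for ", outcome,
                    " is empty after exclusions")
  }
  list(data = d, ledger = led)
}

#' Binary cognitive-deficit indicator
#'
#' 1 iff the MMSE score is strictly below the cutoff (default 24).
#'
#' @param mmse Numeric MMSE scores (or a cohort data.frame with an
#'   `mmse` column).
#' @param cutoff Deficit cutoff.
#' @return Integer 0/1 vector (`NA` preserved).
#' @export
binary_mmse_outcome <- function(mmse, cutoff = 24) {
  if (is.data.frame(mmse)) mmse <- mmse$mmse
  as.integer(mmse < cutoff)
}

significance_tier <- function(p, config = analysis_config()) {
  ifelse(is.na(p), "ns",
         ifelse(p < config$alpha_bonferroni, "bonferroni",
                ifelse(p < config$alpha_overall, "nominal", "ns")))
}

# Covariate sets per outcome (Table-3-footnote style): diseases adjust
# for sex, age, batch and the PCs; education adds birth cohort; MMSE
# outcomes add education level; the change model adds follow-up duration.
covariates_for <- function(cohort, outcome, config = analysis_config(),
                           pcs = TRUE) {
  cv <- data.frame(sex = factor(cohort$sex), age = cohort$age,
                   batch = factor(cohort$batch))
  if (outcome %in% c("education", "MMSE", "MMSE<24", "MMSE_change"))
    cv$birth_cohort <- factor(cohort$birth_cohort)
  if (outcome %in% c("MMSE", "MMSE<24", "MMSE_change"))
    cv$education <- factor(cohort$education, ordered = FALSE)
  if (outcome == "MMSE_change")
    cv$followup_years <- cohort$followup_years
  if (pcs && config$n_pcs > 0L) {
    pc_cols <- paste0("PC", seq_len(config$n_pcs))
    pc_cols <- pc_cols[pc_cols %in% names(cohort)]
    cv <- cbind(cv, cohort[, pc_cols, drop = FALSE])
  }
  cv
}

assoc_row <- function(outcome, model, predictor, n, effect = NA_real_,
                      ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                      delta_r2 = NA_real_, tier = "ns", note = "") {
  data.frame(OUTCOME = outcome, MODEL = model, PREDICTOR = predictor,
             N = n, EFFECT = effect, CI_LO = ci_lo, CI_HI = ci_hi, P = p,
             DELTA_R2_NAGELKERKE = delta_r2, TIER = tier, NOTE = note,
             stringsAsFactors = FALSE)
}

# Drop covariate columns that are constant or aliased so the design is
# full rank; predictors themselves are never dropped silently.
drop_aliased <- function(fit, predictors) {
  aliased <- names(coef(fit))[is.na(coef(fit))]
  bad <- intersect(aliased, predictors)
  if (length(aliased) > length(bad)) {
    warning("rank-deficient design: dropped ",
            paste(setdiff(aliased, bad), collapse = ", "), call. = FALSE)
  }
  bad
}

#' Logistic association of Z-scored predictors with a binary outcome
#'
#' Maximum-likelihood logistic fit of the outcome on all listed
#' predictors jointly plus the covariates; odds ratio per SD of each
#' predictor with Wald 95% CI and p-value.  Perfect separation yields a
#' flagged (`tier = "ns"`) diagnostic row rather than an error; an
#' outcome with a single class is an error.
#'
#' @param outcome 0/1 vector.
#' @param predictors data.frame/matrix of Z-scored predictors (one
#'   column per score).
#' @param covariates data.frame of adjustment covariates.
#' @param config An [analysis_config()] (tiering thresholds).
#' @param outcome_name,model Labels written into the result rows.
#' @return AssociationResult rows (one per predictor).
#' @export
fit_logistic <- function(outcome, predictors, covariates = NULL,
                         config = analysis_config(),
                         outcome_name = "outcome", model = "") {
  predictors <- as.data.frame(predictors)
  pred_names <- make.names(colnames(predictors))
  colnames(predictors) <- pred_names
  if (length(unique(outcome[!is.na(outcome)])) < 2L)
    stop_invalid("outcome has a single class")
  df <- data.frame(.y = outcome, predictors, check.names = TRUE)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  n <- stats::nobs(fit)
  sm <- summary(fit)$coefficients
  out <- do.call(rbind, lapply(seq_along(pred_names), function(i) {
    nm <- pred_names[i]
    if (!nm %in% rownames(sm) || is.na(coef(fit)[nm]))
      return(assoc_row(outcome_name, model, colnames(predictors)[i], n,
                       note = "predictor aliased"))
    b <- sm[nm, 1L]; se <- sm[nm, 2L]; p <- sm[nm, 4L]
    if (sep_warn)
      return(assoc_row(outcome_name, model, colnames(predictors)[i], n,
                       effect = exp(b), ci_lo = exp(b - 1.96 * se),
                       ci_hi = exp(b + 1.96 * se), p = p, tier = "ns",
                       note = "possible perfect separation"))
    assoc_row(outcome_name, model, colnames(predictors)[i], n,
              effect = exp(b), ci_lo = exp(b - qnorm(0.975) * se),
              ci_hi = exp(b + qnorm(0.975) * se), p = p,
              tier = significance_tier(p, config))
  }))
  attr(out, "fit") <- fit
  out
}

nagelkerke_from_loglik <- function(ll_null, ll_model, n) {
  r2_cs <- 1 - exp((2 / n) * (ll_null - ll_model))
  r2_cs / (1 - exp((2 / n) * ll_null))
}

#' Incremental Nagelkerke pseudo-R2
#'
#' Nagelkerke R2 = Cox-Snell R2 / (1 - L0^(2/n)) is computed for the
#' covariates-only model and the covariates-plus-predictors model (both
#' against the intercept-only null), and the difference returned.  An
#' empty predictor set yields exactly 0.
#'
#' @param outcome 0/1 vector.
#' @param predictors data.frame of predictors added in the full model
#'   (may have zero columns).
#' @param covariates data.frame of base covariates.
#' @return The increment (non-negative up to numerical noise).
#' @export
nagelkerke_r2_increment <- function(outcome, predictors, covariates = NULL) {
  predictors <- as.data.frame(predictors)
  base <- if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L)
    data.frame(.y = outcome)
  else data.frame(.y = outcome, covariates)
  if (ncol(predictors) == 0L) return(0)
  full <- cbind(base, predictors)
  # separation/convergence diagnostics are reported by the companion
  # fit_logistic call; here only the maximized likelihoods are needed
  f0 <- suppressWarnings(stats::glm(.y ~ ., data = base,
                                    family = stats::binomial()))
  f1 <- suppressWarnings(stats::glm(.y ~ ., data = full,
                                    family = stats::binomial()))
  n <- stats::nobs(f1)
  if (stats::nobs(f0) != n)
    stop_structural("nested models fitted on different samples")
  null_ll <- as.numeric(stats::logLik(
    suppressWarnings(stats::glm(.y ~ 1, data = base,
                                family = stats::binomial()))))
  nagelkerke_from_loglik(null_ll, as.numeric(stats::logLik(f1)), n) -
    nagelkerke_from_loglik(null_ll, as.numeric(stats::logLik(f0)), n)
}

#' Proportional-odds association with ordinal education
#'
#' Cumulative-logit maximum-likelihood fit (proportional odds), oriented
#' so OR > 1 means higher attainment per SD of the predictor; Wald 95%
#' CI and p.  Non-convergence yields a flagged diagnostic row.
#'
#' @param outcome Ordered factor with >= 2 observed levels.
#' @param predictors data.frame of Z-scored predictors (fit jointly).
#' @param covariates data.frame of adjustment covariates.
#' @param config An [analysis_config()].
#' @param start Optional start values passed to the optimizer (used to
#'   warm-start replicated fits).
#' @param reltol Optimizer convergence tolerance; the tight default
#'   supports oracle-level comparisons, replicated simulations may relax
#'   it.
#' @param outcome_name,model Labels for the result rows.
#' @return AssociationResult rows; the fitted `polr` object is attached
#'   as attribute `fit`.
#' @export
fit_ordinal <- function(outcome, predictors, covariates = NULL,
                        config = analysis_config(), start = NULL,
                        reltol = 1e-12,
                        outcome_name = "education", model = "") {
  outcome <- droplevels(as.ordered(outcome))
  if (nlevels(outcome) < 2L)
    stop_invalid("ordinal outcome has fewer than 2 observed levels")
  predictors <- as.data.frame(predictors)
  orig_names <- colnames(predictors)
  pred_names <- make.names(orig_names)
  colnames(predictors) <- pred_names
  if (nlevels(outcome) == 2L) {
    return(fit_cumlogit2(outcome, predictors, covariates, config,
                         orig_names, outcome_name, model))
  }
  df <- data.frame(.y = outcome, predictors, check.names = TRUE)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  polr_args <- list(.y ~ ., data = df, Hess = TRUE, model = FALSE,
                    control = list(reltol = reltol, maxit = 500))
  if (!is.null(start)) polr_args$start <- start
  fit <- tryCatch(
    suppressWarnings(do.call(MASS::polr, polr_args)),
    error = function(e) e)
  n <- nrow(df)
  if (inherits(fit, "error")) {
    return(do.call(rbind, lapply(orig_names, function(nm)
      assoc_row(outcome_name, model, nm, n,
                note = paste0("ordinal fit failed: ",
                              conditionMessage(fit))))))
  }
  vc <- stats::vcov(fit)
  out <- do.call(rbind, lapply(seq_along(pred_names), function(i) {
    nm <- pred_names[i]
    if (!nm %in% names(coef(fit)))
      return(assoc_row(outcome_name, model, orig_names[i], n,
                       note = "predictor aliased"))
    b <- coef(fit)[[nm]]
    se <- sqrt(vc[nm, nm])
    z <- b / se
    p <- 2 * pnorm(-abs(z))
    assoc_row(outcome_name, model, orig_names[i], n, effect = exp(b),
              ci_lo = exp(b - qnorm(0.975) * se),
              ci_hi = exp(b + qnorm(0.975) * se), p = p,
              tier = significance_tier(p, config))
  }))
  attr(out, "fit") <- fit
  out
}

# Two-category cumulative-logit fit: logit P(Y <= 1) = zeta - eta.  polr
# declines K = 2, so the proportional-odds likelihood is maximized
# directly (BFGS with analytic gradient); the optimum coincides with
# binary logistic regression on the upper level, which the test suite
# exploits as a model-equivalence oracle.
fit_cumlogit2 <- function(outcome, predictors, covariates, config,
                          orig_names, outcome_name, model) {
  pred_names <- colnames(predictors)
  df <- data.frame(predictors, check.names = TRUE)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  X <- stats::model.matrix(~ ., df)[, -1L, drop = FALSE]
  y2 <- as.numeric(outcome == levels(outcome)[2L])
  nll <- function(par) {
    mu <- drop(X %*% par[-length(par)]) - par[length(par)]
    -sum(y2 * stats::plogis(mu, log.p = TRUE) +
           (1 - y2) * stats::plogis(-mu, log.p = TRUE))
  }
  grad <- function(par) {
    mu <- drop(X %*% par[-length(par)]) - par[length(par)]
    r <- y2 - stats::plogis(mu)
    c(-drop(crossprod(X, r)), sum(r))
  }
  par0 <- c(rep(0, ncol(X)), -stats::qlogis(mean(y2)))
  opt <- stats::optim(par0, nll, grad, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
  H <- stats::optimHess(opt$par, nll, grad)
  vc <- solve(H)
  n <- length(y2)
  idx <- match(pred_names, colnames(X))
  out <- do.call(rbind, lapply(seq_along(pred_names), function(i) {
    j <- idx[i]
    if (is.na(j))
      return(assoc_row(outcome_name, model, orig_names[i], n,
                       note = "predictor aliased"))
    b <- opt$par[j]; se <- sqrt(vc[j, j])
    p <- 2 * pnorm(-abs(b / se))
    assoc_row(outcome_name, model, orig_names[i], n, effect = exp(b),
              ci_lo = exp(b - qnorm(0.975) * se),
              ci_hi = exp(b + qnorm(0.975) * se), p = p,
              tier = significance_tier(p, config))
  }))
  out
}

#' Linear association with a continuous outcome
#'
#' Ordinary least squares; slope per SD of each predictor with t-based
#' 95% CI and p.
#'
#' @inheritParams fit_logistic
#' @export
fit_linear <- function(outcome, predictors, covariates = NULL,
                       config = analysis_config(),
                       outcome_name = "outcome", model = "") {
  if (stats::var(outcome, na.rm = TRUE) == 0)
    stop_invalid("outcome has zero variance")
  predictors <- as.data.frame(predictors)
  orig_names <- colnames(predictors)
  pred_names <- make.names(orig_names)
  colnames(predictors) <- pred_names
  df <- data.frame(.y = outcome, predictors, check.names = TRUE)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  fit <- stats::lm(.y ~ ., data = df)
  drop_aliased(fit, pred_names)
  n <- stats::nobs(fit)
  sm <- summary(fit)$coefficients
  tq <- stats::qt(0.975, fit$df.residual)
  out <- do.call(rbind, lapply(seq_along(pred_names), function(i) {
    nm <- pred_names[i]
    if (!nm %in% rownames(sm) || is.na(coef(fit)[nm]))
      return(assoc_row(outcome_name, model, orig_names[i], n,
                       note = "predictor aliased"))
    b <- sm[nm, 1L]; se <- sm[nm, 2L]; p <- sm[nm, 4L]
    assoc_row(outcome_name, model, orig_names[i], n, effect = b,
              ci_lo = b - tq * se, ci_hi = b + tq * se, p = p,
              tier = significance_tier(p, config))
  }))
  attr(out, "fit") <- fit
  out
}

model_predictors <- function(config = analysis_config()) {
  list("1" = c("SCZ", "BPD"),
       "2" = "SCZ+BPD",
       "3" = "SCZvsBPD",
       "4" = c("SCZ_concordant", "SCZ_discordant",
               "BPD_concordant", "BPD_discordant"))
}

#' Run the full association model suite
#'
#' For each outcome (SCZ, BPD, education, MMSE, MMSE<24, MMSE change)
#' fits the four model families — Model 1: SCZ and BPD scores jointly;
#' Model 2: the shared SCZ+BPD score; Model 3: the SCZ-vs-BPD contrast
#' score; Model 4: the four sign-concordance split scores jointly — each
#' with the outcome's covariate set and analysis-sample exclusions, and
#' tiers every result at the Bonferroni (0.0125) and nominal (0.05)
#' levels.  Disease outcomes also record the incremental Nagelkerke R2
#' of the model's predictor set.  Per-cell failures are captured as
#' flagged rows without aborting the grid.
#'
#' @param profile A `prs_profile` with all eight labels.
#' @param cohort Cohort table (rows keyed by `IID` matching the profile).
#' @param config An [analysis_config()].
#' @param outcomes Outcomes to fit (default all six).
#' @param pcs Include the PC covariates (default `TRUE`).
#' @return List with `results` (the AssociationResult grid) and
#'   `ledgers` (per-outcome exclusion ledgers).
#' @export
run_model_suite <- function(profile, cohort, config = analysis_config(),
                            outcomes = .outcomes, pcs = TRUE) {
  stopifnot(all(.prs_labels %in% colnames(profile$z)))
  mp <- model_predictors(config)
  rows <- list(); ledgers <- list()
  for (oc in outcomes) {
    prep <- prepare_analysis_sample(cohort, oc)
    ledgers[[oc]] <- prep$ledger
    d <- prep$data
    zi <- profile$z[match(d$IID, rownames(profile$z)), , drop = FALSE]
    if (anyNA(zi[, 1L])) stop_structural("cohort samples missing from profile")
    y <- switch(oc,
                "SCZ" = d$scz, "BPD" = d$bpd, "education" = d$education,
                "MMSE" = d$mmse,
                "MMSE<24" = binary_mmse_outcome(d$mmse,
                                                config$mmse_deficit_cutoff),
                "MMSE_change" = d$mmse_change)
    cv <- covariates_for(d, oc, config, pcs = pcs)
    for (mid in names(mp)) {
      preds <- zi[, mp[[mid]], drop = FALSE]
      pred_sets <- if (oc %in% c("SCZ", "BPD") && mid == "1" &&
                       !config$model1_joint) {
        lapply(mp[[mid]], function(l) preds[, l, drop = FALSE])
      } else list(preds)
      for (ps in pred_sets) {
        res <- tryCatch({
          if (oc %in% c("SCZ", "BPD", "MMSE<24")) {
            r <- fit_logistic(y, ps, cv, config, outcome_name = oc,
                              model = mid)
            if (oc != "MMSE<24") {
              r$DELTA_R2_NAGELKERKE <-
                nagelkerke_r2_increment(y, ps, cv)
            }
            r
          } else if (oc == "education") {
            fit_ordinal(y, ps, cv, config, outcome_name = oc, model = mid)
          } else {
            fit_linear(y, ps, cv, config, outcome_name = oc, model = mid)
          }
        }, error = function(e) {
          assoc_row(oc, mid, paste(colnames(ps), collapse = "+"),
                    nrow(d), note = paste0("failed: ", conditionMessage(e)))
        })
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  attr(results, "alpha_bonferroni") <- config$alpha_bonferroni
  list(results = results, ledgers = ledgers)
}

#' Single-score disease prediction table
#'
#' For each of the eight scores, the logistic association with each
#' disorder (other-disorder cases excluded) and the incremental
#' Nagelkerke R2 over the covariates-only model.
#'
#' @inheritParams run_model_suite
#' @return data.frame with one row per score x disorder.
#' @export
disease_prs_table <- function(profile, cohort, config = analysis_config(),
                              pcs = TRUE) {
  rows <- list()
  for (oc in c("SCZ", "BPD")) {
    prep <- prepare_analysis_sample(cohort, oc)
    d <- prep$data
    y <- if (oc == "SCZ") d$scz else d$bpd
    cv <- covariates_for(d, oc, config, pcs = pcs)
    zi <- profile$z[match(d$IID, rownames(profile$z)), , drop = FALSE]
    for (lab in colnames(zi)) {
      ps <- zi[, lab, drop = FALSE]
      r <- tryCatch({
        r <- fit_logistic(y, ps, cv, config, outcome_name = oc, model = lab)
        r$DELTA_R2_NAGELKERKE <- nagelkerke_r2_increment(y, ps, cv)
        r
      }, error = function(e)
        assoc_row(oc, lab, lab, nrow(d),
                  note = paste0("failed: ", conditionMessage(e))))
      r$N_VARIANTS <- profile$n_variants[[lab]]
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Inter-PRS correlation matrix
#'
#' Pearson correlations among the eight Z-scores over the subsample with
#' neither SCZ nor BPD.
#'
#' @param profile A `prs_profile`.
#' @param cohort Cohort table with `scz`/`bpd` indicators.
#' @return Symmetric 8x8 correlation matrix with unit diagonal.
#' @export
prs_correlations <- function(profile, cohort) {
  ids <- cohort$IID[cohort$scz == 0 & cohort$bpd == 0]
  if (length(ids) < 3L) stop_invalid("need at least 3 unaffected samples")
  z <- profile$z[match(ids, rownames(profile$z)), , drop = FALSE]
  sds <- apply(z, 2L, stats::sd)
  if (any(sds == 0))
    stop_invalid("degenerate score column: ",
                 paste(colnames(z)[sds == 0], collapse = ", "))
  stats::cor(z)
}

#' Write the association results and correlation matrix
#'
#' @param results AssociationResult data.frame.
#' @param path Output TSV path.
#' @export
write_results <- function(results, path) {
  data.table::fwrite(results, path, sep = "\t")
  invisible(path)
}

#' @rdname write_results
#' @param cmat Correlation matrix.
#' @export
write_correlations <- function(cmat, path) {
  out <- data.frame(LABEL = rownames(cmat), cmat, check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
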
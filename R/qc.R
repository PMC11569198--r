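# Variant- and sample-level quality control: missingness, MAF, the
# Hardy-Weinberg exact test, imputation-info filtering, heterozygosity
# outliers, and PI-HAT-based duplicate/relatedness pruning, all booked in
# exclusion ledgers.

# Hard calls for heterozygosity and HWE: dosages rounded to the nearest
# integer genotype (heterozygosity is undefined on fractional dosages).
hard_calls <- function(dosage) {
  h <- round(dosage)
  h[h < 0] <- 0; h[h > 2] <- 2
  h
}

#' Per-variant missing fraction
#'
#' @param geno A `genotype_matrix`.
#' @return Named numeric vector in `[0, 1]`, one entry per variant.
#' @export
variant_missingness <- function(geno) {
  if (nrow(geno$dosage) < 1L) stop_invalid("at least one sample required")
  colMeans(is.na(geno$dosage))
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact p-value of the observed heterozygote count conditional
#' on the allele counts: the sum of the probabilities of all heterozygote
#' configurations no more probable than the observed one.  Probabilities
#' are evaluated in log space by the stable ratio recurrence over
#' heterozygote counts of matching parity.  Monomorphic input returns 1
#' by convention.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total >= 1).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop_invalid("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1L) stop_invalid("total genotype count must be >= 1")
  n_a1 <- 2 * n_AA + n_Aa
  n_a2 <- 2 * n_aa + n_Aa
  nr <- min(n_a1, n_a2)
  if (nr == 0) return(1)
  hs <- seq.int(nr %% 2L, nr, by = 2L)
  if (length(hs) > 1L) {
    h <- hs[-length(hs)]
    hom_r <- (nr - h) / 2
    hom_c <- (2 * n - nr - h) / 2
    # P(h+2)/P(h) = 4 hom_r hom_c / ((h+2)(h+1))
    lp <- c(0, cumsum(log(4 * hom_r * hom_c) - log((h + 2) * (h + 1))))
  } else lp <- 0
  lp <- lp - max(lp)
  pr <- exp(lp)
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hs)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

# Genotype counts (hom A1, het, hom A2) per variant from hard calls.
genotype_counts <- function(geno) {
  h <- hard_calls(geno$dosage)
  t(apply(h, 2L, function(g) c(n_AA = sum(g == 2, na.rm = TRUE),
                               n_Aa = sum(g == 1, na.rm = TRUE),
                               n_aa = sum(g == 0, na.rm = TRUE))))
}

#' Variant quality-control filters
#'
#' Removes, in fixed order, variants failing (1) missingness, (2) minor
#' allele frequency computed on non-missing dosages, (3) the
#' Hardy-Weinberg exact test, and (4) the imputation info score when one
#' is supplied; each stage is booked in the returned ledger.  A variant
#' without an info value is not subject to the info stage.
#'
#' @param geno A `genotype_matrix`.
#' @param thresholds A [qc_thresholds()].
#' @param info Optional per-variant info scores (named by variant id or
#'   in panel order; `NA` = not imputed / stage skipped).
#' @return List with `kept` (variant ids), `ledger`, and a `detail`
#'   data.frame of per-variant statistics.
#' @export
filter_variants <- function(geno, thresholds = qc_thresholds(), info = NULL) {
  ids <- geno$variants$id
  m <- length(ids)
  if (!is.null(info)) {
    if (!is.null(names(info))) info <- unname(info[ids])
    if (length(info) != m)
      stop_structural("info scores do not match the variant panel")
  } else info <- rep(NA_real_, m)
  led <- new_ledger(m, "variant")

  miss <- variant_missingness(geno)
  fail_miss <- miss > thresholds$variant_missing_max
  led <- ledger_add(led, "missingness", sum(fail_miss))
  alive <- !fail_miss

  freq <- colMeans(geno$dosage, na.rm = TRUE) / 2
  freq[is.nan(freq)] <- 0
  maf <- pmin(freq, 1 - freq)
  fail_maf <- alive & maf < thresholds$maf_min
  led <- ledger_add(led, "maf", sum(fail_maf))
  alive <- alive & !fail_maf

  cnt <- genotype_counts(geno)
  hwe_p <- rep(NA_real_, m)
  hwe_p[alive] <- vapply(which(alive), function(j)
    hwe_exact_test(cnt[j, 1L], cnt[j, 2L], cnt[j, 3L]), 0)
  fail_hwe <- alive & hwe_p < thresholds$hwe_p_min
  led <- ledger_add(led, "hwe", sum(fail_hwe))
  alive <- alive & !fail_hwe

  fail_info <- alive & !is.na(info) & info < thresholds$info_min
  led <- ledger_add(led, "info", sum(fail_info))
  alive <- alive & !fail_info

  list(kept = ids[alive], ledger = led,
       detail = data.frame(id = ids, missingness = miss, maf = maf,
                           hwe_p = hwe_p, info = info, kept = alive,
                           stringsAsFactors = FALSE))
}

#' Sample missingness and heterozygosity filters
#'
#' Removes samples with a missing fraction above the threshold, then
#' computes the per-sample heterozygosity rate (heterozygous hard calls /
#' non-missing calls) on the survivors and removes those beyond
#' mean +/- `het_sd_bound` standard deviations.  A zero SD (all samples
#' identical) yields no outliers; with fewer than 3 samples the
#' heterozygosity stage is skipped with a warning record in the ledger.
#'
#' @param geno A `genotype_matrix`.
#' @param thresholds A [qc_thresholds()].
#' @return List with `kept` (sample ids), `ledger` and per-sample
#'   `detail`.
#' @export
sample_missingness_het <- function(geno, thresholds = qc_thresholds()) {
  ids <- rownames(geno$dosage)
  led <- new_ledger(length(ids), "sample")
  miss <- rowMeans(is.na(geno$dosage))
  fail_miss <- miss > thresholds$sample_missing_max
  led <- ledger_add(led, "missingness", sum(fail_miss))
  alive <- !fail_miss

  het <- rep(NA_real_, length(ids))
  if (sum(alive) < 3L) {
    led <- ledger_add(led, "heterozygosity", 0L,
                      note = "skipped: fewer than 3 samples")
  } else {
    h <- hard_calls(geno$dosage[alive, , drop = FALSE])
    het_rate <- rowSums(h == 1, na.rm = TRUE) / rowSums(!is.na(h))
    het[alive] <- het_rate
    s <- stats::sd(het_rate)
    if (is.na(s) || s == 0) {
      fail_het <- rep(FALSE, sum(alive))
    } else {
      fail_het <- abs(het_rate - mean(het_rate)) > thresholds$het_sd_bound * s
    }
    led <- ledger_add(led, "heterozygosity", sum(fail_het))
    alive[alive] <- !fail_het
  }
  list(kept = ids[alive], ledger = led,
       detail = data.frame(id = ids, missingness = miss, het = het,
                           kept = alive, stringsAsFactors = FALSE))
}

# Expected IBS proportions per locus given allele frequency p:
#   IBD0: P(IBS0)=2p^2q^2, P(IBS1)=4p^3q+4pq^3, P(IBS2)=p^4+q^4+4p^2q^2
#   IBD1: P(IBS1)=2pq, P(IBS2)=p^2+q^2 ; IBD2: P(IBS2)=1
ibd_expectations <- function(p) {
  q <- 1 - p
  list(e0_ibs0 = sum(2 * p^2 * q^2),
       e0_ibs1 = sum(4 * p^3 * q + 4 * p * q^3),
       e0_ibs2 = sum(p^4 + q^4 + 4 * p^2 * q^2),
       e1_ibs1 = sum(2 * p * q),
       e1_ibs2 = sum(p^2 + q^2))
}

ibd_from_counts <- function(n0, n1, n2, mpair, ex, m_total) {
  scale <- mpair / m_total
  z0 <- n0 / (ex$e0_ibs0 * scale)
  z1 <- (n1 - z0 * ex$e0_ibs1 * scale) / (ex$e1_ibs1 * scale)
  z2 <- (n2 - z0 * ex$e0_ibs2 * scale - z1 * ex$e1_ibs2 * scale) / mpair
  z <- cbind(z0, z1, z2)
  z[!is.finite(z)] <- 0
  z[z < 0] <- 0; z[z > 1] <- 1
  tot <- rowSums(z)
  z <- z / ifelse(tot > 0, tot, 1)
  cbind(Z0 = z[, 1], Z1 = z[, 2], Z2 = z[, 3],
        PI_HAT = z[, 3] + 0.5 * z[, 2])
}

# Per-locus P(IBS class | IBD state) coefficients for the pairwise
# likelihood, selected by the observed IBS class of each locus.
ibd_class_coefs <- function(p, ibs) {
  q <- 1 - p
  p0 <- cbind(2 * p^2 * q^2, 4 * p^3 * q + 4 * p * q^3,
              p^4 + q^4 + 4 * p^2 * q^2)
  p1 <- cbind(0, 2 * p * q, p^2 + q^2)
  idx <- cbind(seq_along(p), ibs + 1L)
  list(c0 = p0[idx], c1 = p1[idx], c2 = as.numeric(ibs == 2L))
}

# Maximum-likelihood refinement of (Z0, Z1, Z2) on the simplex for one
# pair, given observed IBS classes; started from the moment estimate.
ibd_ml_pair <- function(p, ibs, start = c(1, 0, 0)) {
  cf <- ibd_class_coefs(p, ibs)
  nll <- function(par) {
    z <- exp(c(par, 0))
    z <- z / sum(z)
    -sum(log(pmax(cf$c0 * z[1] + cf$c1 * z[2] + cf$c2 * z[3], 1e-300)))
  }
  gr <- function(par) {
    z <- exp(c(par, 0))
    z <- z / sum(z)
    d <- pmax(cf$c0 * z[1] + cf$c1 * z[2] + cf$c2 * z[3], 1e-300)
    dz <- -c(sum(cf$c0 / d), sum(cf$c1 / d), sum(cf$c2 / d))
    (z * (dz - sum(z * dz)))[1:2]
  }
  st <- log(pmax(start[1:2], 1e-8) / max(start[3], 1e-8))
  o <- stats::optim(st, nll, gr, method = "BFGS",
                    control = list(reltol = 1e-12, maxit = 200))
  z <- exp(c(o$par, 0))
  z / sum(z)
}

#' Pairwise IBD estimation
#'
#' Estimates the pairwise identity-by-descent probabilities P(IBD=0/1/2)
#' from identity-by-state counts weighted by allele frequencies.  The
#' PLINK-style moment cascade (clamped to `[0, 1]` and renormalized) is
#' computed for every pair; pairs whose moment PI-HAT exceeds
#' `refine_above` -- and every explicitly listed pair -- are then
#' refined by maximizing the multinomial IBS-class likelihood on the
#' probability simplex, which has markedly lighter tails at moderate
#' marker counts.  `PI_HAT = P(IBD=2) + 0.5 P(IBD=1)` throughout.  All
#' sample pairs are computed (block-wise, so memory stays bounded)
#' unless an explicit pair list is given.  Monomorphic variants are
#' excluded; missing genotypes reduce the per-pair locus count, with
#' moment expectations rescaled proportionally.
#'
#' @param geno A `genotype_matrix` (hard calls are taken from rounded
#'   dosages).
#' @param freqs Optional effect-allele frequencies in (0,1); defaults to
#'   the empirical frequencies of the non-missing dosages.
#' @param pairs Optional two-column matrix/data.frame of sample ids.
#' @param block Sample block size for the all-pairs computation.
#' @param method `"ml"` (moment screen plus likelihood refinement, the
#'   default) or `"moment"` (cascade only).
#' @param refine_above Moment PI-HAT above which an all-pairs entry is
#'   re-estimated by maximum likelihood.
#' @return data.frame with ID1, ID2, Z0, Z1, Z2, PI_HAT.
#' @export
estimate_ibd <- function(geno, freqs = NULL, pairs = NULL, block = 1024L,
                         method = c("ml", "moment"), refine_above = 0.1) {
  method <- match.arg(method)
  ids <- rownames(geno$dosage)
  if (length(ids) < 2L) stop_invalid("at least 2 samples required")
  g <- hard_calls(geno$dosage)
  if (is.null(freqs)) freqs <- colMeans(g, na.rm = TRUE) / 2
  keep <- is.finite(freqs) & freqs > 0 & freqs < 1
  if (!any(keep)) stop_structural("no polymorphic variants left for IBD")
  g <- g[, keep, drop = FALSE]
  p <- freqs[keep]
  m <- ncol(g)
  ex <- ibd_expectations(p)

  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    res <- t(apply(pairs, 1L, function(pr) {
      g1 <- g[pr[1L], ]; g2 <- g[pr[2L], ]
      ok <- !is.na(g1) & !is.na(g2)
      ibs <- 2 - abs(g1[ok] - g2[ok])
      mom <- ibd_from_counts(sum(ibs == 0), sum(ibs == 1), sum(ibs == 2),
                             sum(ok), ex, m)[1L, ]
      if (method == "moment") return(mom)
      z <- ibd_ml_pair(p[ok], ibs, start = mom[c("Z0", "Z1", "Z2")])
      c(Z0 = z[1], Z1 = z[2], Z2 = z[3], PI_HAT = z[3] + 0.5 * z[2])
    }))
    return(data.frame(ID1 = pairs[, 1L], ID2 = pairs[, 2L], res,
                      stringsAsFactors = FALSE))
  }

  n <- nrow(g)
  has_na <- anyNA(g)
  V <- if (has_na) 1 - is.na(g) else NULL
  g0 <- g; if (has_na) g0[is.na(g)] <- -9
  A0 <- (g0 == 0) * 1; A1 <- (g0 == 1) * 1; A2 <- (g0 == 2) * 1
  blocks <- split(seq_len(n), ceiling(seq_len(n) / block))
  out <- vector("list", length(blocks) * (length(blocks) + 1L) / 2L)
  k <- 0L
  for (bi in seq_along(blocks)) {
    i <- blocks[[bi]]
    for (bj in bi:length(blocks)) {
      j <- blocks[[bj]]
      N0 <- A0[i, , drop = FALSE] %*% t(A2[j, , drop = FALSE]) +
            A2[i, , drop = FALSE] %*% t(A0[j, , drop = FALSE])
      N2 <- A0[i, , drop = FALSE] %*% t(A0[j, , drop = FALSE]) +
            A1[i, , drop = FALSE] %*% t(A1[j, , drop = FALSE]) +
            A2[i, , drop = FALSE] %*% t(A2[j, , drop = FALSE])
      Mp <- if (has_na) V[i, , drop = FALSE] %*% t(V[j, , drop = FALSE])
            else matrix(m, length(i), length(j))
      N1 <- Mp - N0 - N2
      idx <- which(outer(i, j, "<"), arr.ind = TRUE)
      if (nrow(idx)) {
        z <- ibd_from_counts(N0[idx], N1[idx], N2[idx], Mp[idx], ex, m)
        k <- k + 1L
        out[[k]] <- data.frame(ID1 = ids[i[idx[, 1L]]],
                               ID2 = ids[j[idx[, 2L]]], z,
                               stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  if (method == "ml" && any(res$PI_HAT > refine_above)) {
    for (i in which(res$PI_HAT > refine_above)) {
      g1 <- g[res$ID1[i], ]; g2 <- g[res$ID2[i], ]
      ok <- !is.na(g1) & !is.na(g2)
      ibs <- 2 - abs(g1[ok] - g2[ok])
      z <- ibd_ml_pair(p[ok], ibs,
                       start = unlist(res[i, c("Z0", "Z1", "Z2")]))
      res$Z0[i] <- z[1]; res$Z1[i] <- z[2]; res$Z2[i] <- z[3]
      res$PI_HAT[i] <- z[3] + 0.5 * z[2]
    }
  }
  res
}

# Deterministic light variant subset for relatedness estimation: common,
# nearly complete variants, thinned by stride to a cap.
select_ibd_variants <- function(geno, maf_min = 0.05, miss_max = 0.01,
                                max_variants = 50000L) {
  freq <- colMeans(geno$dosage, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  ok <- which(maf >= maf_min & variant_missingness(geno) <= miss_max)
  if (length(ok) > max_variants) {
    ok <- ok[seq(1L, length(ok), length.out = max_variants)]
  }
  geno$variants$id[ok]
}

#' Greedy relatedness pruning
#'
#' Repeatedly removes the sample participating in the most
#' above-threshold pairs until none remain; ties are broken by higher
#' missingness, then by lexicographically larger id.
#'
#' @param ibd IBD estimate table (columns ID1, ID2, PI_HAT).
#' @param samples Sample ids under consideration.
#' @param thresholds A [qc_thresholds()]; `pihat_max` is the default cut.
#' @param missingness Optional named per-sample missing fractions for
#'   tie-breaking.
#' @param threshold Override for the PI-HAT cut (e.g. `dup_pihat` for
#'   the duplicate stage).
#' @return List with `kept` and `removed` sample id vectors.
#' @export
prune_related <- function(ibd, samples, thresholds = qc_thresholds(),
                          missingness = NULL,
                          threshold = thresholds$pihat_max) {
  if (is.null(missingness)) {
    missingness <- stats::setNames(rep(0, length(samples)), samples)
  }
  flagged <- ibd[ibd$PI_HAT > threshold &
                 ibd$ID1 %in% samples & ibd$ID2 %in% samples, , drop = FALSE]
  removed <- character()
  while (nrow(flagged) > 0L) {
    deg <- table(c(flagged$ID1, flagged$ID2))
    cand <- names(deg)[deg == max(deg)]
    if (length(cand) > 1L) {
      ms <- missingness[cand]
      ms[is.na(ms)] <- 0
      cand <- cand[ms == max(ms)]
      cand <- sort(cand)
      cand <- cand[length(cand)]  # lexicographically larger id removed
    }
    removed <- c(removed, cand)
    flagged <- flagged[flagged$ID1 != cand & flagged$ID2 != cand, ,
                       drop = FALSE]
  }
  list(kept = setdiff(samples, removed), removed = removed)
}

#' Genotype principal components
#'
#' First `k` principal components of the standardized dosage matrix
#' (column-mean imputation of missing entries), for use as population
#' stratification covariates.  Signs are fixed by making each
#' component's largest-magnitude variant loading positive, so repeated
#' runs are identical.
#'
#' @param geno A `genotype_matrix`.
#' @param k Number of components (default 20).
#' @return n x k matrix of per-sample coordinates (columns PC1..PCk).
#' @export
genotype_pca <- function(geno, k = 20L) {
  X <- geno$dosage
  if (k > min(dim(X))) stop_invalid("k exceeds min(n samples, m variants)")
  if (anyNA(X)) {
    cm <- colMeans(X, na.rm = TRUE)
    for (j in which(colSums(is.na(X)) > 0L)) X[is.na(X[, j]), j] <- cm[j]
  }
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  ok <- sdv > 0
  if (!any(ok)) stop_invalid("no standardizable variants (all monomorphic)")
  Xs <- sweep(sweep(X[, ok, drop = FALSE], 2L, mu[ok], "-"), 2L, sdv[ok], "/")
  sv <- La.svd(Xs, nu = k, nv = k)
  rot <- t(sv$vt[seq_len(k), , drop = FALSE])
  flip <- vapply(seq_len(k), function(j) {
    l <- rot[, j]
    sign(l[which.max(abs(l))])
  }, 0)
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2L, flip, "*")
  dimnames(scores) <- list(rownames(geno$dosage), paste0("PC", seq_len(k)))
  attr(scores, "rotation") <- sweep(rot, 2L, flip, "*")
  scores
}

#' Full cohort quality control
#'
#' Orchestrates the QC suite: variant filters (missingness, MAF, HWE,
#' info), an optional externally supplied sample exclusion list (e.g.
#' ancestry), sample missingness and heterozygosity filters, then
#' duplicate detection (PI-HAT > `dup_pihat`) and relatedness pruning
#' (PI-HAT > `pihat_max`) on a light common-variant subset, each booked
#' as a distinct ledger stage.
#'
#' @param geno A `genotype_matrix`.
#' @param thresholds A [qc_thresholds()].
#' @param info Optional per-variant imputation info scores.
#' @param exclude_samples Optional character vector of sample ids to
#'   drop before the genotype-based sample filters.
#' @return List with `kept_variants`, `kept_samples`, `ledgers`
#'   (variant/sample), and the pairwise `ibd` table.
#' @export
run_qc <- function(geno, thresholds = qc_thresholds(), info = NULL,
                   exclude_samples = NULL) {
  vres <- filter_variants(geno, thresholds, info)
  sub <- geno
  keep_j <- match(vres$kept, geno$variants$id)
  sub$dosage <- geno$dosage[, keep_j, drop = FALSE]
  sub$variants <- geno$variants[keep_j, , drop = FALSE]

  sled <- new_ledger(nrow(sub$dosage), "sample")
  alive <- rownames(sub$dosage)
  if (!is.null(exclude_samples)) {
    drop <- intersect(alive, exclude_samples)
    sled <- ledger_add(sled, "external_exclusion", length(drop))
    alive <- setdiff(alive, drop)
  }
  sub2 <- sub
  sub2$dosage <- sub$dosage[alive, , drop = FALSE]
  sres <- sample_missingness_het(sub2, thresholds)
  for (i in seq_len(nrow(sres$ledger$entries))) {
    e <- sres$ledger$entries[i, ]
    sled <- ledger_add(sled, e$filter, e$removed, e$note)
  }
  alive <- sres$kept

  sub3 <- sub2
  sub3$dosage <- sub2$dosage[alive, , drop = FALSE]
  ibd_ids <- select_ibd_variants(sub3)
  ibd <- NULL
  if (length(ibd_ids) >= 50L && length(alive) >= 2L) {
    gi <- sub3
    jj <- match(ibd_ids, sub3$variants$id)
    gi$dosage <- sub3$dosage[, jj, drop = FALSE]
    gi$variants <- sub3$variants[jj, , drop = FALSE]
    ibd <- estimate_ibd(gi, refine_above = thresholds$pihat_max)
    miss <- stats::setNames(rowMeans(is.na(sub3$dosage)), alive)
    dup <- prune_related(ibd, alive, thresholds, miss,
                         threshold = thresholds$dup_pihat)
    sled <- ledger_add(sled, "duplicates", length(dup$removed))
    rel <- prune_related(ibd, dup$kept, thresholds, miss)
    sled <- ledger_add(sled, "relatedness", length(rel$removed))
    alive <- rel$kept
  } else {
    sled <- ledger_add(sled, "relatedness", 0L,
                       note = "skipped: too few common variants or samples")
  }
  list(kept_variants = vres$kept, kept_samples = alive,
       ledgers = list(variant = vres$ledger, sample = sled),
       variant_detail = vres$detail, ibd = ibd)
}
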
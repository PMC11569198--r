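test_that("variant missingness fractions are exact", {
  d <- matrix(c(0, 1, 2, NA,
                1, 1, 1, 1,
                NA, NA, NA, NA), nrow = 4)
  g <- make_geno(d)
  miss <- variant_missingness(g)
  expect_equal(unname(miss), c(0.25, 0, 1))
  expect_equal(variant_missingness(make_geno(matrix(0:1, 2, 1))), c(v1 = 0))
})

test_that("HWE exact test agrees with the enumeration oracle", {
  expect_equal(hwe_exact_test(0, 0, 100), 1)
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  # 1 AA, 0 het, 1 aa: two A and two a alleles, het counts {0, 2} with
  # P(0) = 1/3, P(2) = 2/3, so the two-sided p is 1/3
  expect_equal(hwe_exact_test(1, 0, 1), hwe_enumeration_oracle(1, 0, 1))
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  expect_lt(abs(hwe_exact_test(57, 14, 50) -
                hwe_enumeration_oracle(57, 14, 50)), 1e-12)
  set.seed(77)
  for (i in 1:200) {
    tot <- sample(1:200, 1)
    a <- sample(0:tot, 1)
    b <- sample(0:(tot - a), 1)
    expect_lt(abs(hwe_exact_test(a, b, tot - a - b) -
                  hwe_enumeration_oracle(a, b, tot - a - b)), 1e-12)
  }
  expect_error(hwe_exact_test(-1, 0, 1), class = "crossprs_invalid_config")
  expect_error(hwe_exact_test(0, 0, 0), class = "crossprs_invalid_config")
})

test_that("variant filters run in fixed order with an auditable ledger", {
  set.seed(5)
  n <- 2000
  base <- matrix(rbinom(n * 3, 2, 0.3), n, 3)
  rare <- rbinom(n, 2, 0.0005)          # fails MAF
  hwe_bad <- rep(1, n)                  # all heterozygous: extreme HWE
  missing <- c(rep(NA, 150), rbinom(n - 150, 2, 0.3))  # 7.5% missing
  d <- cbind(base, rare, hwe_bad, missing)
  colnames(d) <- paste0("v", 1:6)
  g <- make_geno(d)
  info <- c(0.9, 0.69, NA, 0.95, 0.95, 0.95)  # v2 fails info, v3 untyped
  res <- filter_variants(g, qc_thresholds(), info = info)
  expect_setequal(res$kept, c("v1", "v3"))
  e <- res$ledger$entries
  expect_equal(e$filter, c("missingness", "maf", "hwe", "info"))
  expect_equal(e$removed, c(1L, 1L, 1L, 1L))
  expect_true(crossprs:::ledger_conserved(res$ledger))

  all_pass <- filter_variants(make_geno(base), qc_thresholds())
  expect_equal(sum(all_pass$ledger$entries$removed), 0L)
})

test_that("sample missingness and heterozygosity outliers are removed", {
  set.seed(6)
  m <- 200
  d <- matrix(rbinom(1000 * m, 2, 0.3), 1000, m)
  d[1, seq_len(6)] <- NA                    # 3% missing -> removed
  d[2, ] <- 2 * rbinom(m, 1, 0.3)           # zero heterozygosity outlier
  g <- make_geno(d)
  res <- sample_missingness_het(g, qc_thresholds())
  expect_false("s001" %in% res$kept)
  expect_false("s002" %in% res$kept)
  expect_equal(res$ledger$entries$removed, c(1L, 1L))
  expect_true(crossprs:::ledger_conserved(res$ledger))

  # identical heterozygosity for everyone: degenerate SD, none removed
  same <- make_geno(matrix(1, 10, 50))
  res2 <- sample_missingness_het(same, qc_thresholds())
  expect_length(res2$kept, 10L)

  tiny <- sample_missingness_het(make_geno(matrix(0:1, 2, 10)),
                                 qc_thresholds())
  expect_match(tiny$ledger$entries$note[2], "skipped")
})

test_that("moment-based IBD recovers duplicates, parent-offspring and unrelated", {
  cfg <- sim_config(m_variants = 10000, maf_range = c(0.05, 0.5),
                    n_target = 2, seed = 2)
  panel <- crossprs:::simulate_variant_panel(cfg)
  f <- panel$freq
  m <- length(f)
  set.seed(14)
  gp <- rbinom(m, 2, f)
  trans <- ifelse(gp == 0, 0L, ifelse(gp == 2, 1L, rbinom(m, 1, 0.5)))
  child <- trans + rbinom(m, 1, f)
  pair_geno <- function(g1, g2) {
    M <- rbind(s1 = g1, s2 = g2)
    colnames(M) <- panel$id
    crossprs:::new_genotype_matrix(M, panel)
  }
  est <- function(g1, g2)
    estimate_ibd(pair_geno(g1, g2), freqs = f,
                 pairs = cbind("s1", "s2"))$PI_HAT
  expect_lt(abs(est(gp, gp) - 1), 0.02)
  expect_lt(abs(est(gp, child) - 0.5), 0.05)
  pis <- vapply(1:10, function(i)
    est(rbinom(m, 2, f), rbinom(m, 2, f)), 0)
  expect_true(all(abs(pis) <= 0.05))
  expect_lt(abs(mean(pis)), 0.02)  # estimator bias bound

  # IBD probabilities are a clamped simplex and PI-HAT follows the formula
  tab <- estimate_ibd(pair_geno(gp, child), freqs = f)
  expect_true(all(tab[, c("Z0", "Z1", "Z2")] >= 0 &
                  tab[, c("Z0", "Z1", "Z2")] <= 1))
  expect_equal(tab$Z0 + tab$Z1 + tab$Z2, rep(1, nrow(tab)))
  expect_equal(tab$PI_HAT, tab$Z2 + 0.5 * tab$Z1)
  expect_error(estimate_ibd(pair_geno(gp, gp), freqs = rep(0, m)),
               class = "crossprs_structural_error")
})

test_that("all-pairs IBD matches the per-pair route", {
  set.seed(15)
  m <- 2000
  f <- runif(m, 0.1, 0.5)
  d <- matrix(rbinom(6 * m, 2, rep(f, each = 6)), 6, m, byrow = FALSE)
  d[1, sample(m, 20)] <- NA
  g <- make_geno(matrix(as.numeric(d), 6, m), freq = f)
  full <- estimate_ibd(g, freqs = f, block = 3L, method = "moment")
  pairs <- cbind(full$ID1, full$ID2)
  per <- estimate_ibd(g, freqs = f, pairs = pairs, method = "moment")
  expect_equal(full$PI_HAT, per$PI_HAT, tolerance = 1e-12)
  expect_equal(nrow(full), choose(6, 2))
})

test_that("greedy pruning removes the fewest samples and clears all pairs", {
  ibd <- data.frame(ID1 = c("A", "B"), ID2 = c("B", "C"),
                    PI_HAT = c(0.3, 0.4))
  th <- qc_thresholds()
  res <- prune_related(ibd, c("A", "B", "C"), th)
  expect_identical(res$removed, "B")
  expect_setequal(res$kept, c("A", "C"))

  one <- prune_related(data.frame(ID1 = "A", ID2 = "B", PI_HAT = 0.5),
                       c("A", "B"), th)
  expect_identical(one$removed, "B")  # lexicographic tie-break

  miss <- c(A = 0.01, B = 0)
  one2 <- prune_related(data.frame(ID1 = "A", ID2 = "B", PI_HAT = 0.5),
                        c("A", "B"), th, missingness = miss)
  expect_identical(one2$removed, "A")  # higher missingness removed first

  none <- prune_related(data.frame(ID1 = "A", ID2 = "B", PI_HAT = 0.1),
                        c("A", "B", "C"), th)
  expect_length(none$removed, 0L)

  # post-condition on a random table: no kept pair above threshold
  set.seed(16)
  ids <- sprintf("s%02d", 1:15)
  rnd <- data.frame(ID1 = sample(ids, 40, TRUE), ID2 = sample(ids, 40, TRUE),
                    PI_HAT = runif(40, 0, 0.6))
  rnd <- rnd[rnd$ID1 != rnd$ID2, ]
  pr <- prune_related(rnd, ids, th)
  left <- rnd[rnd$ID1 %in% pr$kept & rnd$ID2 %in% pr$kept, ]
  expect_true(all(left$PI_HAT <= th$pihat_max))
})

test_that("genotype PCA separates structure with a fixed sign convention", {
  set.seed(18)
  m <- 80
  f1 <- rep(0.1, m); f2 <- rep(0.9, m)
  d <- rbind(matrix(rbinom(30 * m, 2, f1), 30, m, byrow = TRUE),
             matrix(rbinom(30 * m, 2, f2), 30, m, byrow = TRUE))
  g <- make_geno(d)
  pcs <- genotype_pca(g, 3)
  cluster <- rep(c(0, 1), each = 30)
  expect_gt(abs(cor(pcs[, 1], cluster)), 0.9)
  expect_identical(pcs, genotype_pca(g, 3))
  expect_error(genotype_pca(g, 100), class = "crossprs_invalid_config")

  # rank-1 noise-free matrix: one component reconstructs exactly
  a <- runif(20, 0, 2); b <- runif(10, 0.5, 2)
  r1 <- make_geno(outer(a, b))
  p1 <- genotype_pca(r1, 1)
  X <- scale(outer(a, b))
  rec <- p1 %*% t(attr(p1, "rotation"))
  expect_lt(max(abs(rec - X)), 1e-8)
})

test_that("run_qc conserves counts across both ledgers", {
  st <- small_study(n = 500, m = 600, seed = 41, missing_rate = 0.005)
  qc <- run_qc(st$genotypes)
  expect_true(crossprs:::ledger_conserved(qc$ledgers$variant))
  expect_true(crossprs:::ledger_conserved(qc$ledgers$sample))
  expect_equal(qc$ledgers$variant$n_initial, 600L)
  expect_equal(qc$ledgers$sample$n_initial, 500L)
  expect_true(all(qc$kept_variants %in% st$genotypes$variants$id))
  # ledger arithmetic: initial = remaining + removals
  expect_equal(length(qc$kept_samples) +
                 sum(qc$ledgers$sample$entries$removed), 500L)
})
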
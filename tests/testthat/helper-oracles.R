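# Shared fixtures and independent oracles used across the suite.

# Direct-formula enumeration oracle for the conditional exact HWE test:
# P(h | allele counts) from the log-factorial expression, summed over
# configurations no more probable than the observed one.  Independent of
# the package's ratio-recurrence implementation.
hwe_enumeration_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nr <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (nr == 0) return(1)
  hs <- seq(nr %% 2, nr, by = 2)
  lp <- vapply(hs, function(h) {
    hom_r <- (nr - h) / 2
    hom_c <- (2 * n - nr - h) / 2
    lfactorial(n) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c) +
      h * log(2) + lfactorial(nr) + lfactorial(2 * n - nr) - lfactorial(2 * n)
  }, 0)
  pr <- exp(lp)
  p_obs <- pr[match(n_Aa, hs)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

# Newton-Raphson logistic ML, converged to machine precision: the
# independent maximizer behind the Nagelkerke formula oracle.
newton_logistic_loglik <- function(X, y, tol = 1e-14, maxit = 100) {
  X <- cbind(1, X)
  b <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% b)
    p <- plogis(eta)
    W <- p * (1 - p)
    step <- solve(crossprod(X, X * W), crossprod(X, y - p))
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% b)
  sum(y * plogis(eta, log.p = TRUE) + (1 - y) * plogis(-eta, log.p = TRUE))
}

# Build a genotype_matrix from a literal dosage matrix.
make_geno <- function(dosage, a1 = NULL, a2 = NULL, chrom = NULL,
                      pos = NULL, freq = NULL, label = "test") {
  m <- ncol(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("s%03d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("v", seq_len(m))
  variants <- data.frame(
    chrom = chrom %||% rep(1L, m), id = colnames(dosage), cm = 0,
    pos = pos %||% seq(1000L, by = 1000L, length.out = m),
    a1 = a1 %||% rep("A", m), a2 = a2 %||% rep("G", m),
    freq = freq %||% unname(colMeans(dosage, na.rm = TRUE) / 2),
    stringsAsFactors = FALSE)
  crossprs:::new_genotype_matrix(dosage, variants, label)
}

make_weights <- function(id, effect, a1 = "A", a2 = "G", chrom = 1L,
                         pos = NULL, label = "W") {
  n <- length(id)
  crossprs:::new_weight_set(data.frame(
    chrom = rep_len(chrom, n), id = id,
    pos = pos %||% seq(1000L, by = 1000L, length.out = n),
    a1 = rep_len(a1, n), a2 = rep_len(a2, n), effect = effect,
    stringsAsFactors = FALSE), label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small end-to-end synthetic study reused by scoring/association tests.
small_study <- function(n = 1500, m = 400, seed = 101, ...) {
  cfg <- sim_config(n_target = n, m_variants = m, seed = seed, ...)
  simulate_study(cfg)
}

profiles_of <- function(study) {
  ws <- lapply(study$sumstats, derive_weights)
  al <- lapply(ws, function(w)
    align_weights(w, study$genotypes$variants)$weights)
  build_all_profiles(study$genotypes, al[["SCZ"]], al[["BPD"]],
                     al[["SCZ+BPD"]], al[["SCZvsBPD"]])
}
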
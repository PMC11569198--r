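# From summary-statistic weight files to the eight per-sample polygenic
# scores: allele alignment (swap / strand-flip / ambiguous-drop rules),
# the sign-concordance split of one disorder's weights by the other's
# effect directions, additive scoring with mean imputation of missing
# dosages, and Z-normalization over the QC-passed unrelated cohort.

.prs_labels <- c("SCZ", "BPD", "SCZ+BPD", "SCZvsBPD",
                 "SCZ_concordant", "SCZ_discordant",
                 "BPD_concordant", "BPD_discordant")

new_weight_set <- function(df, label) {
  need <- c("chrom", "id", "pos", "a1", "a2", "effect")
  if (!all(need %in% names(df)))
    stop_structural("weight set lacks columns: ",
                    paste(setdiff(need, names(df)), collapse = ", "))
  if (anyDuplicated(df$id))
    stop_structural("duplicate variant ids in weight set")
  if (any(df$a1 == df$a2)) stop_structural("weight set has A1 == A2")
  structure(df[, need], label = label, class = c("weight_set", "data.frame"))
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("weight_set '%s': %d variants, %d nonzero effects\n",
              attr(x, "label"), nrow(x), sum(x$effect != 0)))
  invisible(x)
}

weight_label <- function(w) attr(w, "label") %||% "weights"

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Align a weight set to a target variant panel
#'
#' Matches on (chromosome, position).  Weights whose alleles equal the
#' target A1/A2 are kept; swapped alleles negate the effect; complement
#' pairs are resolved as a strand flip and re-matched.  Strand-ambiguous
#' variants (A/T, C/G) and variants that are unmatched or
#' allele-incompatible after flipping are dropped with a reason.
#'
#' @param weights A `weight_set`.
#' @param variants Target variant table (columns chrom, id, pos, a1, a2).
#' @return List with `weights` (aligned `weight_set`, target
#'   orientation) and `drops` (data.frame id, reason).
#' @export
align_weights <- function(weights, variants) {
  if (nrow(weights) == 0L || nrow(variants) == 0L)
    stop_invalid("weights and target variants must be non-empty")
  wkey <- paste(weights$chrom, weights$pos)
  vkey <- paste(variants$chrom, variants$pos)
  if (anyDuplicated(wkey))
    stop_structural("duplicate position in weights: ",
                    wkey[duplicated(wkey)][1])
  if (anyDuplicated(vkey))
    stop_structural("duplicate position in target variants: ",
                    vkey[duplicated(vkey)][1])
  drops <- list()
  ambiguous <- (weights$a1 == "A" & weights$a2 == "T") |
               (weights$a1 == "T" & weights$a2 == "A") |
               (weights$a1 == "C" & weights$a2 == "G") |
               (weights$a1 == "G" & weights$a2 == "C")
  hit <- match(wkey, vkey)
  absent <- is.na(hit)
  keep <- !ambiguous & !absent
  t_a1 <- variants$a1[hit]
  t_a2 <- variants$a2[hit]
  w_a1 <- weights$a1; w_a2 <- weights$a2
  same <- keep & w_a1 == t_a1 & w_a2 == t_a2
  swap <- keep & w_a1 == t_a2 & w_a2 == t_a1
  f_a1 <- unname(.complement[w_a1]); f_a2 <- unname(.complement[w_a2])
  flip      <- keep & !same & !swap & f_a1 == t_a1 & f_a2 == t_a2
  flip_swap <- keep & !same & !swap & f_a1 == t_a2 & f_a2 == t_a1
  mismatch <- keep & !(same | swap | flip | flip_swap)

  ok <- same | swap | flip | flip_swap
  eff <- weights$effect
  eff[swap | flip_swap] <- -eff[swap | flip_swap]
  aligned <- data.frame(chrom = variants$chrom[hit[ok]],
                        id = variants$id[hit[ok]],
                        pos = variants$pos[hit[ok]],
                        a1 = t_a1[ok], a2 = t_a2[ok], effect = eff[ok],
                        stringsAsFactors = FALSE)
  reason <- rep(NA_character_, nrow(weights))
  reason[ambiguous] <- "strand_ambiguous"
  reason[!ambiguous & absent] <- "absent"
  reason[mismatch] <- "allele_mismatch"
  list(weights = new_weight_set(aligned, weight_label(weights)),
       drops = data.frame(id = weights$id[!ok], reason = reason[!ok],
                          stringsAsFactors = FALSE))
}

#' Split a weight set by sign concordance with another disorder
#'
#' Restricted to variants present in both aligned weight sets (same
#' effect-allele orientation): a variant is concordant iff the source and
#' other effects have the same strict sign, discordant iff strictly
#' opposite; a zero effect in either set has no defined sign and the
#' variant is dropped, as are source variants absent from the other set.
#'
#' @param source,other `weight_set`s aligned to the same target panel.
#' @return List with `concordant` and `discordant` `weight_set`s
#'   (carrying the source effects, labels suffixed `_concordant` /
#'   `_discordant`) and `split`, a data.frame (id, set, reason) covering
#'   every source variant.
#' @export
split_by_sign_concordance <- function(source, other) {
  hit <- match(source$id, other$id)
  shared <- !is.na(hit)
  if (any(shared & source$a1 != other$a1[hit]))
    stop_structural("effect-allele orientation mismatch between weight sets; ",
                    "align both to the same target first")
  s_eff <- source$effect
  o_eff <- other$effect[hit]
  set <- rep("dropped", nrow(source))
  reason <- rep(NA_character_, nrow(source))
  reason[!shared] <- "absent"
  zero <- shared & (s_eff == 0 | o_eff == 0)
  reason[zero] <- "zero-effect"
  conc <- shared & !zero & sign(s_eff) == sign(o_eff)
  disc <- shared & !zero & sign(s_eff) == -sign(o_eff)
  set[conc] <- "concordant"
  set[disc] <- "discordant"
  lab <- weight_label(source)
  list(concordant = new_weight_set(source[conc, , drop = FALSE],
                                   paste0(lab, "_concordant")),
       discordant = new_weight_set(source[disc, , drop = FALSE],
                                   paste0(lab, "_discordant")),
       split = data.frame(id = source$id, set = set, reason = reason,
                          stringsAsFactors = FALSE))
}

#' Derive scoring weights from summary statistics
#'
#' `passthrough` copies the effect estimates verbatim (the route used
#' for externally shrunk weights such as PRS-CS output); `p_threshold`
#' retains only variants with `P <= p_max`.
#'
#' @param sumstats Summary-statistics data.frame (CHR, POS, SNP, A1, A2,
#'   BETA, P ...).
#' @param method `"passthrough"` or `"p_threshold"`.
#' @param p_max P-value threshold, in (0, 1].
#' @return A `weight_set` carrying the summary statistics' provenance
#'   label.
#' @export
derive_weights <- function(sumstats, method = c("passthrough", "p_threshold"),
                           p_max = 1) {
  method <- match.arg(method)
  if (method == "p_threshold" && (p_max <= 0 || p_max > 1))
    stop_invalid("p_max must lie in (0, 1]")
  keep <- if (method == "p_threshold") sumstats$P <= p_max
          else rep(TRUE, nrow(sumstats))
  new_weight_set(data.frame(chrom = sumstats$CHR[keep],
                            id = as.character(sumstats$SNP[keep]),
                            pos = sumstats$POS[keep],
                            a1 = sumstats$A1[keep], a2 = sumstats$A2[keep],
                            effect = sumstats$BETA[keep],
                            stringsAsFactors = FALSE),
                 attr(sumstats, "label") %||% "weights")
}

# Dosage columns for a set of variant ids with missing entries replaced
# by twice the effect-allele frequency of the non-missing target dosages.
imputed_dosage <- function(geno, ids) {
  j <- match(ids, geno$variants$id)
  if (anyNA(j))
    stop_structural("weight variants absent from genotype matrix: ",
                    paste(utils::head(ids[is.na(j)], 3), collapse = ", "),
                    " (run align_weights first)")
  # avoid a full-matrix copy when the score uses the whole panel as-is
  X <- if (identical(j, seq_len(ncol(geno$dosage)))) geno$dosage
       else geno$dosage[, j, drop = FALSE]
  if (anyNA(X)) {
    for (jj in which(colSums(is.na(X)) > 0L)) {
      f <- mean(X[, jj], na.rm = TRUE) / 2
      if (is.nan(f)) f <- 0
      X[is.na(X[, jj]), jj] <- 2 * f
    }
  }
  X
}

#' Additive polygenic score
#'
#' `score_i = sum_j dosage_ij * effect_j` over the weight variants, with
#' missing dosages replaced by twice the target-sample effect-allele
#' frequency.
#'
#' @param geno A `genotype_matrix` (orientation must match the aligned
#'   weights; variants absent from the matrix are a structural error).
#' @param weights A `weight_set`.
#' @return Named per-sample raw scores with attribute `n_variants`.
#' @export
compute_prs <- function(geno, weights) {
  if (nrow(weights) == 0L) {
    raw <- stats::setNames(rep(0, nrow(geno$dosage)), rownames(geno$dosage))
    attr(raw, "n_variants") <- 0L
    return(raw)
  }
  X <- imputed_dosage(geno, weights$id)
  raw <- drop(X %*% weights$effect)
  names(raw) <- rownames(geno$dosage)
  attr(raw, "n_variants") <- nrow(weights)
  raw
}

#' Z-normalize scores over a reference cohort
#'
#' `(score - mean) / sd` with the mean and sample SD (n-1 denominator)
#' taken over the normalization cohort — by convention all QC-passed
#' unrelated samples, before any analysis-specific exclusion.
#'
#' @param raw Named raw scores.
#' @param cohort Ids of the normalization cohort (default: all scored
#'   samples).
#' @return List with `z` (named vector), `mean` and `sd`.
#' @export
standardize_scores <- function(raw, cohort = names(raw)) {
  ref <- raw[cohort]
  if (anyNA(ref)) stop_invalid("normalization cohort has unscored samples")
  mu <- mean(ref)
  s <- stats::sd(ref)
  if (!is.finite(s) || s == 0)
    stop_invalid("degenerate score: zero SD over the normalization cohort")
  list(z = (raw - mu) / s, mean = mu, sd = s)
}

#' Build the eight polygenic-risk-score profiles
#'
#' Computes the four direct scores (SCZ, BPD, shared SCZ+BPD, contrast
#' SCZvsBPD), splits the SCZ weights by the sign of the BPD effects and
#' the BPD weights by the sign of the SCZ effects to obtain the four
#' concordant/discordant scores, and Z-normalizes all eight over the
#' normalization cohort.
#'
#' @param geno A `genotype_matrix`.
#' @param weights_scz,weights_bpd,weights_shared,weights_contrast
#'   `weight_set`s aligned to the genotype panel.
#' @param cohort Normalization cohort ids (default all samples).
#' @return A `prs_profile`: list with `raw` and `z` (samples x 8
#'   matrices), `n_variants`, `norms` (per-label mean/sd) and `splits`
#'   (the two sign-concordance reports).
#' @export
build_all_profiles <- function(geno, weights_scz, weights_bpd,
                               weights_shared, weights_contrast,
                               cohort = rownames(geno$dosage)) {
  split_scz <- split_by_sign_concordance(weights_scz, weights_bpd)
  split_bpd <- split_by_sign_concordance(weights_bpd, weights_scz)
  sets <- list("SCZ" = weights_scz, "BPD" = weights_bpd,
               "SCZ+BPD" = weights_shared, "SCZvsBPD" = weights_contrast,
               "SCZ_concordant" = split_scz$concordant,
               "SCZ_discordant" = split_scz$discordant,
               "BPD_concordant" = split_bpd$concordant,
               "BPD_discordant" = split_bpd$discordant)
  # one imputation + one matrix multiply over the union of scored variants
  ids <- unique(unlist(lapply(sets, `[[`, "id"), use.names = FALSE))
  X <- imputed_dosage(geno, ids)
  W <- matrix(0, length(ids), length(sets),
              dimnames = list(ids, names(sets)))
  for (nm in names(sets)) {
    W[match(sets[[nm]]$id, ids), nm] <- sets[[nm]]$effect
  }
  raw <- X %*% W
  rownames(raw) <- rownames(geno$dosage)
  z <- raw
  norms <- data.frame(label = names(sets), mean = NA_real_, sd = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_along(sets)) {
    st <- standardize_scores(stats::setNames(raw[, i], rownames(raw)), cohort)
    z[, i] <- st$z
    norms$mean[i] <- st$mean
    norms$sd[i] <- st$sd
  }
  structure(list(raw = raw, z = z,
                 n_variants = vapply(sets, nrow, 0L),
                 norms = norms,
                 splits = list(SCZ = split_scz$split, BPD = split_bpd$split)),
            class = "prs_profile")
}

#' @export
print.prs_profile <- function(x, ...) {
  cat(sprintf("prs_profile: %d samples x %d scores\n", nrow(x$raw),
              ncol(x$raw)))
  print(data.frame(label = colnames(x$raw), n_variants = x$n_variants,
                   row.names = NULL))
  invisible(x)
}

#' Write score and split-report TSVs
#'
#' Scores: IID, LABEL, RAW, Z, N_VARIANTS (long). Split report: SNP,
#' SET, REASON.
#'
#' @param profile A `prs_profile`.
#' @param path Output path.
#' @export
write_scores <- function(profile, path) {
  long <- do.call(rbind, lapply(colnames(profile$raw), function(lab) {
    data.frame(IID = rownames(profile$raw), LABEL = lab,
               RAW = profile$raw[, lab], Z = profile$z[, lab],
               N_VARIANTS = profile$n_variants[[lab]],
               stringsAsFactors = FALSE)
  }))
  data.table::fwrite(long, path, sep = "\t")
  invisible(path)
}

#' @rdname write_scores
#' @param split A split report from [split_by_sign_concordance()].
#' @export
write_split_report <- function(split, path) {
  out <- data.frame(SNP = split$id, SET = split$set,
                    REASON = ifelse(is.na(split$reason), "", split$reason))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
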
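# Readers and writers for the pipeline's plain-text interchange formats:
# VCF 4.2 (GT/DS), PLINK-bim-style variant sidecar, dosage TSV, GWAS
# summary-statistic TSV, PRS-CS weight files, phenotype TSV and the
# fixture manifest.  All TSV IO goes through data.table.

read_tsv_checked <- function(path, ...) {
  if (!file.exists(path)) stop_structural("file not found: ", path)
  out <- tryCatch(data.table::fread(path, sep = "\t", data.table = FALSE, ...),
                  error = function(e)
                    stop_structural("failed to read ", path, ": ",
                                    conditionMessage(e)))
  out
}

#' Write a genotype matrix as VCF 4.2
#'
#' Records are sorted by (chromosome, position); the effect allele (A1,
#' the allele counted by the dosage) is written as ALT and the other
#' allele as REF, with both GT (hard call) and DS (dosage) per sample and
#' `./.:.` for missing entries.
#'
#' @param geno A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  v <- geno$variants
  ord <- order(v$chrom, v$pos)
  v <- v[ord, , drop = FALSE]
  d <- geno$dosage[, ord, drop = FALSE]
  gt <- c("0/0", "0/1", "1/1")
  cells <- matrix("./.:.", nrow(v), nrow(d))
  ok <- !is.na(t(d))
  dv <- t(d)
  cells[ok] <- paste0(gt[dv[ok] + 1L], ":", format(dv[ok], trim = TRUE))
  body <- data.frame(CHROM = v$chrom, POS = v$pos, ID = v$id, REF = v$a2,
                     ALT = v$a1, QUAL = ".", FILTER = "PASS", INFO = ".",
                     FORMAT = "GT:DS", stringsAsFactors = FALSE)
  body <- cbind(body, as.data.frame(cells, stringsAsFactors = FALSE))
  names(body) <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(d))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the ALT (effect) allele\">")
  tryCatch({
    writeLines(hdr, path)
    data.table::fwrite(body, path, sep = "\t", append = TRUE, col.names = TRUE)
  }, error = function(e)
    stop_structural("failed to write VCF ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Read a plain-text VCF into a genotype matrix
#'
#' Accepts the VCF 4.2 subset used by the pipeline: per-sample GT and/or
#' DS fields, uncompressed text.  DS is preferred when present; otherwise
#' the GT allele count is used.  Dosages count the ALT allele, which is
#' taken as the effect allele A1.
#'
#' @param path VCF path.
#' @param label Cohort label for the resulting `genotype_matrix`.
#' @return A `genotype_matrix` (variant `freq` is the empirical
#'   effect-allele frequency).
#' @export
read_vcf <- function(path, label = "vcf") {
  if (!file.exists(path)) stop_structural("file not found: ", path)
  tab <- data.table::fread(path, sep = "\t", skip = "#CHROM",
                           data.table = FALSE)
  fixed <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
             "FORMAT")
  samples <- setdiff(names(tab), fixed)
  fmt <- strsplit(tab$FORMAT[1], ":", fixed = TRUE)[[1]]
  ds_i <- match("DS", fmt)
  gt_i <- match("GT", fmt)
  if (is.na(ds_i) && is.na(gt_i))
    stop_structural("VCF ", path, " has neither GT nor DS")
  parse_col <- function(x) {
    parts <- strsplit(x, ":", fixed = TRUE)
    if (!is.na(ds_i)) {
      out <- suppressWarnings(as.numeric(vapply(parts, `[`, "", ds_i)))
    } else out <- rep(NA_real_, length(parts))
    if (!is.na(gt_i)) {
      g <- vapply(parts, `[`, "", gt_i)
      cnt <- vapply(strsplit(g, "[/|]"), function(a) {
        a <- suppressWarnings(as.integer(a))
        if (anyNA(a)) NA_real_ else sum(a)
      }, 0)
      out[is.na(out)] <- cnt[is.na(out)]
    }
    out
  }
  dosage <- vapply(samples, function(s) parse_col(tab[[s]]),
                   numeric(nrow(tab)))
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = nrow(tab))
  dosage <- t(dosage)
  rownames(dosage) <- samples
  colnames(dosage) <- tab$ID
  freq <- colMeans(dosage, na.rm = TRUE) / 2
  variants <- data.frame(chrom = tab[["#CHROM"]], id = tab$ID, cm = 0,
                         pos = tab$POS, a1 = tab$ALT, a2 = tab$REF,
                         freq = unname(freq), stringsAsFactors = FALSE)
  new_genotype_matrix(dosage, variants, label)
}

#' Write / read the dosage TSV and variant sidecar
#'
#' The dosage TSV is samples x variants with a header row of variant ids
#' and first column `IID`; the sidecar carries the PLINK .bim column
#' order CHROM, ID, CM, POS, A1, A2 (header optional on read).
#'
#' @param geno A `genotype_matrix`.
#' @param dosage_path,sidecar_path Output paths.
#' @return Paths, invisibly.
#' @export
write_dosage <- function(geno, dosage_path, sidecar_path) {
  d <- data.frame(IID = rownames(geno$dosage), geno$dosage,
                  check.names = FALSE, stringsAsFactors = FALSE)
  v <- geno$variants[, c("chrom", "id", "cm", "pos", "a1", "a2")]
  names(v) <- c("CHROM", "ID", "CM", "POS", "A1", "A2")
  tryCatch({
    data.table::fwrite(d, dosage_path, sep = "\t")
    data.table::fwrite(v, sidecar_path, sep = "\t")
  }, error = function(e)
    stop_structural("failed to write dosage fixture ", dosage_path, ": ",
                    conditionMessage(e)))
  invisible(c(dosage_path, sidecar_path))
}

#' @rdname write_dosage
#' @param freq Optional per-variant effect-allele frequencies to attach
#'   (defaults to the empirical frequency).
#' @param label Cohort label.
#' @export
read_dosage <- function(dosage_path, sidecar_path, freq = NULL,
                        label = "cohort") {
  d <- read_tsv_checked(dosage_path)
  first <- readLines(sidecar_path, n = 1L)
  has_header <- grepl("^CHROM\\b", first)
  v <- data.table::fread(sidecar_path, sep = "\t", header = has_header,
                         data.table = FALSE)
  names(v) <- c("CHROM", "ID", "CM", "POS", "A1", "A2")[seq_len(ncol(v))]
  dosage <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(dosage) <- "double"
  rownames(dosage) <- d$IID
  if (!identical(colnames(dosage), as.character(v$ID)))
    stop_structural("dosage columns and sidecar variant ids disagree: ",
                    dosage_path)
  variants <- data.frame(chrom = v$CHROM, id = as.character(v$ID), cm = v$CM,
                         pos = v$POS, a1 = v$A1, a2 = v$A2,
                         freq = if (is.null(freq))
                           unname(colMeans(dosage, na.rm = TRUE) / 2)
                         else freq,
                         stringsAsFactors = FALSE)
  new_genotype_matrix(dosage, variants, label)
}

#' Write / read GWAS summary statistics
#'
#' Header CHR, POS, SNP, A1, A2, FRQ, BETA, SE, P, N; the provenance
#' label rides along as an attribute.
#'
#' @param ss Summary-statistic data.frame.
#' @param path File path.
#' @return `path` / the data.frame.
#' @export
write_sumstats <- function(ss, path) {
  data.table::fwrite(ss, path, sep = "\t")
  invisible(path)
}

#' @rdname write_sumstats
#' @param label Provenance label to attach.
#' @export
read_sumstats <- function(path, label = NULL) {
  ss <- read_tsv_checked(path)
  need <- c("CHR", "POS", "SNP", "A1", "A2", "FRQ", "BETA", "SE", "P", "N")
  if (!all(need %in% names(ss)))
    stop_structural("summary-statistics file ", path, " lacks columns: ",
                    paste(setdiff(need, names(ss)), collapse = ", "))
  if (any(ss$SE <= 0)) stop_structural("non-positive SE in ", path)
  attr(ss, "label") <- label
  ss
}

#' Read a PRS-CS-style weight file
#'
#' Columns CHR, SNP, BP, A1, A2, EFFECT; a header row is auto-detected
#' (PRS-CS output itself has none).
#'
#' @param path Weight file path.
#' @param label Provenance label (one of the eight score definitions).
#' @return A `weight_set` data.frame (columns chrom, id, pos, a1, a2,
#'   effect).
#' @export
read_weights <- function(path, label = "weights") {
  if (!file.exists(path)) stop_structural("file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  has_header <- any(toupper(first) %in% c("CHR", "SNP", "BP", "EFFECT", "A1"))
  w <- data.table::fread(path, sep = "\t", header = has_header,
                         data.table = FALSE)
  names(w) <- c("CHR", "SNP", "BP", "A1", "A2", "EFFECT")[seq_len(ncol(w))]
  new_weight_set(data.frame(chrom = w$CHR, id = as.character(w$SNP),
                            pos = w$BP, a1 = w$A1, a2 = w$A2,
                            effect = w$EFFECT, stringsAsFactors = FALSE),
                 label)
}

#' @rdname read_weights
#' @param weights A `weight_set`.
#' @param header Write a header row (`TRUE`) or the bare PRS-CS layout.
#' @export
write_weights <- function(weights, path, header = TRUE) {
  out <- data.frame(CHR = weights$chrom, SNP = weights$id, BP = weights$pos,
                    A1 = weights$a1, A2 = weights$a2, EFFECT = weights$effect)
  data.table::fwrite(out, path, sep = "\t", col.names = header)
  invisible(path)
}

#' Write the full synthetic-study fixture
#'
#' Emits the VCF, dosage TSV + variant sidecar, the four
#' summary-statistic TSVs, the phenotype TSV and a JSON manifest holding
#' the configuration (including the seed); [read_fixture()] round-trips
#' the files losslessly.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_fixture <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2L) != 0L)
    stop_structural("directory not writable: ", dir)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             dosage = file.path(dir, "genotypes.dosage.tsv"),
             sidecar = file.path(dir, "variants.bim"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             manifest = file.path(dir, "manifest.json"))
  ss_files <- c("SCZ" = "sumstats_SCZ.tsv", "BPD" = "sumstats_BPD.tsv",
                "SCZ+BPD" = "sumstats_SCZplusBPD.tsv",
                "SCZvsBPD" = "sumstats_SCZvsBPD.tsv")
  write_vcf(study$genotypes, paths[["vcf"]])
  write_dosage(study$genotypes, paths[["dosage"]], paths[["sidecar"]])
  for (ct in names(ss_files)) {
    write_sumstats(study$sumstats[[ct]], file.path(dir, ss_files[[ct]]))
  }
  data.table::fwrite(study$cohort, paths[["phenotypes"]], sep = "\t")
  manifest <- list(seed = study$config$seed,
                   config = unclass(study$config),
                   sumstats = as.list(ss_files),
                   package_version = as.character(utils::packageVersion("crossprs")))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, file.path(dir, ss_files)))
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!identical(as.integer(manifest$seed), as.integer(manifest$config$seed)))
    stop_invalid("manifest seed differs from config seed in ", manifest_path)
  ss <- lapply(manifest$sumstats, function(f)
    read_sumstats(file.path(dir, f)))
  for (ct in names(ss)) attr(ss[[ct]], "label") <- ct
  geno <- read_dosage(file.path(dir, "genotypes.dosage.tsv"),
                      file.path(dir, "variants.bim"),
                      freq = ss[[1]]$FRQ, label = "target")
  cohort <- read_tsv_checked(file.path(dir, "phenotypes.tsv"))
  cohort$birth_cohort <- factor(cohort$birth_cohort,
                                levels = c("<1950", "1950s", "1960s",
                                           "1970s", ">=1980"))
  list(config = manifest$config, genotypes = geno, sumstats = ss,
       cohort = cohort)
}
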
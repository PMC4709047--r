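# Readers and writers for the formats the pipeline touches: VCF (GT only),
# PLINK-style text .ped/.map, covariate and result tables, YAML run
# configuration. Internal coordinates are 1-based throughout, matching VCF
# and the BP columns of published association tables.

empty_sample_meta <- function(ids, cohort_id = NA_character_) {
  data.frame(sample_id = ids, stage = NA_character_, age = NA_real_,
             sex = NA_character_, cohort_id = cohort_id,
             stringsAsFactors = FALSE)
}

# Re-designate A1 as the minor allele across the loaded samples, flipping
# dosages where the counted allele is the major one. Idempotent.
minorize <- function(dos, variants) {
  af <- colSums(dos, na.rm = TRUE) / (2 * pmax(colSums(!is.na(dos)), 1))
  flip <- af > 0.5
  if (any(flip)) {
    dos[, flip] <- 2L - dos[, flip, drop = FALSE]
    tmp <- variants$a1[flip]
    variants$a1[flip] <- variants$a2[flip]
    variants$a2[flip] <- tmp
  }
  variants$flipped <- flip
  list(dosages = dos, variants = variants, n_flipped = sum(flip))
}

#' Read a VCF into a genotype dataset
#'
#' Loads biallelic SNPs from a VCF 4.x file (GT field; phased separators
#' are treated as unphased). A1 is re-designated to the minor allele across
#' the loaded samples — dosages are flipped where needed and the flip is
#' recorded in the `flipped` variant column. Multi-allelic or non-SNP
#' records are skipped with a message. Sample metadata (stage, age, sex)
#' is left `NA` until joined with [read_covariates()].
#'
#' @param path VCF file path (plain text or bgzipped).
#' @return a [genotype_dataset()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fx) == 0) stop("no variant records in ", path)
  ok <- !is.na(fx$ALT) & !grepl(",", fx$ALT) &
    fx$REF %in% c("A", "C", "G", "T") & fx$ALT %in% c("A", "C", "G", "T")
  if (any(!ok))
    message("skipped ", sum(!ok), " multi-allelic or non-SNP record(s)")
  if (!any(ok)) stop("no biallelic SNPs in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[ok, , drop = FALSE]
  fx <- fx[ok, , drop = FALSE]
  gt[] <- gsub("|", "/", gt, fixed = TRUE)
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dos <- matrix(unname(code[gt]), nrow = nrow(gt))  # others -> NA
  dos <- t(dos)                                     # samples x variants
  ids <- fx$ID
  ids[is.na(ids) | ids == "."] <- paste0(fx$CHROM, ":", fx$POS)[is.na(ids) | ids == "."]
  variants <- data.frame(variant_id = ids, chrom = fx$CHROM,
                         pos = as.integer(fx$POS),
                         a1 = fx$ALT, a2 = fx$REF,
                         is_index = FALSE, stringsAsFactors = FALSE)
  m <- minorize(dos, variants)
  genotype_dataset(m$dosages, empty_sample_meta(colnames(gt)), m$variants)
}

#' Write a genotype dataset as a plain-text VCF
#'
#' Emits an uncompressed VCF 4.2 with GT-only genotypes, REF = A2 and
#' ALT = A1, one contig per chromosome present.
#'
#' @param dataset a [genotype_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(dataset, path) {
  v <- dataset$variants
  gtcode <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(dataset$dosages), ncol(dataset$dosages))
  nz <- !is.na(dataset$dosages)
  gt[nz] <- gtcode[dataset$dosages[nz] + 1L]
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", unique(v$chrom), ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", dataset$samples$sample_id),
                 collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$variant_id, v$a2, v$a1, ".", "PASS", ".",
                "GT", apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read PLINK-style text pedigree files
#'
#' Parses a `.ped`/`.map` pair (white-space delimited text). The map order
#' defines variant order; genotypes `0 0` (or any allele `0`) become
#' missing dosages. A1 is re-designated to the minor allele across loaded
#' samples, as in [read_vcf()].
#'
#' @param ped_path,map_path paths to the paired files.
#' @return a [genotype_dataset()]; ped column 5 fills `sex`
#'   (1 = male, 2 = female).
#' @export
read_plink_text <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("chrom", "variant_id", "cm", "pos"),
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  ped <- utils::read.table(ped_path, header = FALSE,
                           colClasses = "character")
  if (ncol(ped) < 8 || (ncol(ped) - 6) %% 2 != 0 ||
      (ncol(ped) - 6) / 2 != nrow(map))
    stop("ped/map mismatch: ", (ncol(ped) - 6) / 2, " genotype pairs vs ",
         nrow(map), " map records")
  n <- nrow(ped)
  m <- nrow(map)
  a1c <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  a2c <- as.matrix(ped[, 6 + 2 * seq_len(m), drop = FALSE])
  a1c[a1c == "0"] <- NA; a2c[a2c == "0"] <- NA
  miss <- is.na(a1c) | is.na(a2c)
  a1c[miss] <- NA; a2c[miss] <- NA
  dos <- matrix(NA_integer_, n, m)
  al1 <- al2 <- character(m)
  for (j in seq_len(m)) {
    obs <- c(a1c[, j], a2c[, j])
    lv <- sort(unique(obs[!is.na(obs)]))
    if (length(lv) > 2)
      stop("more than two alleles at ", map$variant_id[j])
    if (length(lv) == 0) lv <- c("N", "N")
    if (length(lv) == 1) lv <- c(lv, "N")
    # count the first allele; minorize() fixes the orientation below
    dos[, j] <- (a1c[, j] == lv[1]) + (a2c[, j] == lv[1])
    al1[j] <- lv[1]; al2[j] <- lv[2]
  }
  variants <- data.frame(variant_id = map$variant_id, chrom = map$chrom,
                         pos = map$pos, a1 = al1, a2 = al2,
                         is_index = FALSE, stringsAsFactors = FALSE)
  samples <- empty_sample_meta(ped[[2]])
  samples$sex <- c("male", "female")[match(ped[[5]], c("1", "2"))]
  mz <- minorize(dos, variants)
  genotype_dataset(mz$dosages, samples, mz$variants)
}

#' Write PLINK-style text pedigree files
#'
#' @param dataset a [genotype_dataset()].
#' @param ped_path,map_path output paths.
#' @return `ped_path`, invisibly.
#' @export
write_plink_text <- function(dataset, ped_path, map_path) {
  v <- dataset$variants
  utils::write.table(data.frame(v$chrom, v$variant_id, 0, v$pos),
                     map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  s <- dataset$samples
  sexcode <- ifelse(is.na(s$sex), "0", ifelse(s$sex == "male", "1", "2"))
  phe <- ifelse(is.na(s$stage), "-9",
                ifelse(s$stage == "IV", "2",
                       ifelse(s$stage %in% c("I", "II"), "1", "-9")))
  n <- nrow(dataset$dosages)
  geno <- matrix("0", n, 2 * ncol(dataset$dosages))
  for (j in seq_len(ncol(dataset$dosages))) {
    d <- dataset$dosages[, j]
    g1 <- ifelse(is.na(d), "0", ifelse(d >= 1, v$a1[j], v$a2[j]))
    g2 <- ifelse(is.na(d), "0", ifelse(d == 2, v$a1[j], v$a2[j]))
    geno[, 2 * j - 1] <- g1
    geno[, 2 * j] <- g2
  }
  out <- cbind(s$sample_id, s$sample_id, "0", "0", sexcode, phe, geno)
  utils::write.table(out, ped_path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(ped_path)
}

#' Read a covariate table and join it to genotype samples
#'
#' The file must be delimited text with a header containing `sample_id`,
#' `stage`, `age` and `sex` (optionally `cohort_id`). Stage values outside
#' I / II / IV / control raise an error naming the offending row.
#'
#' @param path covariate file path (tab- or whitespace-delimited).
#' @param dataset optional [genotype_dataset()]; if supplied, covariates
#'   are joined by `sample_id` (covariate rows without a genotyped sample
#'   are dropped with a warning, genotyped samples without covariates are
#'   warned about) and the updated dataset is returned.
#' @return a covariate data.frame, or the joined dataset when `dataset`
#'   is given.
#' @export
read_covariates <- function(path, dataset = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  cv <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(cv) == 1)  # fall back to whitespace delimiting
    cv <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("sample_id", "stage", "age", "sex")
  miss <- setdiff(req, names(cv))
  if (length(miss)) stop("covariate file missing required column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(!cv$stage %in% c("I", "II", "IV", "control") & !is.na(cv$stage))
  if (length(bad))
    stop("invalid stage '", cv$stage[bad[1]], "' in covariate row ", bad[1],
         " (sample ", cv$sample_id[bad[1]], ")")
  bad <- which(!cv$sex %in% c("male", "female") & !is.na(cv$sex))
  if (length(bad))
    stop("invalid sex '", cv$sex[bad[1]], "' in covariate row ", bad[1])
  if (!"cohort_id" %in% names(cv)) cv$cohort_id <- NA_character_
  if (is.null(dataset)) return(cv)
  extra <- setdiff(cv$sample_id, dataset$samples$sample_id)
  if (length(extra))
    warning(length(extra), " covariate row(s) without genotyped sample dropped")
  idx <- match(dataset$samples$sample_id, cv$sample_id)
  if (anyNA(idx))
    warning(sum(is.na(idx)), " genotyped sample(s) without covariates")
  hit <- !is.na(idx)
  for (col in c("stage", "age", "sex", "cohort_id"))
    dataset$samples[[col]][hit] <- cv[[col]][idx[hit]]
  genotype_dataset(dataset$dosages, dataset$samples, dataset$variants)
}

#' Write the covariate table of a dataset
#'
#' @param dataset a [genotype_dataset()].
#' @param path output path (tab-delimited, header
#'   `sample_id stage age sex cohort_id`).
#' @return `path`, invisibly.
#' @export
write_covariates <- function(dataset, path) {
  utils::write.table(dataset$samples[, c("sample_id", "stage", "age", "sex",
                                         "cohort_id")],
                     path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Write an association results table
#'
#' Tab-delimited, one row per SNP, in the layout of a published
#' association table: `SNP Chr BP A1 MAF OR L95 U95 P` (the 95% CI split
#' into two numeric columns so round trips are lossless). Numbers carry 6
#' significant digits and the output is byte-stable across runs.
#'
#' @param scan a `genome_scan` object, or its `results` data.frame.
#' @param path output file path.
#' @param dataset the [genotype_dataset()] supplying Chr/BP/A1 (required
#'   when `scan` lacks them).
#' @param mafs optional named vector of reference-group MAFs per variant;
#'   defaults to the scan's reference-group summaries when available.
#' @return the written data.frame, invisibly.
#' @export
write_results_table <- function(scan, path, dataset = NULL, mafs = NULL) {
  res <- if (inherits(scan, "genome_scan")) scan$results else scan
  if (is.null(mafs) && inherits(scan, "genome_scan")) {
    gs <- scan$group_summaries
    ref <- gs[gs$group == "reference", ]
    mafs <- stats::setNames(ref$maf, ref$variant_id)
  }
  vinfo <- if (!is.null(dataset)) dataset$variants
  nr <- nrow(res)
  vcol <- function(col)
    if (!is.null(vinfo)) vinfo[[col]][match(res$variant_id, vinfo$variant_id)]
    else rep(NA, nr)
  tab <- data.frame(
    SNP = res$variant_id, Chr = vcol("chrom"), BP = vcol("pos"),
    A1 = vcol("a1"),
    MAF = if (!is.null(mafs)) as.numeric(mafs[res$variant_id])
          else rep(NA_real_, nr),
    OR = res$or_, L95 = res$ci_lo, U95 = res$ci_hi, P = res$p,
    stringsAsFactors = FALSE)
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", x))
  out <- tab
  for (col in c("MAF", "OR", "L95", "U95", "P")) out[[col]] <- fmt(tab[[col]])
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(tab)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path file path.
#' @return a data.frame with numeric `MAF`, `OR`, `L95`, `U95`, `P`.
#' @export
read_results_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(SNP = "character"))
}

run_config_defaults <- list(
  group_case = "IV", group_ref = c("I", "II"),
  maf_min = 0.01, miss_max = 0.02, call_rate_min = 0.98, hwe_alpha = 1e-6,
  covariates = c("age", "sex"), n_components = 2,
  tier1 = c(9, 0.04), tier2 = c(8, 0.01), power_floor = 0.80,
  n_perm = 10000, ld_tolerance = 1e-6, seed = 1)

#' Read and validate a YAML run configuration
#'
#' Unspecified fields take pipeline defaults (QC thresholds 0.01 / 0.02 /
#' 0.98 / 1e-6, replication budget 9:0.04 + 8:0.01, power floor 0.8,
#' 10,000 permutations).
#'
#' @param path YAML file path.
#' @return a named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  out <- utils::modifyList(run_config_defaults, cfg)
  for (f in c("maf_min", "miss_max", "call_rate_min", "hwe_alpha"))
    if (out[[f]] < 0 || out[[f]] > 1)
      stop(f, " must be a fraction in [0, 1]")
  if (out$n_perm < 100) stop("n_perm must be >= 100")
  structure(out, class = "run_config")
}

#' Write a JSON run manifest
#'
#' Records package version, R version and the parameters of a run, the
#' way pipeline tools log their provenance.
#'
#' @param path output path.
#' @param params named list of parameters to record.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, params = list()) {
  jsonlite::write_json(
    list(tool = "founderscan",
         version = as.character(utils::packageVersion("founderscan")),
         r_version = R.version.string,
         params = params),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
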
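#' Construct a genotype dataset
#'
#' The central container of the pipeline: a sample-by-variant matrix of
#' minor-allele dosages together with sample and variant metadata. Dosages
#' count copies of the effect allele A1, so each non-missing entry is 0, 1
#' or 2; missing genotypes are `NA`.
#'
#' @param dosages integer matrix, samples in rows, variants in columns.
#'   Entries must be 0, 1, 2 or `NA`.
#' @param samples data.frame with columns `sample_id`, `stage` (one of
#'   `"I"`, `"II"`, `"IV"`, `"control"`), `age` (years, > 0), `sex`
#'   (`"male"`/`"female"`) and `cohort_id`.
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based), `a1` (effect/minor allele), `a2` and logical `is_index`.
#'
#' @return an object of class `genotype_dataset` with elements `dosages`,
#'   `samples` and `variants`.
#' @export
genotype_dataset <- function(dosages, samples, variants) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  stopifnot(is.data.frame(samples), is.data.frame(variants))
  if (nrow(dosages) != nrow(samples))
    stop("dosage rows (", nrow(dosages), ") != samples (", nrow(samples), ")")
  if (ncol(dosages) != nrow(variants))
    stop("dosage columns (", ncol(dosages), ") != variants (", nrow(variants), ")")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosages must be 0, 1, 2 or NA")
  req_s <- c("sample_id", "stage", "age", "sex", "cohort_id")
  miss <- setdiff(req_s, names(samples))
  if (length(miss)) stop("samples missing column(s): ", paste(miss, collapse = ", "))
  st <- samples$stage[!is.na(samples$stage)]
  if (!all(st %in% c("I", "II", "IV", "control")))
    stop("stage must be one of I, II, IV, control")
  sx <- samples$sex[!is.na(samples$sex)]
  if (!all(sx %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  req_v <- c("variant_id", "chrom", "pos", "a1", "a2", "is_index")
  miss <- setdiff(req_v, names(variants))
  if (length(miss)) stop("variants missing column(s): ", paste(miss, collapse = ", "))
  if (any(variants$pos <= 0)) stop("positions must be positive (1-based)")
  if (any(variants$a1 == variants$a2)) stop("a1 and a2 must differ")
  rownames(dosages) <- samples$sample_id
  colnames(dosages) <- variants$variant_id
  structure(list(dosages = dosages, samples = samples, variants = variants),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "variants\n")
  st <- table(x$samples$stage)
  cat("  stages:", paste(names(st), st, sep = "=", collapse = ", "), "\n")
  nm <- sum(is.na(x$dosages))
  cat("  missing dosages:", nm,
      sprintf("(%.2f%%)", 100 * nm / length(x$dosages)), "\n")
  if (any(x$variants$is_index))
    cat("  index SNP:", x$variants$variant_id[x$variants$is_index], "\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosages)

#' Subset a genotype dataset by samples
#'
#' @param dataset a `genotype_dataset`
#' @param keep logical or integer index, or a character vector of sample ids
#' @return a `genotype_dataset` restricted to the selected samples
#' @export
subset_samples <- function(dataset, keep) {
  if (is.character(keep)) keep <- match(keep, dataset$samples$sample_id)
  genotype_dataset(dataset$dosages[keep, , drop = FALSE],
                   dataset$samples[keep, , drop = FALSE],
                   dataset$variants)
}

#' Subset a genotype dataset by variants
#'
#' @param dataset a `genotype_dataset`
#' @param keep logical or integer index, or a character vector of variant ids
#' @return a `genotype_dataset` restricted to the selected variants
#' @export
subset_variants <- function(dataset, keep) {
  if (is.character(keep)) keep <- match(keep, dataset$variants$variant_id)
  genotype_dataset(dataset$dosages[, keep, drop = FALSE],
                   dataset$samples,
                   dataset$variants[keep, , drop = FALSE])
}

#' Samples belonging to one or more tumor stages
#'
#' @param dataset a `genotype_dataset`
#' @param stages character vector of stage labels, e.g. `c("I", "II")`
#' @return integer indices of the matching samples
#' @export
stage_samples <- function(dataset, stages) {
  which(dataset$samples$stage %in% stages)
}
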
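#' Peptide traces container
#'
#' The central data structure of the package: a peptides x measurements
#' intensity matrix together with peptide-level and measurement-level
#' metadata. Measurements are either consecutive chromatographic fractions
#' (`trace_kind = "fractionated"`, e.g. SEC-SWATH-MS) or independent samples
#' (`trace_kind = "samplewise"`, e.g. a tissue cohort). Missing observations
#' are stored as `NA`; they are only converted to zero intensity at the
#' correlation stage (non-detection is treated as absence in co-fractionation
#' data).
#'
#' @param intensities numeric matrix, peptides in rows, measurements in
#'   columns. Row names are peptide ids, column names measurement ids.
#' @param peptide_meta `data.frame` with one row per matrix row. Required
#'   columns: `peptide_id`, `protein_id`. Optional annotation columns
#'   (`peptide_sequence`, `start_pos`, `end_pos`, `annotated`, `ambiguous`,
#'   `is_representative`) are added with defaults when absent.
#' @param measurement_meta `data.frame` with one row per matrix column.
#'   Required columns: `measurement_id`, `condition`, `replicate`, `index`
#'   (fraction number for fractionated traces, sample index otherwise).
#' @param trace_kind `"fractionated"` or `"samplewise"`.
#'
#' @return An object of class `peptide_traces`.
#' @export
peptide_traces <- function(intensities, peptide_meta, measurement_meta,
                           trace_kind = c("fractionated", "samplewise")) {
  trace_kind <- match.arg(trace_kind)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  peptide_meta <- as.data.frame(peptide_meta, stringsAsFactors = FALSE)
  measurement_meta <- as.data.frame(measurement_meta, stringsAsFactors = FALSE)

  for (col in c("peptide_id", "protein_id")) {
    if (!col %in% names(peptide_meta)) {
      stop("peptide_meta must contain column '", col, "'")
    }
  }
  if (!"peptide_sequence" %in% names(peptide_meta)) {
    peptide_meta$peptide_sequence <- strip_modifications(peptide_meta$peptide_id)
  }
  n_pep <- nrow(peptide_meta)
  if (!"start_pos" %in% names(peptide_meta)) {
    peptide_meta$start_pos <- rep(NA_integer_, n_pep)
  }
  if (!"end_pos" %in% names(peptide_meta)) {
    peptide_meta$end_pos <- rep(NA_integer_, n_pep)
  }
  if (!"annotated" %in% names(peptide_meta)) {
    peptide_meta$annotated <- rep(FALSE, n_pep)
  }
  if (!"ambiguous" %in% names(peptide_meta)) {
    peptide_meta$ambiguous <- rep(FALSE, n_pep)
  }
  if (!"is_representative" %in% names(peptide_meta)) {
    peptide_meta$is_representative <- rep(TRUE, n_pep)
  }

  for (col in c("measurement_id", "condition", "replicate", "index")) {
    if (!col %in% names(measurement_meta)) {
      stop("measurement_meta must contain column '", col, "'")
    }
  }
  measurement_meta$index <- as.integer(measurement_meta$index)

  rownames(intensities) <- peptide_meta$peptide_id
  colnames(intensities) <- measurement_meta$measurement_id

  x <- structure(
    list(intensities = intensities,
         peptide_meta = peptide_meta,
         measurement_meta = measurement_meta,
         trace_kind = trace_kind),
    class = "peptide_traces"
  )
  validate_peptide_traces(x)
  x
}

#' Validate a peptide_traces object
#'
#' Checks dimensional consistency, uniqueness of ids, non-negativity of
#' observed intensities and, for fractionated traces, strictly increasing
#' fraction indices within each condition x replicate block.
#'
#' @param x a `peptide_traces` object.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_peptide_traces <- function(x) {
  stopifnot(inherits(x, "peptide_traces"))
  if (nrow(x$intensities) != nrow(x$peptide_meta)) {
    stop("row count of intensities does not match peptide_meta")
  }
  if (ncol(x$intensities) != nrow(x$measurement_meta)) {
    stop("column count of intensities does not match measurement_meta")
  }
  if (anyDuplicated(x$peptide_meta$peptide_id)) {
    stop("duplicated peptide_id in peptide_meta")
  }
  if (anyDuplicated(x$measurement_meta$measurement_id)) {
    stop("duplicated measurement_id in measurement_meta")
  }
  obs <- x$intensities[!is.na(x$intensities)]
  if (length(obs) && any(obs < 0)) stop("negative intensities are not allowed")
  if (x$trace_kind == "fractionated") {
    mm <- x$measurement_meta
    for (block in split(mm, paste(mm$condition, mm$replicate, sep = "\r"))) {
      if (any(diff(block$index) <= 0)) {
        stop("fraction indices must be strictly increasing within each ",
             "condition x replicate block")
      }
    }
  }
  invisible(x)
}

#' @export
print.peptide_traces <- function(x, ...) {
  cat(sprintf("peptide_traces (%s): %d peptides / %d proteins x %d measurements\n",
              x$trace_kind, nrow(x$intensities),
              length(unique(x$peptide_meta$protein_id)), ncol(x$intensities)))
  cat(sprintf("  conditions: %s\n",
              paste(unique(x$measurement_meta$condition), collapse = ", ")))
  n_miss <- sum(is.na(x$intensities))
  cat(sprintf("  missing values: %d (%.1f%%)\n", n_miss,
              100 * n_miss / length(x$intensities)))
  invisible(x)
}

#' @export
dim.peptide_traces <- function(x) dim(x$intensities)

# internal: subset rows, keeping metadata aligned
subset_peptides <- function(traces, keep) {
  traces$intensities <- traces$intensities[keep, , drop = FALSE]
  traces$peptide_meta <- traces$peptide_meta[keep, , drop = FALSE]
  rownames(traces$peptide_meta) <- NULL
  traces
}

# internal: NA -> 0 intensity matrix used for all correlation computations
zero_fill <- function(traces) {
  m <- traces$intensities
  m[is.na(m)] <- 0
  m
}

# internal: remove modification tags and charge suffixes from a peptide id,
# leaving the plain amino-acid sequence (e.g. "AAS(UniMod:21)K_2" -> "AASK")
strip_modifications <- function(ids) {
  s <- gsub("\\(.*?\\)|\\[.*?\\]", "", ids)
  s <- sub("_[0-9]+$", "", s)
  gsub("[^A-Za-z]", "", s)
}
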
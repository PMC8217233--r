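#' Preprocessing configuration
#'
#' Bundles the filter chain settings applied before proteoform detection.
#' The defaults reproduce the SEC co-fractionation pipeline (collapse
#' missed-cleavage peptides, impute single-fraction gaps, require >= 3
#' consecutive detected fractions, drop zero-variance peptides, keep only
#' multi-peptide proteins). `mode = "samplewise"` turns off the
#' fraction-specific steps (gap imputation and the consecutive-detection
#' filter), as appropriate for sample x intensity cohort matrices.
#'
#' @param mode `"sec"` or `"samplewise"`.
#' @param min_consecutive minimum run of consecutively detected fractions
#'   (max over condition x replicate blocks) for a peptide to be kept.
#' @param impute_gaps impute missing fractions flanked by two observed ones.
#' @param collapse_overlapping collapse position-overlapping peptides to the
#'   most intense representative (requires position annotation).
#' @param min_peptides_per_protein proteins with fewer surviving peptides
#'   are removed entirely.
#' @param drop_zero_variance remove peptides with zero intensity variance.
#' @param exclude_proteins character vector of protein accessions to drop
#'   before filtering (empty by default).
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(mode = c("sec", "samplewise"),
                              min_consecutive = if (mode[1] == "sec") 3L else 1L,
                              impute_gaps = mode[1] == "sec",
                              collapse_overlapping = TRUE,
                              min_peptides_per_protein = 2L,
                              drop_zero_variance = TRUE,
                              exclude_proteins = character(0)) {
  mode <- match.arg(mode)
  stopifnot(min_consecutive >= 1L, min_peptides_per_protein >= 2L)
  structure(list(mode = mode,
                 min_consecutive = as.integer(min_consecutive),
                 impute_gaps = impute_gaps,
                 collapse_overlapping = collapse_overlapping,
                 min_peptides_per_protein = as.integer(min_peptides_per_protein),
                 drop_zero_variance = drop_zero_variance,
                 exclude_proteins = exclude_proteins),
            class = "preprocess_config")
}

#' Collapse position-overlapping peptides to one representative
#'
#' Within each protein, peptides whose annotated `[start_pos, end_pos]`
#' intervals overlap (directly or through a chain, as produced by missed
#' cleavages) are grouped by transitive closure; only the peptide with the
#' highest total intensity across all measurements is retained per group.
#' Unannotated peptides are never collapsed.
#'
#' @param traces a [peptide_traces] object with positions annotated.
#' @return the traces containing only representative peptides.
#' @export
collapse_overlapping_peptides <- function(traces) {
  pm <- traces$peptide_meta
  totals <- rowSums(traces$intensities, na.rm = TRUE)
  keep <- rep(TRUE, nrow(pm))
  for (prot in unique(pm$protein_id)) {
    idx <- which(pm$protein_id == prot & pm$annotated)
    if (length(idx) < 2L) next
    ord <- idx[order(pm$start_pos[idx], pm$end_pos[idx])]
    # sweep over start-sorted intervals; a new component starts when the
    # next interval begins after the furthest end seen so far
    comp <- integer(length(ord))
    comp_id <- 0L
    reach <- -Inf
    for (k in seq_along(ord)) {
      i <- ord[k]
      if (pm$start_pos[i] > reach) {
        comp_id <- comp_id + 1L
        reach <- pm$end_pos[i]
      } else {
        reach <- max(reach, pm$end_pos[i])
      }
      comp[k] <- comp_id
    }
    for (g in split(ord, comp)) {
      if (length(g) < 2L) next
      best <- g[which.max(totals[g])]
      keep[setdiff(g, best)] <- FALSE
    }
  }
  traces$peptide_meta$is_representative <- keep
  removed <- sum(!keep)
  if (removed) {
    message(sprintf("collapse_overlapping_peptides: removed %d of %d peptides",
                    removed, nrow(pm)))
  }
  subset_peptides(traces, keep)
}

#' Impute single-fraction gaps
#'
#' For fractionated traces, a missing fraction whose immediately preceding
#' and following fractions (within the same condition x replicate block)
#' both carry observed values receives the arithmetic mean of the two
#' flanking intensities. Runs of two or more missing fractions, and gaps at
#' block boundaries, are left untouched. Observed values are never changed.
#'
#' @param traces a fractionated [peptide_traces] object.
#' @return the traces with single gaps imputed.
#' @export
impute_single_gaps <- function(traces) {
  if (traces$trace_kind != "fractionated") {
    stop("gap imputation applies to fractionated traces only")
  }
  mm <- traces$measurement_meta
  mat <- traces$intensities
  n_imputed <- 0L
  for (cols in split(seq_len(nrow(mm)), paste(mm$condition, mm$replicate,
                                              sep = "\r"))) {
    cols <- cols[order(mm$index[cols])]
    if (length(cols) < 3L) next
    contiguous <- diff(mm$index[cols]) == 1L
    for (k in 2:(length(cols) - 1L)) {
      if (!contiguous[k - 1L] || !contiguous[k]) next
      j <- cols[k]
      gap <- is.na(mat[, j]) & !is.na(mat[, cols[k - 1L]]) &
        !is.na(mat[, cols[k + 1L]])
      if (any(gap)) {
        mat[gap, j] <- (mat[gap, cols[k - 1L]] + mat[gap, cols[k + 1L]]) / 2
        n_imputed <- n_imputed + sum(gap)
      }
    }
  }
  if (n_imputed) message(sprintf("impute_single_gaps: imputed %d values",
                                 n_imputed))
  traces$intensities <- mat
  traces
}

#' Filter peptides by consecutive detection
#'
#' Keeps a peptide iff its longest run of observed (post-imputation)
#' fractions, maximized over condition x replicate blocks, reaches
#' `min_consecutive`. A peptide well-detected in any one block therefore
#' survives.
#'
#' @param traces a fractionated [peptide_traces] object.
#' @param min_consecutive minimum run length (default 3).
#' @return the filtered traces.
#' @export
filter_consecutive <- function(traces, min_consecutive = 3L) {
  if (min_consecutive <= 1L) return(traces)
  mm <- traces$measurement_meta
  best <- rep(0L, nrow(traces$intensities))
  for (cols in split(seq_len(nrow(mm)), paste(mm$condition, mm$replicate,
                                              sep = "\r"))) {
    cols <- cols[order(mm$index[cols])]
    obs <- !is.na(traces$intensities[, cols, drop = FALSE])
    runs <- apply(obs, 1L, function(v) {
      r <- rle(v)
      m <- r$lengths[r$values]
      if (length(m)) max(m) else 0L
    })
    best <- pmax(best, runs)
  }
  keep <- best >= min_consecutive
  if (any(!keep)) {
    message(sprintf("filter_consecutive: removed %d of %d peptides",
                    sum(!keep), length(keep)))
  }
  subset_peptides(traces, keep)
}

#' Remove zero-variance peptides
#'
#' Drops peptides whose intensity vector (missing values counted as zero,
#' matching the correlation-stage convention) has zero variance; this also
#' removes entirely unobserved peptides.
#'
#' @param traces a [peptide_traces] object.
#' @return the filtered traces.
#' @export
filter_zero_variance <- function(traces) {
  m <- zero_fill(traces)
  v <- apply(m, 1L, stats::var)
  keep <- v > 0
  if (any(!keep)) {
    message(sprintf("filter_zero_variance: removed %d of %d peptides",
                    sum(!keep), length(keep)))
  }
  subset_peptides(traces, keep)
}

#' Remove proteins with too few peptides
#'
#' @param traces a [peptide_traces] object.
#' @param min_peptides minimum number of surviving peptides per protein
#'   (default 2).
#' @return the filtered traces.
#' @export
filter_single_peptide_proteins <- function(traces, min_peptides = 2L) {
  counts <- table(traces$peptide_meta$protein_id)
  keep_prot <- names(counts)[counts >= min_peptides]
  keep <- traces$peptide_meta$protein_id %in% keep_prot
  if (any(!keep)) {
    message(sprintf(
      "filter_single_peptide_proteins: removed %d proteins (%d peptides)",
      length(counts) - length(keep_prot), sum(!keep)))
  }
  subset_peptides(traces, keep)
}

#' Median-normalize measurement columns
#'
#' Rescales every measurement column so that its median observed intensity
#' equals the global reference (the median of the column medians), making
#' intensities comparable across runs.
#'
#' @param traces a [peptide_traces] object.
#' @return the normalized traces.
#' @export
median_normalize <- function(traces) {
  med <- apply(traces$intensities, 2L, stats::median, na.rm = TRUE)
  ref <- stats::median(med, na.rm = TRUE)
  scale <- ifelse(is.na(med) | med == 0, 1, ref / med)
  traces$intensities <- sweep(traces$intensities, 2L, scale, `*`)
  traces
}

#' Run the full preprocessing chain
#'
#' Applies, in order: protein exclusion list, overlapping-peptide collapse,
#' single-gap imputation, consecutive-detection filter, zero-variance
#' filter, and the multi-peptide protein filter, as configured by
#' [preprocess_config()]. Each stage logs the number of removed peptides or
#' proteins.
#'
#' @param traces a [peptide_traces] object.
#' @param config a [preprocess_config()] object.
#' @return the preprocessed traces.
#' @export
preprocess_traces <- function(traces, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  if (length(config$exclude_proteins)) {
    traces <- subset_peptides(
      traces, !traces$peptide_meta$protein_id %in% config$exclude_proteins)
  }
  if (config$collapse_overlapping && any(traces$peptide_meta$annotated)) {
    traces <- collapse_overlapping_peptides(traces)
  }
  if (config$impute_gaps && traces$trace_kind == "fractionated") {
    traces <- impute_single_gaps(traces)
  }
  if (traces$trace_kind == "fractionated" && config$min_consecutive > 1L) {
    traces <- filter_consecutive(traces, config$min_consecutive)
  }
  if (config$drop_zero_variance) traces <- filter_zero_variance(traces)
  filter_single_peptide_proteins(traces, config$min_peptides_per_protein)
}
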
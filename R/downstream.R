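#' Quantify proteoform groups across samples
#'
#' Aggregates peptide intensities to one profile per proteoform group
#' (protein x cluster) and sample. Outlier peptides from the clustering are
#' excluded; within each group the `topN` peptides by total intensity
#' across the dataset are summed per sample (the default `topN = 1000`
#' effectively includes all group members).
#'
#' @param traces the [peptide_traces] object detection was run on.
#' @param results a `proteoform_results` object; only proteins with
#'   `proteoform_flag` are quantified by default.
#' @param topN number of most intense peptides summed per group (default
#'   1000, i.e. all).
#' @param flagged_only quantify only flagged proteins (default TRUE).
#' @return `data.frame` in long format: `proteoform_id` (protein_id + "_" +
#'   group), `protein_id`, `group`, `n_peptides_used`, `measurement_id`,
#'   `condition`, `intensity`.
#' @export
quantify_proteoforms <- function(traces, results, topN = 1000L,
                                 flagged_only = TRUE) {
  prot <- results$proteins
  if (flagged_only) prot <- prot[prot$proteoform_flag, , drop = FALSE]
  mm <- traces$measurement_meta
  mat <- zero_fill(traces)
  totals <- rowSums(mat)
  out <- vector("list", 0L)
  for (p in prot$protein_id) {
    assign <- results$peptides[results$peptides$protein_id == p &
                                 !results$peptides$outlier, ]
    for (g in sort(unique(assign$group))) {
      peps <- assign$peptide_id[assign$group == g]
      stopifnot(length(peps) >= 1L)
      rows <- match(peps, rownames(mat))
      rows <- rows[order(totals[rows], decreasing = TRUE)]
      rows <- rows[seq_len(min(topN, length(rows)))]
      profile <- colSums(mat[rows, , drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        proteoform_id = paste(p, g, sep = "_"),
        protein_id = p, group = g, n_peptides_used = length(rows),
        measurement_id = mm$measurement_id,
        condition = mm$condition,
        intensity = unname(profile),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(proteoform_id = character(0), protein_id = character(0),
                      group = integer(0), n_peptides_used = integer(0),
                      measurement_id = character(0), condition = character(0),
                      intensity = numeric(0)))
  }
  do.call(rbind, out)
}

#' Two-way ANOVA test for condition-specific proteoform expression
#'
#' For every protein with at least two proteoform groups, fits a
#' fixed-effects two-way ANOVA of log2 proteoform intensity on condition
#' (e.g. tissue), proteoform group and their interaction
#' (`log2(intensity) ~ condition * proteoform`, sequential sums of squares
#' with condition entered first). Zero intensities are replaced by a
#' pseudo-count (half the smallest nonzero intensity by default) before the
#' log transform. The protein-level p-value is the minimum of the condition
#' main-effect and interaction p-values; Bonferroni correction is applied
#' across all tested proteins and proteins are flagged condition-specific
#' at `bonferroni_p <= alpha`. All three term p-values are reported so
#' either convention can be recomputed.
#'
#' @param quant proteoform quantification table from
#'   [quantify_proteoforms()].
#' @param alpha significance threshold on the Bonferroni-corrected p-value
#'   (default 0.01).
#' @param pseudo_count value used for zero intensities before log2; default
#'   half the smallest nonzero intensity in `quant`.
#' @return `data.frame` with one row per tested protein: `protein_id`,
#'   `n_groups`, `p_condition`, `p_proteoform`, `p_interaction`, `p_value`,
#'   `bonferroni_p`, `condition_specific_flag`.
#' @export
anova_condition_specificity <- function(quant, alpha = 0.01,
                                        pseudo_count = NULL) {
  if (length(unique(quant$condition)) < 2L) {
    stop("condition-specificity testing requires at least two conditions")
  }
  if (is.null(pseudo_count)) {
    nz <- quant$intensity[quant$intensity > 0]
    pseudo_count <- if (length(nz)) min(nz) / 2 else 1
  }
  counts <- tapply(quant$group, quant$protein_id,
                   function(g) length(unique(g)))
  proteins <- names(counts)[counts >= 2L]
  out <- vector("list", length(proteins))
  for (i in seq_along(proteins)) {
    sub <- quant[quant$protein_id == proteins[i], ]
    d <- data.frame(
      y = log2(ifelse(sub$intensity > 0, sub$intensity, pseudo_count)),
      condition = factor(sub$condition),
      proteoform = factor(sub$group)
    )
    # interaction df requires replication within condition x proteoform cells
    cells <- table(d$condition, d$proteoform)
    if (any(cells < 2L)) {
      stop("protein ", proteins[i], ": the interaction is not estimable ",
           "without replicate samples per condition x proteoform cell")
    }
    fit <- stats::aov(y ~ condition * proteoform, data = d)
    tab <- summary(fit)[[1]]
    pv <- tab[["Pr(>F)"]]
    terms <- trimws(rownames(tab))
    p_cond <- pv[match("condition", terms)]
    p_form <- pv[match("proteoform", terms)]
    p_int <- pv[match("condition:proteoform", terms)]
    out[[i]] <- data.frame(
      protein_id = proteins[i],
      n_groups = length(unique(sub$group)),
      p_condition = p_cond, p_proteoform = p_form, p_interaction = p_int,
      p_value = min(p_cond, p_int, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(protein_id = character(0), n_groups = integer(0),
                      p_condition = numeric(0), p_proteoform = numeric(0),
                      p_interaction = numeric(0), p_value = numeric(0),
                      bonferroni_p = numeric(0),
                      condition_specific_flag = logical(0)))
  }
  res$bonferroni_p <- stats::p.adjust(res$p_value, method = "bonferroni")
  res$condition_specific_flag <- res$bonferroni_p <= alpha
  res
}
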
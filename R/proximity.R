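#' Sequence-proximity score of a proteoform group
#'
#' Tests whether the peptides of a proteoform group sit closer together in
#' the protein sequence than expected for a random grouping. All annotated
#' peptides of the protein are ranked by start position (average ranks for
#' ties); the score is the sample standard deviation of the group members'
#' ranks divided by the standard deviation of the discrete uniform
#' distribution on 1..N, `sqrt((N^2 - 1) / 12)`, where N is the number of
#' ranked peptides. Tightly clustered groups score near 0, dispersed groups
#' near (or above) 1.
#'
#' @param starts integer vector of start positions of all ranked peptides of
#'   the protein.
#' @param member logical vector marking the group members (>= 2 required).
#' @return the proximity score (nonnegative real).
#' @export
proximity_score <- function(starts, member) {
  stopifnot(length(starts) == length(member), sum(member) >= 2L)
  ranks <- rank(starts)
  n <- length(starts)
  stats::sd(ranks[member]) / sqrt((n^2 - 1) / 12)
}

#' Permutation test for sequence proximity of proteoform groups
#'
#' For each proteoform group of a protein, compares the observed proximity
#' score against a null distribution obtained by randomly shuffling the
#' group membership over the protein's peptide ranks (default 1000
#' permutations). Smaller scores are more extreme (tighter sequence
#' clustering). Two p-values are reported: the classical empirical p-value
#' counts permutations scoring less than *or equal to* the observation;
#' the pseudo p-value counts strictly smaller permutation scores only, so
#' that proteins with very few peptides -- where the observed score may be
#' as low as combinatorially possible yet shared by many permutations --
#' can still be recognized. The `lowest_decile_flag` marks groups whose
#' pseudo p-value is at most 0.1 while the classical empirical p-value is
#' not (the "lowest 10% of possible p-values" report).
#'
#' @param starts integer start positions of the protein's annotated
#'   peptides.
#' @param labels integer group labels aligned to `starts` (`NA` = outlier,
#'   excluded from groups but kept in the ranking universe).
#' @param n_permutations number of random shuffles (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @return `data.frame` with one row per tested group: `group`, `n_in_group`,
#'   `proximity_score`, `empirical_p`, `pseudo_p`, `n_permutations`,
#'   `lowest_decile_flag`.
#' @export
proximity_permutation_test <- function(starts, labels, n_permutations = 1000L,
                                       seed = NULL) {
  stopifnot(length(starts) == length(labels))
  if (!is.null(seed)) set.seed(seed)
  groups <- sort(unique(labels[!is.na(labels)]))
  groups <- groups[vapply(groups, function(g) sum(labels == g, na.rm = TRUE),
                          integer(1)) >= 2L]
  out <- vector("list", length(groups))
  ranks <- rank(starts)
  n <- length(starts)
  denom <- sqrt((n^2 - 1) / 12)
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    member <- !is.na(labels) & labels == g
    obs <- stats::sd(ranks[member]) / denom
    size <- sum(member)
    perm <- numeric(n_permutations)
    for (b in seq_len(n_permutations)) {
      perm[b] <- stats::sd(sample(ranks, size)) / denom
    }
    emp_p <- sum(perm <= obs + 1e-12) / n_permutations
    pseudo_p <- sum(perm < obs - 1e-12) / n_permutations
    out[[gi]] <- data.frame(
      group = g, n_in_group = size, proximity_score = obs,
      empirical_p = emp_p, pseudo_p = pseudo_p,
      n_permutations = n_permutations,
      lowest_decile_flag = pseudo_p <= 0.1 && emp_p > 0.1,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Sequence-proximity analysis of detection results
#'
#' Runs the proximity permutation test for every protein flagged (or,
#' optionally, every scored protein) in a [detect_proteoforms()] result,
#' using the peptide position annotation carried by the traces. Peptides
#' without position annotation are excluded from the ranking with a
#' warning. The per-protein p-value is the minimum over the protein's
#' groups.
#'
#' @param results a `proteoform_results` object.
#' @param traces the annotated [peptide_traces] the detection was run on.
#' @param n_permutations permutations per protein (default 1000).
#' @param seed integer seed for the permutation draws.
#' @param flagged_only test only proteins with `proteoform_flag` (default
#'   TRUE).
#' @return `data.frame` with one row per protein x group, plus columns
#'   `protein_id` and `protein_p` (min empirical p over the protein's
#'   groups).
#' @export
proximity_analysis <- function(results, traces, n_permutations = 1000L,
                               seed = NULL, flagged_only = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  prots <- results$proteins
  if (flagged_only) prots <- prots[prots$proteoform_flag, , drop = FALSE]
  pm <- traces$peptide_meta
  out <- vector("list", nrow(prots))
  n_unannotated <- 0L
  for (i in seq_len(nrow(prots))) {
    prot <- prots$protein_id[i]
    assign <- results$peptides[results$peptides$protein_id == prot, ]
    meta <- pm[match(assign$peptide_id, pm$peptide_id), ]
    ok <- meta$annotated & !is.na(meta$start_pos)
    n_unannotated <- n_unannotated + sum(!ok)
    if (sum(ok) < 4L) next
    res <- proximity_permutation_test(meta$start_pos[ok],
                                      ifelse(assign$outlier[ok], NA_integer_,
                                             assign$group[ok]),
                                      n_permutations = n_permutations)
    if (is.null(res) || !nrow(res)) next
    res$protein_id <- prot
    res$protein_p <- min(res$empirical_p)
    out[[i]] <- res
  }
  if (n_unannotated) {
    warning(n_unannotated,
            " peptide(s) without position annotation were excluded from ",
            "proximity ranking")
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(group = integer(0), n_in_group = integer(0),
                      proximity_score = numeric(0), empirical_p = numeric(0),
                      pseudo_p = numeric(0), n_permutations = integer(0),
                      lowest_decile_flag = logical(0),
                      protein_id = character(0), protein_p = numeric(0))
  }
  res[, c("protein_id", "group", "n_in_group", "proximity_score",
          "empirical_p", "pseudo_p", "n_permutations", "lowest_decile_flag",
          "protein_p")]
}
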
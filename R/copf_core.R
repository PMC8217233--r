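#' Pairwise peptide correlation matrix for one protein
#'
#' Computes all pairwise Pearson correlations between the sibling peptides
#' of a protein over the full concatenated measurement vector (missing
#' values counted as zero intensity). Peptides are ordered lexicographically
#' by peptide id so that all downstream clustering is invariant to the row
#' order of the input.
#'
#' @param traces a [peptide_traces] object.
#' @param protein_id protein accession present in the traces.
#' @return an object of class `correlation_matrix`: list with `protein_id`,
#'   `peptides` (ordered ids) and `r` (symmetric correlation matrix).
#' @export
pairwise_correlations <- function(traces, protein_id) {
  idx <- which(traces$peptide_meta$protein_id == protein_id)
  if (length(idx) < 2L) {
    stop("protein ", protein_id, " has fewer than 2 peptides")
  }
  ids <- traces$peptide_meta$peptide_id[idx]
  ord <- order(ids)
  m <- zero_fill(traces)[idx[ord], , drop = FALSE]
  if (any(apply(m, 1L, stats::var) == 0)) {
    stop("zero-variance peptide for protein ", protein_id,
         "; run filter_zero_variance() first")
  }
  r <- stats::cor(t(m))
  dimnames(r) <- list(ids[ord], ids[ord])
  structure(list(protein_id = protein_id, peptides = ids[ord], r = r),
            class = "correlation_matrix")
}

#' Cluster sibling peptides into two proteoform groups
#'
#' Average-linkage hierarchical clustering on correlation distance
#' (1 - Pearson r), cut into two clusters. Each cluster must contain at
#' least two peptides: peptides that would form a singleton cluster are
#' labeled outliers, removed, and the remainder re-clustered, iterating
#' until both clusters have >= 2 members. If fewer than four non-outlier
#' peptides remain, all remaining peptides are reported as a single group
#' (no proteoform call is possible).
#'
#' @param corr a [pairwise_correlations()] result.
#' @return list with integer vector `labels` (named by peptide id; group 1,
#'   group 2, or `NA` for outliers) and logical vector `outlier`.
#' @export
cluster_two_groups <- function(corr) {
  cut_clusters_in_n(corr, k = 2L)
}

# internal: k-group cut with iterative singleton-outlier removal. The tree
# is cut whenever more than k peptides are active; clusters below the
# minimum size are labeled outliers and removed; once fewer than
# k * min_cluster_size peptides remain after outlier removal (or the
# initial peptide set cannot be cut at all), the remainder is one group.
cut_clusters_in_n <- function(corr, k = 2L, min_cluster_size = 2L) {
  peptides <- corr$peptides
  labels <- stats::setNames(rep(NA_integer_, length(peptides)), peptides)
  active <- peptides
  first_pass <- TRUE
  repeat {
    if (length(active) == 0L) break
    too_few <- length(active) <= k ||
      (!first_pass && length(active) < k * min_cluster_size)
    if (too_few) {
      labels[active] <- 1L
      break
    }
    r_sub <- corr$r[active, active, drop = FALSE]
    hc <- stats::hclust(stats::as.dist(1 - r_sub), method = "average")
    grp <- stats::cutree(hc, k = k)
    sizes <- table(grp)
    small <- names(sizes)[sizes < min_cluster_size]
    if (!length(small)) {
      # relabel groups deterministically by first (lexicographic) member
      first_member <- vapply(split(names(grp), grp), min, character(1))
      new_id <- stats::setNames(rank(first_member), names(first_member))
      labels[names(grp)] <- as.integer(new_id[as.character(grp)])
      break
    }
    active <- names(grp)[!grp %in% as.integer(small)]
    first_pass <- FALSE
  }
  list(labels = labels, outlier = stats::setNames(is.na(labels), peptides))
}

#' Cluster sibling peptides into a data-determined number of groups
#'
#' Alternative clustering strategy that can split the peptides of a protein
#' into more than two proteoform groups. On the same average-linkage
#' dendrogram, candidate cuts k = 1, 2, ... are evaluated (with the same
#' singleton-outlier removal as [cluster_two_groups()]) and scored by the
#' generalized proteoform score (minimum within-cluster mean correlation
#' minus overall mean correlation); the smallest k achieving the maximal
#' score is chosen. If no cut exceeds `min_score` the peptides are reported
#' as one group.
#'
#' @param corr a [pairwise_correlations()] result.
#' @param min_peptides_per_cluster minimum peptides per group (default 2).
#' @param min_score minimum generalized score for a multi-group split
#'   (default 0.1, matching the detection score threshold).
#' @return list with `labels` and `outlier` as in [cluster_two_groups()].
#' @export
cluster_dynamic <- function(corr, min_peptides_per_cluster = 2L,
                            min_score = 0.1) {
  n <- length(corr$peptides)
  k_max <- n %/% min_peptides_per_cluster
  best <- list(labels = stats::setNames(rep(1L, n), corr$peptides),
               outlier = stats::setNames(rep(FALSE, n), corr$peptides))
  best_score <- -Inf
  best_k <- 1L
  for (k in seq_len(k_max)[-1]) {
    cand <- cut_clusters_in_n(corr, k = k,
                              min_cluster_size = min_peptides_per_cluster)
    groups <- unique(cand$labels[!is.na(cand$labels)])
    if (length(groups) < k) next
    sc <- proteoform_score(corr, cand)
    if (is.na(sc$score)) next
    if (sc$score > best_score + 1e-12) {
      best_score <- sc$score
      best <- cand
      best_k <- k
    }
  }
  if (best_k == 1L || best_score < min_score) {
    return(list(labels = stats::setNames(rep(1L, n), corr$peptides),
                outlier = stats::setNames(rep(FALSE, n), corr$peptides)))
  }
  best
}

#' Proteoform score for a clustered correlation matrix
#'
#' The within-cluster correlation is the minimum over clusters of the mean
#' pairwise Pearson correlation inside the cluster; the across-cluster
#' correlation is the mean of all pairwise correlations among the protein's
#' non-outlier peptides; the proteoform score is their difference
#' (within minus across). Outlier peptides are excluded from all averages.
#'
#' @param corr a [pairwise_correlations()] result.
#' @param clustering result of [cluster_two_groups()] or [cluster_dynamic()].
#' @return list with `r_within`, `r_across` and `score` (all `NA` when fewer
#'   than two valid clusters exist).
#' @export
proteoform_score <- function(corr, clustering) {
  labels <- clustering$labels[corr$peptides]
  valid <- !is.na(labels)
  groups <- split(corr$peptides[valid], labels[valid])
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  if (length(groups) < 2L) {
    return(list(r_within = NA_real_, r_across = NA_real_, score = NA_real_))
  }
  mean_offdiag <- function(ids) {
    sub <- corr$r[ids, ids, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }
  r_within <- min(vapply(groups, mean_offdiag, numeric(1)))
  r_across <- mean_offdiag(corr$peptides[valid])
  list(r_within = r_within, r_across = r_across, score = r_within - r_across)
}

#' Fisher z-transformation test for the proteoform score
#'
#' Transforms the within- and across-cluster correlations with the Fisher
#' z-transformation `z = arctanh(r)`, forms the statistic
#' `Z = (z_across - z_within) / sqrt(1/(N-3) + 1/(N-3))` where `N` is the
#' number of measurements over which the correlations were computed, and
#' returns the two-sided normal p-value `2 * (1 - pnorm(|Z|))`. Correlations
#' are clipped to +/- (1 - 1e-12) to avoid infinite z for degenerate,
#' perfectly correlated profiles.
#'
#' @param r_within,r_across correlations in \[-1, 1\].
#' @param n_measurements number of measurements N; must exceed 3.
#' @return list with `Z` and `p_value`.
#' @export
score_pvalue <- function(r_within, r_across, n_measurements) {
  if (n_measurements <= 3L) {
    stop("the Fisher z test requires more than 3 measurements")
  }
  clip <- function(r) pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  z_within <- atanh(clip(r_within))
  z_across <- atanh(clip(r_across))
  se <- sqrt(1 / (n_measurements - 3) + 1 / (n_measurements - 3))
  Z <- (z_across - z_within) / se
  list(Z = Z, p_value = 2 * (1 - stats::pnorm(abs(Z))))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment across proteins (wraps
#' `stats::p.adjust(method = "BH")` after validating the input range).
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return adjusted p-values.
#' @export
adjust_bh <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Detect proteins with multiple functional proteoform groups
#'
#' The main entry point. For every protein with at least two peptides it
#' computes the pairwise peptide correlation matrix, clusters the peptides
#' (two-group cut by default, or the dynamic multi-group strategy), derives
#' the proteoform score and its Fisher-z p-value, and corrects p-values
#' across proteins by the Benjamini-Hochberg procedure. A protein is
#' flagged as having multiple proteoform groups iff
#' `adj_p <= adj_p_threshold` and `score >= score_threshold`; all proteins
#' are reported with full statistics regardless of the flag, supporting
#' pseudo-volcano visualization.
#'
#' @param traces a preprocessed [peptide_traces] object.
#' @param adj_p_threshold adjusted p-value threshold (default 0.1).
#' @param score_threshold minimal proteoform score (default 0.1).
#' @param clustering `"two_groups"` (default) or `"dynamic"`.
#' @return an object of class `proteoform_results`: list with `proteins`
#'   (one row per protein: `protein_id`, `n_peptides`, `n_outliers`,
#'   `n_groups`, `r_within`, `r_across`, `score`, `Z`, `n_measurements`,
#'   `p_value`, `adj_p`, `proteoform_flag`) and `peptides` (one row per
#'   peptide: `protein_id`, `peptide_id`, `group`, `outlier`).
#' @export
detect_proteoforms <- function(traces, adj_p_threshold = 0.1,
                               score_threshold = 0.1,
                               clustering = c("two_groups", "dynamic")) {
  clustering <- match.arg(clustering)
  protein_ids <- sort(unique(traces$peptide_meta$protein_id))
  counts <- table(traces$peptide_meta$protein_id)
  protein_ids <- protein_ids[counts[protein_ids] >= 2L]
  n_meas <- ncol(traces$intensities)

  prot_rows <- vector("list", length(protein_ids))
  pep_rows <- vector("list", length(protein_ids))
  for (i in seq_along(protein_ids)) {
    prot <- protein_ids[i]
    corr <- pairwise_correlations(traces, prot)
    cl <- if (clustering == "dynamic") cluster_dynamic(corr)
          else cluster_two_groups(corr)
    sc <- proteoform_score(corr, cl)
    if (!is.na(sc$score)) {
      test <- score_pvalue(sc$r_within, sc$r_across, n_meas)
    } else {
      test <- list(Z = NA_real_, p_value = NA_real_)
    }
    n_groups <- length(unique(cl$labels[!is.na(cl$labels)]))
    prot_rows[[i]] <- data.frame(
      protein_id = prot,
      n_peptides = length(corr$peptides),
      n_outliers = sum(cl$outlier),
      n_groups = n_groups,
      r_within = sc$r_within,
      r_across = sc$r_across,
      score = sc$score,
      Z = test$Z,
      n_measurements = n_meas,
      p_value = test$p_value,
      stringsAsFactors = FALSE
    )
    pep_rows[[i]] <- data.frame(
      protein_id = prot,
      peptide_id = corr$peptides,
      group = unname(cl$labels[corr$peptides]),
      outlier = unname(cl$outlier[corr$peptides]),
      stringsAsFactors = FALSE
    )
  }
  proteins <- do.call(rbind, prot_rows)
  peptides <- do.call(rbind, pep_rows)
  if (is.null(proteins)) {
    proteins <- data.frame(protein_id = character(0), n_peptides = integer(0),
                           n_outliers = integer(0), n_groups = integer(0),
                           r_within = numeric(0), r_across = numeric(0),
                           score = numeric(0), Z = numeric(0),
                           n_measurements = integer(0), p_value = numeric(0))
    peptides <- data.frame(protein_id = character(0), peptide_id = character(0),
                           group = integer(0), outlier = logical(0))
  }
  proteins$adj_p <- adjust_bh(proteins$p_value)
  proteins$proteoform_flag <- !is.na(proteins$adj_p) &
    proteins$adj_p <= adj_p_threshold &
    !is.na(proteins$score) & proteins$score >= score_threshold
  structure(list(proteins = proteins, peptides = peptides,
                 adj_p_threshold = adj_p_threshold,
                 score_threshold = score_threshold),
            class = "proteoform_results")
}

#' @export
print.proteoform_results <- function(x, ...) {
  cat(sprintf(
    "proteoform_results: %d proteins tested, %d flagged (adj_p <= %g, score >= %g)\n",
    nrow(x$proteins), sum(x$proteins$proteoform_flag),
    x$adj_p_threshold, x$score_threshold))
  invisible(x)
}

#' Write detection results to TSV files
#'
#' @param results a `proteoform_results` object.
#' @param prefix output file prefix; writes `<prefix>_proteins.tsv` and
#'   `<prefix>_peptides.tsv`.
#' @return the prefix, invisibly.
#' @export
write_proteoform_results <- function(results, prefix) {
  data.table::fwrite(results$proteins, paste0(prefix, "_proteins.tsv"),
                     sep = "\t", na = "NA")
  data.table::fwrite(results$peptides, paste0(prefix, "_peptides.tsv"),
                     sep = "\t", na = "NA")
  invisible(prefix)
}
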
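# fixture builders shared across test files; everything is generated in code

# minimal traces from a plain matrix; one protein per `proteins` entry
toy_traces <- function(mat, proteins = rep("P1", nrow(mat)),
                       conditions = rep("c1", ncol(mat)),
                       replicates = rep("1", ncol(mat)),
                       kind = "fractionated",
                       index = NULL) {
  if (is.null(index)) {
    index <- stats::ave(seq_len(ncol(mat)), paste(conditions, replicates),
                        FUN = seq_along)
  }
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("PEP%02d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("m%02d", seq_len(ncol(mat)))
  pids <- rownames(mat)
  if (is.null(pids)) pids <- character(0)
  peptide_traces(
    mat,
    data.frame(peptide_id = pids, protein_id = proteins,
               stringsAsFactors = FALSE),
    data.frame(measurement_id = colnames(mat), condition = conditions,
               replicate = replicates, index = index,
               stringsAsFactors = FALSE),
    trace_kind = kind
  )
}

# traces for one protein with two latent profile groups plus noise
two_group_protein <- function(n1 = 2, n2 = 2, n_meas = 30, noise_sd = 0.05,
                              seed = 1) {
  set.seed(seed)
  base1 <- abs(stats::rnorm(n_meas, 10, 4))
  base2 <- abs(stats::rnorm(n_meas, 10, 4))
  mat <- rbind(
    t(replicate(n1, abs(base1 * (1 + stats::rnorm(n_meas, 0, noise_sd))))),
    t(replicate(n2, abs(base2 * (1 + stats::rnorm(n_meas, 0, noise_sd)))))
  )
  rownames(mat) <- sprintf("PEP%02d", seq_len(n1 + n2))
  toy_traces(mat, kind = "samplewise",
             conditions = rep("c1", n_meas), index = seq_len(n_meas))
}

# hand-built correlation_matrix object
make_corr <- function(r, ids = NULL) {
  n <- nrow(r)
  if (is.null(ids)) ids <- sprintf("PEP%02d", seq_len(n))
  dimnames(r) <- list(ids, ids)
  structure(list(protein_id = "P1", peptides = ids, r = r),
            class = "correlation_matrix")
}

# brute-force best 2-partition (both parts >= 2) maximizing the proteoform
# score; independent oracle for the clustering heuristic
brute_force_partition <- function(r) {
  n <- nrow(r)
  ids <- seq_len(n)
  best <- NULL
  best_score <- -Inf
  mean_od <- function(sub) mean(sub[upper.tri(sub)])
  overall <- mean_od(r)
  for (size in 2:(n - 2)) {
    combs <- utils::combn(ids, size)
    for (j in seq_len(ncol(combs))) {
      a <- combs[, j]
      b <- setdiff(ids, a)
      if (length(b) < 2) next
      rw <- min(mean_od(r[a, a, drop = FALSE]), mean_od(r[b, b, drop = FALSE]))
      sc <- rw - overall
      if (sc > best_score) {
        best_score <- sc
        best <- sort(a)
      }
    }
  }
  list(part = best, score = best_score)
}

# block-diagonal correlation matrix with unit diagonal and 0 off-blocks
block_corr <- function(sizes, r_within) {
  n <- sum(sizes)
  m <- matrix(0, n, n)
  at <- 0
  for (s in sizes) {
    idx <- at + seq_len(s)
    m[idx, idx] <- r_within
    at <- at + s
  }
  diag(m) <- 1
  m
}

# exhaustive proximity null distribution over all size-k subsets of ranks
exhaustive_proximity_null <- function(starts, k) {
  ranks <- rank(starts)
  n <- length(starts)
  denom <- sqrt((n^2 - 1) / 12)
  combs <- utils::combn(seq_len(n), k)
  apply(combs, 2, function(idx) stats::sd(ranks[idx]) / denom)
}
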
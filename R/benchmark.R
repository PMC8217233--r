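#' Generate a synthetic benchmark substrate
#'
#' Simulates a complete-case, sample-wise peptide intensity matrix emulating
#' replicate bottom-up proteomics runs of one cell lysate measured on three
#' days (labels day1/day3/day5, assigned in consecutive blocks of equal
#' size). Each peptide gets a log-normal baseline intensity; all sibling
#' peptides of a protein share a per-run multiplicative effect (log-normal,
#' sdlog 0.15, i.e. ~15% run-to-run loading variation, the repeatability
#' scale of technical replicate SWATH runs) that makes sibling peptides
#' co-vary; on top of that, each peptide x run cell receives independent
#' multiplicative log-normal noise with coefficient of variation
#' `noise_cv`.
#'
#' @param n_proteins number of proteins (default 500).
#' @param peptides_per_protein peptides per protein (default 8; must be
#'   >= 4 for the benchmark to be meaningful).
#' @param n_runs number of runs, divisible by 3 (default 21).
#' @param noise_cv coefficient of variation of the peptide-level
#'   multiplicative noise (default 0.2).
#' @param run_effect_sdlog sdlog of the shared per-protein run effect
#'   (default 0.15).
#' @param seed integer seed.
#' @return a samplewise [peptide_traces] object with no missing values.
#' @export
synth_substrate <- function(n_proteins = 500L, peptides_per_protein = 8L,
                            n_runs = 21L, noise_cv = 0.2,
                            run_effect_sdlog = 0.15, seed = 1L) {
  stopifnot(n_runs %% 3L == 0L)
  set.seed(seed)
  n_pep <- n_proteins * peptides_per_protein
  protein_id <- rep(sprintf("PROT%04d", seq_len(n_proteins)),
                    each = peptides_per_protein)
  peptide_id <- sprintf("%s_PEP%02d", protein_id,
                        rep(seq_len(peptides_per_protein), n_proteins))
  baseline <- stats::rlnorm(n_pep, meanlog = log(1e5), sdlog = 1)
  run_effect <- matrix(stats::rlnorm(n_proteins * n_runs, meanlog = 0,
                                     sdlog = run_effect_sdlog),
                       n_proteins, n_runs)
  sdlog_noise <- sqrt(log(1 + noise_cv^2))
  noise <- if (noise_cv > 0) {
    matrix(stats::rlnorm(n_pep * n_runs, meanlog = -sdlog_noise^2 / 2,
                         sdlog = sdlog_noise), n_pep, n_runs)
  } else {
    matrix(1, n_pep, n_runs)
  }
  mat <- baseline * run_effect[rep(seq_len(n_proteins),
                                   each = peptides_per_protein), ] * noise
  per_day <- n_runs %/% 3L
  day <- rep(c("day1", "day3", "day5"), each = per_day)
  mm <- data.frame(
    measurement_id = sprintf("run%02d", seq_len(n_runs)),
    condition = day,
    replicate = as.character(rep(seq_len(per_day), times = 3L)),
    index = seq_len(n_runs),
    stringsAsFactors = FALSE
  )
  colnames(mat) <- mm$measurement_id
  rownames(mat) <- peptide_id
  peptide_traces(mat,
                 data.frame(peptide_id = peptide_id, protein_id = protein_id,
                            stringsAsFactors = FALSE),
                 mm, trace_kind = "samplewise")
}

#' Prepare a raw replicate dataset as benchmark substrate
#'
#' Filters a sample-wise replicate dataset for use as spike-in substrate:
#' removes control peptides (indexed-retention-time and AQUA standards,
#' matched by protein accession pattern), keeps only peptides observed in
#' every run, drops proteins left with fewer than `min_peptides` peptides
#' and median-normalizes intensities across runs. Charge states of the same
#' peptide are summed at import by [import_long_table()].
#'
#' @param traces a samplewise [peptide_traces] object whose
#'   `measurement_meta$condition` carries the day labels.
#' @param min_peptides minimum peptides per protein (default 4).
#' @param control_pattern regular expression identifying control peptides
#'   by protein accession (default matches iRT and AQUA standards).
#' @return the filtered, normalized [peptide_traces] object.
#' @export
prepare_substrate <- function(traces, min_peptides = 4L,
                              control_pattern = "iRT|AQUA") {
  if (!length(unique(traces$measurement_meta$condition)) ||
      all(traces$measurement_meta$condition == "all")) {
    stop("substrate preparation requires day labels in ",
         "measurement_meta$condition")
  }
  keep <- !grepl(control_pattern, traces$peptide_meta$protein_id,
                 ignore.case = FALSE)
  traces <- subset_peptides(traces, keep)
  complete <- rowSums(is.na(traces$intensities)) == 0L
  traces <- subset_peptides(traces, complete)
  traces <- filter_single_peptide_proteins(traces, min_peptides)
  median_normalize(traces)
}

#' Inject fold-changes and artificial proteoforms into a substrate
#'
#' Introduces quantitative variation by multiplying, per protein, all
#' day-3 and day-5 intensities with two random factors drawn uniformly from
#' `day_factor_range`. Then, for `n_proteoform_proteins` randomly chosen
#' proteins, a specified number of peptides is selected and their day-5
#' intensities additionally multiplied by a proteoform perturbation factor
#' drawn uniformly from `factor_range`, creating a detectable co-varying
#' peptide subgroup. Ground truth is returned alongside the perturbed
#' matrix.
#'
#' @param substrate a prepared samplewise [peptide_traces] object with
#'   condition labels `day1`/`day3`/`day5` and no missing values.
#' @param n_proteoform_proteins number of proteins to receive an artificial
#'   proteoform.
#' @param peptides_perturbed `"one"`, `"two"`, `"half"` or
#'   `"random_2_to_half"` (a per-protein uniform draw between 2 and 50% of
#'   the protein's peptides).
#' @param factor_range range of the proteoform perturbation factor
#'   (default `c(0.01, 0.9)`).
#' @param day_factor_range range of the day-3/day-5 fold-change factors
#'   (default `c(1, 6)`).
#' @param seed integer seed.
#' @return list with `traces` (perturbed matrix) and `truth` (`data.frame`:
#'   `protein_id`, `has_proteoform`, `perturbed_peptides`
#'   (semicolon-joined), `n_perturbed`, `perturbation_factor`,
#'   `day3_factor`, `day5_factor`).
#' @export
inject_proteoforms <- function(substrate, n_proteoform_proteins = 100L,
                               peptides_perturbed = c("two", "one", "half",
                                                      "random_2_to_half"),
                               factor_range = c(0.01, 0.9),
                               day_factor_range = c(1, 6),
                               seed = 1L) {
  peptides_perturbed <- match.arg(peptides_perturbed)
  set.seed(seed)
  mm <- substrate$measurement_meta
  stopifnot(all(c("day3", "day5") %in% mm$condition))
  day3_cols <- which(mm$condition == "day3")
  day5_cols <- which(mm$condition == "day5")
  pm <- substrate$peptide_meta
  mat <- substrate$intensities

  proteins <- unique(pm$protein_id)
  counts <- table(pm$protein_id)
  min_pep <- switch(peptides_perturbed, one = 2L, two = 3L, half = 4L,
                    random_2_to_half = 4L)
  eligible <- proteins[counts[proteins] >= min_pep]
  if (n_proteoform_proteins > length(eligible)) {
    stop("requested ", n_proteoform_proteins,
         " proteoform proteins but only ", length(eligible), " are eligible")
  }
  chosen <- sample(eligible, n_proteoform_proteins)

  truth <- data.frame(
    protein_id = proteins,
    has_proteoform = proteins %in% chosen,
    perturbed_peptides = "",
    n_perturbed = 0L,
    perturbation_factor = NA_real_,
    day3_factor = stats::runif(length(proteins), day_factor_range[1],
                               day_factor_range[2]),
    day5_factor = stats::runif(length(proteins), day_factor_range[1],
                               day_factor_range[2]),
    stringsAsFactors = FALSE
  )

  for (i in seq_along(proteins)) {
    rows <- which(pm$protein_id == proteins[i])
    mat[rows, day3_cols] <- mat[rows, day3_cols] * truth$day3_factor[i]
    mat[rows, day5_cols] <- mat[rows, day5_cols] * truth$day5_factor[i]
    if (!truth$has_proteoform[i]) next
    p <- length(rows)
    n_sel <- switch(peptides_perturbed,
                    one = 1L,
                    two = 2L,
                    half = p %/% 2L,
                    random_2_to_half = sample(2:max(2L, p %/% 2L), 1L))
    sel <- sample(rows, n_sel)
    f <- stats::runif(1L, factor_range[1], factor_range[2])
    mat[sel, day5_cols] <- mat[sel, day5_cols] * f
    truth$perturbed_peptides[i] <- paste(pm$peptide_id[sel], collapse = ";")
    truth$n_perturbed[i] <- n_sel
    truth$perturbation_factor[i] <- f
  }
  substrate$intensities <- mat
  list(traces = substrate, truth = truth)
}

#' Evaluate detection results against benchmark ground truth
#'
#' For each adjusted p-value threshold, computes the true positive rate
#' (flagged true-proteoform proteins / true-proteoform proteins), false
#' positive rate (flagged null proteins / null proteins) and empirical FDR
#' (flagged nulls / all flagged; `NA` when nothing is flagged). Also reports
#' the peptide grouping accuracy: among flagged true proteins with >= 2
#' perturbed peptides, the fraction of perturbed peptides assigned to the
#' minority cluster (for equal-size clusters the better-matching cluster is
#' taken, since cluster labels are exchangeable).
#'
#' @param results a `proteoform_results` object from [detect_proteoforms()].
#' @param truth the truth table from [inject_proteoforms()].
#' @param thresholds adjusted p-value thresholds to sweep (default
#'   `c(0.01, 0.05, 0.1, 0.2)`).
#' @param score_threshold additional minimal proteoform score gate; set to
#'   `-Inf` to evaluate on adjusted p-values alone (default 0.1).
#' @return `data.frame` with one row per threshold: `threshold`,
#'   `n_flagged`, `tp`, `fp`, `tpr`, `fpr`, `fdr`, `grouping_accuracy`.
#' @export
evaluate_benchmark <- function(results, truth,
                               thresholds = c(0.01, 0.05, 0.1, 0.2),
                               score_threshold = 0.1) {
  prot <- results$proteins
  m <- match(prot$protein_id, truth$protein_id)
  if (anyNA(m)) stop("results and truth must share the protein universe")
  is_true <- truth$has_proteoform[m]
  n_true <- sum(is_true)
  n_null <- sum(!is_true)
  scoreable <- !is.na(prot$adj_p)
  score_ok <- scoreable & !is.na(prot$score) & prot$score >= score_threshold

  out <- lapply(thresholds, function(t) {
    flag <- scoreable & prot$adj_p <= t & score_ok
    tp <- sum(flag & is_true)
    fp <- sum(flag & !is_true)
    acc <- grouping_accuracy(results, truth,
                             prot$protein_id[flag & is_true])
    data.frame(threshold = t, n_flagged = tp + fp, tp = tp, fp = fp,
               tpr = if (n_true) tp / n_true else NA_real_,
               fpr = if (n_null) fp / n_null else NA_real_,
               fdr = if (tp + fp) fp / (tp + fp) else NA_real_,
               grouping_accuracy = acc)
  })
  do.call(rbind, out)
}

# internal: fraction of perturbed peptides landing in the minority cluster,
# over flagged true proteins with >= 2 perturbed peptides
grouping_accuracy <- function(results, truth, protein_ids) {
  n_hit <- 0L
  n_tot <- 0L
  for (prot in protein_ids) {
    ti <- truth[truth$protein_id == prot, ]
    if (ti$n_perturbed < 2L) next
    perturbed <- strsplit(ti$perturbed_peptides, ";", fixed = TRUE)[[1]]
    assign <- results$peptides[results$peptides$protein_id == prot &
                                 !results$peptides$outlier, ]
    sizes <- table(assign$group)
    if (length(sizes) < 2L) next
    if (sum(sizes == min(sizes)) == 1L) {
      cand <- as.integer(names(sizes)[which.min(sizes)])
    } else {
      # equal split: cluster labels are exchangeable, score the better match
      tied <- as.integer(names(sizes)[sizes == min(sizes)])
      hits <- vapply(tied, function(g) {
        sum(assign$peptide_id[assign$group == g] %in% perturbed)
      }, integer(1))
      cand <- tied[which.max(hits)]
    }
    in_minority <- assign$peptide_id[assign$group == cand]
    n_hit <- n_hit + sum(perturbed %in% in_minority)
    n_tot <- n_tot + length(perturbed)
  }
  if (n_tot) n_hit / n_tot else NA_real_
}

#' Run a complete desk-scale benchmark
#'
#' Convenience wrapper: generates the synthetic substrate, injects
#' fold-changes and artificial proteoforms, runs proteoform detection and
#' evaluates it against the ground truth.
#'
#' @param peptides_perturbed perturbation mode, see [inject_proteoforms()].
#' @param n_proteins,peptides_per_protein,noise_cv substrate parameters,
#'   see [synth_substrate()].
#' @param n_proteoform_proteins number of injected proteoform proteins.
#' @param factor_range proteoform perturbation factor range.
#' @param thresholds,score_threshold evaluation settings, see
#'   [evaluate_benchmark()].
#' @param seed integer seed governing substrate and injection.
#' @return list with `results`, `truth` and `evaluation`.
#' @export
run_benchmark <- function(peptides_perturbed = "two",
                          n_proteins = 500L, peptides_per_protein = 8L,
                          noise_cv = 0.2, n_proteoform_proteins = 100L,
                          factor_range = c(0.01, 0.9),
                          thresholds = c(0.01, 0.05, 0.1, 0.2),
                          score_threshold = 0.1, seed = 1L) {
  substrate <- synth_substrate(n_proteins = n_proteins,
                               peptides_per_protein = peptides_per_protein,
                               noise_cv = noise_cv, seed = seed)
  bench <- inject_proteoforms(substrate,
                              n_proteoform_proteins = n_proteoform_proteins,
                              peptides_perturbed = peptides_perturbed,
                              factor_range = factor_range,
                              seed = seed + 1L)
  results <- detect_proteoforms(bench$traces)
  list(results = results, truth = bench$truth,
       evaluation = evaluate_benchmark(results, bench$truth,
                                       thresholds = thresholds,
                                       score_threshold = score_threshold))
}
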
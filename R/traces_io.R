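#' Import a long-format peptide quantification table
#'
#' Reads a delimited long table (one row per peptide x measurement, as
#' produced by OpenSWATH-style feature alignment or generic peptide
#' quantification exports) and pivots it into a [peptide_traces] matrix.
#' Duplicate (peptide, measurement) rows -- typically precursor charge
#' states -- are summed; absent pairs become missing values (`NA`).
#'
#' @param path path to a tab- or comma-delimited text file.
#' @param column_map named character vector mapping the roles `peptide`,
#'   `protein`, `measurement`, `intensity` (required) and `condition`,
#'   `replicate`, `fraction` (optional) to column names in the file.
#' @param trace_kind `"fractionated"` or `"samplewise"`. For fractionated
#'   data without a `fraction` column the measurement id must be an integer
#'   fraction number.
#' @return a [peptide_traces] object with peptides sorted by protein then
#'   peptide id, and measurements ordered condition-block-wise by fraction /
#'   sample index.
#' @export
import_long_table <- function(path,
                              column_map = c(peptide = "peptide_id",
                                             protein = "protein_id",
                                             measurement = "filename",
                                             intensity = "intensity"),
                              trace_kind = c("samplewise", "fractionated")) {
  trace_kind <- match.arg(trace_kind)
  dt <- data.table::fread(path, header = TRUE, sep = "auto")
  required <- c("peptide", "protein", "measurement", "intensity")
  missing_roles <- setdiff(required, names(column_map))
  if (length(missing_roles)) {
    stop("column_map must define roles: ", paste(missing_roles, collapse = ", "))
  }
  absent <- setdiff(unname(column_map), names(dt))
  if (length(absent)) {
    stop("input table is missing mandatory column(s): ",
         paste(absent, collapse = ", "))
  }

  raw_int <- dt[[column_map[["intensity"]]]]
  num_int <- suppressWarnings(as.numeric(raw_int))
  bad <- which(!is.na(raw_int) & is.na(num_int) & trimws(as.character(raw_int)) != "")
  if (length(bad)) {
    stop("non-numeric intensity value '", raw_int[bad[1]],
         "' in data row ", bad[1])
  }

  long <- data.table::data.table(
    peptide_id = as.character(dt[[column_map[["peptide"]]]]),
    protein_id = as.character(dt[[column_map[["protein"]]]]),
    measurement_id = as.character(dt[[column_map[["measurement"]]]]),
    intensity = num_int
  )
  long$condition <- if ("condition" %in% names(column_map)) {
    as.character(dt[[column_map[["condition"]]]])
  } else "all"
  long$replicate <- if ("replicate" %in% names(column_map)) {
    as.character(dt[[column_map[["replicate"]]]])
  } else "1"
  if ("fraction" %in% names(column_map)) {
    long$index <- as.integer(dt[[column_map[["fraction"]]]])
  } else if (trace_kind == "fractionated") {
    long$index <- suppressWarnings(as.integer(long$measurement_id))
    if (anyNA(long$index)) {
      stop("fractionated import requires a 'fraction' column or integer ",
           "measurement ids")
    }
  } else {
    long$index <- NA_integer_
  }

  mm <- unique(long[, c("measurement_id", "condition", "replicate", "index")])
  if (anyDuplicated(mm$measurement_id)) {
    stop("inconsistent condition/replicate/fraction annotation per measurement")
  }
  if (trace_kind == "samplewise") {
    mm <- mm[order(mm$condition, mm$replicate, mm$measurement_id), ]
    mm$index <- stats::ave(seq_len(nrow(mm)), paste(mm$condition, mm$replicate),
                           FUN = seq_along)
  } else {
    mm <- mm[order(mm$condition, mm$replicate, mm$index), ]
  }

  # one protein per peptide; ambiguous mappings keep the first listed protein
  pep_map <- unique(long[, c("peptide_id", "protein_id")])
  pep_map <- pep_map[!duplicated(pep_map$peptide_id), ]
  pep_map <- pep_map[order(pep_map$protein_id, pep_map$peptide_id), ]

  wide <- data.table::dcast(long, peptide_id ~ measurement_id,
                            value.var = "intensity",
                            fun.aggregate = function(v) sum(v, na.rm = TRUE),
                            fill = NA)
  wide_df <- as.data.frame(wide)
  mat <- as.matrix(wide_df[, setdiff(names(wide_df), "peptide_id"),
                           drop = FALSE])
  rownames(mat) <- wide_df$peptide_id
  mat <- mat[pep_map$peptide_id, mm$measurement_id, drop = FALSE]

  peptide_traces(
    intensities = mat,
    peptide_meta = data.frame(peptide_id = pep_map$peptide_id,
                              protein_id = pep_map$protein_id,
                              stringsAsFactors = FALSE),
    measurement_meta = as.data.frame(mm),
    trace_kind = trace_kind
  )
}

#' Annotate peptide start/end positions from a protein FASTA
#'
#' Locates each peptide sequence in the canonical sequence of its parent
#' protein and records 1-based, end-inclusive coordinates. UniProt-style
#' headers (`sp|ACC|NAME`) are parsed for the accession. Peptides absent
#' from their protein (or whose protein is absent from the FASTA) stay
#' unannotated and are excluded from sequence-proximity analysis only;
#' peptides matching at multiple positions take the first occurrence and
#' are flagged ambiguous. The intensity matrix is never modified.
#'
#' @param traces a [peptide_traces] object.
#' @param fasta path to a protein FASTA file, or a named character vector /
#'   `Biostrings::AAStringSet` of protein sequences keyed by accession.
#' @return the traces with `start_pos`, `end_pos`, `annotated` and
#'   `ambiguous` filled in `peptide_meta`.
#' @export
annotate_peptide_positions <- function(traces, fasta) {
  seqs <- read_protein_fasta(fasta)
  pm <- traces$peptide_meta
  pm$start_pos <- NA_integer_
  pm$end_pos <- NA_integer_
  pm$annotated <- FALSE
  pm$ambiguous <- FALSE
  for (i in seq_len(nrow(pm))) {
    prot <- seqs[pm$protein_id[i]]
    pep <- pm$peptide_sequence[i]
    if (is.na(prot) || is.na(pep) || !nzchar(pep)) next
    hits <- gregexpr(pep, prot, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    pm$start_pos[i] <- as.integer(hits[1])
    pm$end_pos[i] <- as.integer(hits[1]) + nchar(pep) - 1L
    pm$annotated[i] <- TRUE
    pm$ambiguous[i] <- length(hits) > 1L
  }
  traces$peptide_meta <- pm
  traces
}

# internal: FASTA (or pre-parsed vector) -> named character vector of
# sequences keyed by accession
read_protein_fasta <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    aa <- Biostrings::readAAStringSet(fasta)
    seqs <- as.character(aa)
    names(seqs) <- parse_fasta_accession(names(aa))
  } else if (inherits(fasta, "AAStringSet")) {
    seqs <- as.character(fasta)
    names(seqs) <- parse_fasta_accession(names(fasta))
  } else if (is.character(fasta) && !is.null(names(fasta))) {
    seqs <- fasta
  } else {
    stop("fasta must be a file path, an AAStringSet, or a named character vector")
  }
  seqs
}

# internal: "sp|P12345|NAME description" -> "P12345"; otherwise first token
parse_fasta_accession <- function(headers) {
  first <- sub("\\s.*$", "", headers)
  vapply(first, function(h) {
    parts <- strsplit(h, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2L) parts[2] else parts[1]
  }, character(1), USE.NAMES = FALSE)
}

#' Calibrate fraction number to molecular weight
#'
#' Fits a log-linear molecular-weight calibration for SEC fractions by
#' ordinary least squares of log10(MW) on fraction number, from a table of
#' measured standard proteins.
#'
#' @param standards `data.frame` with columns `fraction` and `mw` (kDa).
#' @return an object of class `mw_calibration` with elements `slope` and
#'   `intercept` (log10 kDa scale); use [predict.mw_calibration()] to map
#'   fractions to kDa.
#' @export
calibrate_mw <- function(standards) {
  standards <- as.data.frame(standards)
  if (!all(c("fraction", "mw") %in% names(standards))) {
    stop("standards must have columns 'fraction' and 'mw'")
  }
  if (length(unique(standards$fraction)) < 2L) {
    stop("at least two distinct standard fractions are required")
  }
  if (any(standards$mw <= 0)) stop("molecular weights must be positive")
  fit <- stats::lm(log10(mw) ~ fraction, data = standards)
  co <- stats::coef(fit)
  if (!is.finite(co[["fraction"]])) stop("calibration fit is degenerate")
  if (co[["fraction"]] >= 0) {
    warning("calibration slope is non-negative; SEC expects MW to decrease ",
            "with fraction number")
  }
  structure(list(slope = unname(co[["fraction"]]),
                 intercept = unname(co[["(Intercept)"]]),
                 standards = standards),
            class = "mw_calibration")
}

#' Predict molecular weight (kDa) for fraction numbers
#'
#' @param object an `mw_calibration` object from [calibrate_mw()].
#' @param fraction numeric vector of fraction numbers.
#' @param ... unused.
#' @return numeric vector of molecular weights in kDa.
#' @export
predict.mw_calibration <- function(object, fraction, ...) {
  10^(object$intercept + object$slope * fraction)
}

#' @export
print.mw_calibration <- function(x, ...) {
  cat(sprintf("MW calibration: log10(kDa) = %.4f %+.4f * fraction (%d standards)\n",
              x$intercept, x$slope, nrow(x$standards)))
  invisible(x)
}

#' Integrate replicate measurements within each condition
#'
#' Collapses replicates to one column per condition x fraction (or
#' condition x sample index) using the arithmetic mean of the available
#' (non-missing) replicate values; a cell missing in every replicate stays
#' missing.
#'
#' @param traces a [peptide_traces] object.
#' @return a [peptide_traces] object with replicate label `"integrated"`.
#' @export
integrate_replicates <- function(traces) {
  mm <- traces$measurement_meta
  u <- unique(mm[, c("condition", "index")])
  u <- u[order(match(u$condition, unique(mm$condition)), u$index), , drop = FALSE]
  new_mat <- matrix(NA_real_, nrow(traces$intensities), nrow(u))
  for (j in seq_len(nrow(u))) {
    cols <- which(mm$condition == u$condition[j] & mm$index == u$index[j])
    v <- rowMeans(traces$intensities[, cols, drop = FALSE], na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    new_mat[, j] <- v
  }
  new_mm <- data.frame(
    measurement_id = paste(u$condition, u$index, sep = "_"),
    condition = u$condition,
    replicate = "integrated",
    index = u$index,
    stringsAsFactors = FALSE
  )
  colnames(new_mat) <- new_mm$measurement_id
  rownames(new_mat) <- rownames(traces$intensities)
  peptide_traces(new_mat, traces$peptide_meta, new_mm, traces$trace_kind)
}

#' Concatenate measurement profiles across conditions
#'
#' Orders the measurement columns condition-block-wise (fraction / sample
#' index ascending within each block) so that downstream correlations are
#' computed on the full concatenated profile spanning all conditions. The
#' peptide universe is the union over conditions; a peptide not observed in
#' a condition carries missing values across that block.
#'
#' @param traces a [peptide_traces] object.
#' @return the traces with columns in condition-block order.
#' @export
concat_conditions <- function(traces) {
  mm <- traces$measurement_meta
  ord <- order(match(mm$condition, unique(mm$condition)),
               match(mm$replicate, unique(mm$replicate)),
               mm$index)
  traces$measurement_meta <- mm[ord, , drop = FALSE]
  rownames(traces$measurement_meta) <- NULL
  traces$intensities <- traces$intensities[, ord, drop = FALSE]
  traces
}

#' Write / read peptide traces as plain TSV files
#'
#' `write_traces()` exports the intensity matrix, peptide annotation and
#' measurement annotation as three tab-separated files with stable column
#' names (`<prefix>_matrix.tsv`, `<prefix>_peptides.tsv`,
#' `<prefix>_measurements.tsv`); `read_traces()` reads them back, giving a
#' bit-exact round trip.
#'
#' @param traces a [peptide_traces] object.
#' @param prefix file path prefix (directory must exist).
#' @return `write_traces()` the prefix, invisibly; `read_traces()` a
#'   [peptide_traces] object.
#' @export
write_traces <- function(traces, prefix) {
  # doubles are written with 17 significant digits so the round trip is exact
  chr <- format(traces$intensities, digits = 17, scientific = TRUE,
                trim = TRUE)
  chr[is.na(traces$intensities)] <- NA_character_
  mat <- data.frame(peptide_id = rownames(traces$intensities), chr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(mat, paste0(prefix, "_matrix.tsv"), sep = "\t", na = "NA")
  data.table::fwrite(traces$peptide_meta, paste0(prefix, "_peptides.tsv"),
                     sep = "\t", na = "NA")
  mm <- traces$measurement_meta
  mm$trace_kind <- traces$trace_kind
  data.table::fwrite(mm, paste0(prefix, "_measurements.tsv"), sep = "\t",
                     na = "NA")
  invisible(prefix)
}

#' @rdname write_traces
#' @export
read_traces <- function(prefix) {
  mat_df <- as.data.frame(data.table::fread(
    paste0(prefix, "_matrix.tsv"), sep = "\t",
    colClasses = list(character = "peptide_id")))
  pm <- as.data.frame(data.table::fread(
    paste0(prefix, "_peptides.tsv"), sep = "\t",
    colClasses = list(character = c("peptide_id", "protein_id",
                                    "peptide_sequence"),
                      integer = c("start_pos", "end_pos"),
                      logical = c("annotated", "ambiguous",
                                  "is_representative"))))
  mm <- as.data.frame(data.table::fread(
    paste0(prefix, "_measurements.tsv"), sep = "\t",
    colClasses = list(character = c("measurement_id", "condition",
                                    "replicate"))))
  kind <- mm$trace_kind[1]
  mm$trace_kind <- NULL
  mat <- as.matrix(mat_df[, setdiff(names(mat_df), "peptide_id"),
                          drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- mat_df$peptide_id
  peptide_traces(mat, pm, mm, kind)
}
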
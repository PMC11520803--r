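# Reading, writing and cleaning interaction tables.

#' Read an interaction table from CSV/TSV
#'
#' Expects a delimited text file with header columns
#' `compound_id, smiles, target_id, sequence, affinity, measure` and
#' optionally `label`, `source`, `variant`. Rows whose affinity cannot be
#' parsed as a number (when a measure other than BINARY is declared) are
#' dropped and reported with their line numbers rather than aborting the
#' read.
#'
#' @param path File path.
#' @param delim Field delimiter; `"\t"` (default) or `","`. `NULL` guesses
#'   from the file extension.
#' @return A list with elements `records` (a [cti_records()] table) and
#'   `failures` (data frame of line numbers and reasons for rejected rows).
#' @export
read_interaction_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  req <- c("compound_id", "smiles", "target_id", "sequence",
           "affinity", "measure")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  label <- if ("label" %in% names(raw)) raw$label else rep(NA, n)
  source <- if ("source" %in% names(raw)) raw$source else rep("SYNTHETIC", n)
  variant <- if ("variant" %in% names(raw)) raw$variant else rep("UNKNOWN", n)

  aff <- suppressWarnings(as.numeric(raw$affinity))
  lab <- suppressWarnings(as.integer(label))
  lab[is.na(label) | label == ""] <- NA_integer_

  # header is line 1, data row i is file line i + 1
  bad_aff <- is.na(aff) & raw$measure != "BINARY" &
    !(is.na(raw$affinity) | raw$affinity == "")
  bad_lab <- !is.na(label) & label != "" & is.na(lab)
  keep <- !(bad_aff | bad_lab)
  failures <- data.frame(
    line = which(!keep) + 1L,
    reason = ifelse(bad_aff[!keep], "unparseable_affinity", "unparseable_label"),
    stringsAsFactors = FALSE
  )
  records <- cti_records(
    compound_id = raw$compound_id[keep],
    smiles = raw$smiles[keep],
    target_id = raw$target_id[keep],
    sequence = raw$sequence[keep],
    affinity_value = aff[keep],
    measure = raw$measure[keep],
    label = lab[keep],
    source = source[keep],
    variant = variant[keep]
  )
  list(records = records, failures = failures)
}

#' Write an interaction table
#'
#' Inverse of [read_interaction_table()]: writing then reading a valid table
#' reproduces the records exactly.
#'
#' @param records A `cti_records` table.
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(records, path, delim = "\t") {
  validate_cti_records(records)
  out <- data.frame(
    compound_id = records$compound_id,
    smiles = records$smiles,
    target_id = records$target_id,
    sequence = records$sequence,
    affinity = records$affinity_value,
    measure = records$measure,
    label = records$label,
    source = records$source,
    variant = records$variant,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = delim, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Default binarization thresholds
#'
#' Affinity cut-offs used to turn continuous affinities into binary
#' interaction labels: a KiBA score is a hit when it is at most
#' `kiba_max_hit` (default 3), and a dissociation constant in micromolar is
#' a hit when strictly below `kd_um_hit` (default 10).
#'
#' @param kiba_max_hit Inclusive KiBA-score hit threshold.
#' @param kd_um_hit Exclusive Kd hit threshold in micromolar.
#' @return Named list of thresholds.
#' @export
cti_thresholds <- function(kiba_max_hit = 3, kd_um_hit = 10) {
  stopifnot(is.numeric(kiba_max_hit), is.numeric(kd_um_hit))
  list(kiba_max_hit = kiba_max_hit, kd_um_hit = kd_um_hit)
}

#' Binarize an affinity value into an interaction label
#'
#' KiBA scores label 1 iff `value <= kiba_max_hit` (lower score = stronger
#' binding under this convention); micromolar Kd labels 1 iff
#' `value < kd_um_hit` (values at or above the threshold are non-binders);
#' `BINARY` passes through after checking domain.
#'
#' @param value Numeric affinity (finite); vectorized.
#' @param measure One of [cti_measures()] (scalar or vector).
#' @param thresholds See [cti_thresholds()].
#' @return Integer vector of 0/1 labels.
#' @export
binarize_affinity <- function(value, measure, thresholds = cti_thresholds()) {
  if (length(measure) == 1) measure <- rep(measure, length(value))
  stopifnot(length(measure) == length(value))
  bad <- !(measure %in% cti_measures())
  if (any(bad)) stop("unknown measure: ", paste(unique(measure[bad]), collapse = ", "))
  if (any(!is.finite(value))) stop("affinity values must be finite")
  out <- integer(length(value))
  ki <- measure == "KIBA_SCORE"
  kd <- measure == "KD_MICROMOLAR"
  bi <- measure == "BINARY"
  out[ki] <- as.integer(value[ki] <= thresholds$kiba_max_hit)
  out[kd] <- as.integer(value[kd] < thresholds$kd_um_hit)
  if (any(bi)) {
    v <- value[bi]
    if (any(!(v %in% c(0, 1)))) stop("BINARY affinity values must be 0 or 1")
    out[bi] <- as.integer(v)
  }
  out
}

#' Filter an interaction table for modelling
#'
#' Removes records that the featurization stack cannot represent: target
#' sequences longer than `max_seq_len` residues, SMILES longer than
#' `max_smiles_len` characters, unparseable SMILES (optional), and exact
#' duplicate (canonical SMILES, sequence, label) triples. Canonicalization
#' happens before deduplication so two spellings of the same molecule count
#' as duplicates. The operation is idempotent.
#'
#' @param records A `cti_records` table.
#' @param max_seq_len Maximum residue count retained (default 1400).
#' @param max_smiles_len Maximum SMILES character count retained (default
#'   348, the width of the one-hot encoder).
#' @param require_parseable Drop records whose SMILES the chemistry backend
#'   cannot parse?
#' @return A list with `records` (kept rows) and `report`: per-reason counts
#'   and the offending compound/target ids.
#' @export
preprocess_records <- function(records, max_seq_len = 1400,
                               max_smiles_len = 348,
                               require_parseable = TRUE) {
  validate_cti_records(records)
  n <- nrow(records)
  reason <- rep(NA_character_, n)

  too_long_seq <- nchar(records$sequence) > max_seq_len
  reason[too_long_seq] <- "sequence_too_long"

  too_long_smi <- is.na(reason) & nchar(records$smiles) > max_smiles_len
  reason[too_long_smi] <- "smiles_too_long"

  canon <- records$smiles
  if (require_parseable) {
    idx <- which(is.na(reason))
    can <- smiles_canonical(records$smiles[idx], error_on_fail = FALSE)
    bad <- is.na(can)
    reason[idx[bad]] <- "smiles_unparseable"
    canon[idx[!bad]] <- can[!bad]
  }

  key <- paste(canon, records$sequence, records$label, sep = "\r")
  dup <- is.na(reason) & duplicated(key)
  reason[dup] <- "duplicate"

  keep <- is.na(reason)
  reasons_all <- c("sequence_too_long", "smiles_too_long",
                   "smiles_unparseable", "duplicate")
  counts <- vapply(reasons_all, function(r) sum(reason == r, na.rm = TRUE), 0L)
  excluded <- data.frame(
    compound_id = records$compound_id[!keep],
    target_id = records$target_id[!keep],
    reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cti_records", "data.frame")
  list(
    records = out,
    report = list(n_in = n, n_kept = sum(keep),
                  counts = as.list(counts), excluded = excluded)
  )
}

#' Write an exclusion report as JSON
#'
#' @param report The `report` element returned by [preprocess_records()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(report, path) {
  jsonlite::write_json(
    list(n_in = report$n_in, n_kept = report$n_kept,
         counts = report$counts,
         excluded = report$excluded),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read target sequences from a FASTA file
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Named character vector (names are FASTA ids).
#' @export
read_targets_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  names(out) <- sub("\\s.*$", "", names(aa))
  out
}

#' Write target sequences to a FASTA file
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_targets_fasta <- function(sequences, path) {
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read compounds from a SMI file
#'
#' One compound per line: a SMILES string optionally followed by whitespace
#' and an identifier.
#'
#' @param path SMI file path.
#' @return Named character vector of SMILES (names are compound ids;
#'   `cmp<k>` when the file has no id column).
#' @export
read_compounds_smi <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  smi <- vapply(parts, `[`, "", 1)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2) parts[[i]][2] else sprintf("cmp%d", i)
  }, "")
  stats::setNames(smi, ids)
}

#' Write compounds to a SMI file
#' @param smiles Named character vector of SMILES.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_compounds_smi <- function(smiles, path) {
  ids <- names(smiles)
  if (is.null(ids)) ids <- sprintf("cmp%d", seq_along(smiles))
  writeLines(paste(smiles, ids, sep = "\t"), path)
  invisible(path)
}
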
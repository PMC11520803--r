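# Core record container: a compound-target interaction table.

#' Canonical amino-acid alphabet
#'
#' The 20 standard one-letter residue codes, in alphabetical order. This
#' ordering fixes the column order of all sequence one-hot and
#' physicochemical matrices produced by the package.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Affinity measures understood by the toolkit
#' @return Character vector of measure codes.
#' @export
cti_measures <- function() c("KIBA_SCORE", "KD_MICROMOLAR", "BINARY")

#' Construct a compound-target interaction table
#'
#' Builds the canonical record table used throughout the toolkit. Each row is
#' one compound-target pair with an affinity readout and (optionally) a
#' binary interaction label and a wild-type/mutant variant flag.
#'
#' @param compound_id Character, opaque compound identifiers.
#' @param smiles Character, SMILES strings (non-empty).
#' @param target_id Character, opaque target identifiers.
#' @param sequence Character, amino-acid sequences over the 20-letter
#'   alphabet (see [aa_alphabet()]).
#' @param affinity_value Numeric affinity in the units of `measure`.
#' @param measure Character, one of [cti_measures()].
#' @param label Integer 0/1 or `NA` when not yet assigned.
#' @param source Character provenance tag (e.g. `"KiBA"`, `"SYNTHETIC"`).
#' @param variant One of `"WILD"`, `"MUTANT"`, `"UNKNOWN"`.
#' @param validate Check invariants (sequence alphabet, label domain)?
#' @return A `data.frame` of class `cti_records`.
#' @export
cti_records <- function(compound_id, smiles, target_id, sequence,
                        affinity_value = NA_real_,
                        measure = "BINARY",
                        label = NA_integer_,
                        source = "SYNTHETIC",
                        variant = "UNKNOWN",
                        validate = TRUE) {
  df <- data.frame(
    compound_id = as.character(compound_id),
    smiles = as.character(smiles),
    target_id = as.character(target_id),
    sequence = as.character(sequence),
    affinity_value = as.numeric(affinity_value),
    measure = as.character(measure),
    label = as.integer(label),
    source = as.character(source),
    variant = as.character(variant),
    stringsAsFactors = FALSE
  )
  class(df) <- c("cti_records", "data.frame")
  if (validate) validate_cti_records(df)
  df
}

#' Validate a cti_records table
#'
#' Checks the container invariants: labels in \{0, 1, NA\}, sequences over
#' the canonical alphabet, non-empty SMILES, known measures and variant
#' flags. Errors on the first violated invariant.
#'
#' @param records A `cti_records` data frame.
#' @return The input, invisibly, if valid.
#' @export
validate_cti_records <- function(records) {
  req <- c("compound_id", "smiles", "target_id", "sequence",
           "affinity_value", "measure", "label", "source", "variant")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    stop("records table is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  lab <- records$label
  bad_lab <- !is.na(lab) & !(lab %in% c(0L, 1L))
  if (any(bad_lab)) {
    stop("labels must be 0, 1 or NA; offending rows: ",
         paste(utils::head(which(bad_lab), 5), collapse = ", "))
  }
  if (any(!nzchar(records$smiles) | is.na(records$smiles))) {
    stop("SMILES strings must be non-empty")
  }
  ok_seq <- grepl(paste0("^[", paste(aa_alphabet(), collapse = ""), "]+$"),
                  records$sequence)
  if (any(!ok_seq)) {
    stop("sequences must use only the 20 canonical amino-acid letters; ",
         "offending rows: ",
         paste(utils::head(which(!ok_seq), 5), collapse = ", "))
  }
  bad_measure <- !(records$measure %in% cti_measures())
  if (any(bad_measure)) {
    stop("unknown affinity measure: ",
         paste(unique(records$measure[bad_measure]), collapse = ", "))
  }
  bad_var <- !(records$variant %in% c("WILD", "MUTANT", "UNKNOWN"))
  if (any(bad_var)) {
    stop("variant must be WILD, MUTANT or UNKNOWN")
  }
  invisible(records)
}

#' @export
print.cti_records <- function(x, ...) {
  n_lab <- sum(!is.na(x$label))
  cat(sprintf(
    "<cti_records> %d records | %d compounds | %d targets | %d labelled (%d positive)\n",
    nrow(x), length(unique(x$compound_id)), length(unique(x$target_id)),
    n_lab, sum(x$label == 1L, na.rm = TRUE)))
  NextMethod()
}
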
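# Fold construction: warm-start, cold-start, mutation-aware splits and the
# label-reversal validator.

new_fold_assignment <- function(scenario, n_folds, fold_of, seed = NA_integer_,
                                capacity = NA_integer_, flags = character(0)) {
  structure(list(scenario = scenario, n_folds = as.integer(n_folds),
                 fold_of = as.integer(fold_of), seed = seed,
                 capacity = capacity, flags = flags),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment> %s: %d records in %d folds (sizes %s)\n",
              x$scenario, length(x$fold_of), x$n_folds,
              paste(tabulate(x$fold_of, x$n_folds), collapse = ", ")))
  invisible(x)
}

#' Warm-start cross-validation split
#'
#' Distributes the records of every entity (compound or target) across
#' folds round-robin after a seeded shuffle within the entity, so that the
#' entity distribution is as equal as possible between folds: any entity
#' with at least `n_folds` records appears in every fold, which is the
#' defining property of the warm-start scenario (test-set entities were
#' seen in training).
#'
#' @param records A `cti_records` table.
#' @param entity `"compound"` or `"target"`.
#' @param n_folds Number of folds (default 10).
#' @param seed RNG seed for the within-entity shuffle.
#' @return A `fold_assignment`.
#' @export
warm_split <- function(records, entity = c("compound", "target"),
                       n_folds = 10, seed = 1) {
  entity <- match.arg(entity)
  stopifnot(n_folds >= 2)
  ids <- if (entity == "compound") records$compound_id else records$target_id
  n <- length(ids)
  fold_of <- integer(n)
  # rotate the starting fold across entities so fold sizes stay balanced
  start <- 0L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (id in sort(unique(ids))) {
    idx <- which(ids == id)
    idx <- idx[sample.int(length(idx))]
    fold_of[idx] <- ((start + seq_along(idx) - 1L) %% n_folds) + 1L
    start <- (start + length(idx)) %% n_folds
  }
  scen <- if (entity == "compound") "WARM_COMPOUND" else "WARM_TARGET"
  new_fold_assignment(scen, n_folds, fold_of, seed = seed)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Cold-start cross-validation split
#'
#' Assigns all records of each entity (compound or target) as a block, so
#' no entity ever spans two folds: entities are sorted by descending record
#' count (ties by id), and blocks are dealt to folds visited cyclically,
#' skipping folds that have reached `capacity`. Test folds therefore
#' contain only entities never seen in the other folds - the cold-start
#' scenario. An entity whose block alone exceeds the capacity is assigned
#' to the currently emptiest fold and flagged.
#'
#' @param records A `cti_records` table.
#' @param entity `"compound"` or `"target"`.
#' @param n_folds Number of folds (default 10).
#' @param capacity Per-fold record cap; default
#'   `ceiling(nrow(records) / n_folds * 1.007)`, a small slack over the
#'   equal-share size (the slack generalizes a fixed cap of 34,000 used at
#'   337,526 records and 10 folds).
#' @return A `fold_assignment` (element `flags` lists oversized entities).
#' @export
cold_split <- function(records, entity = c("compound", "target"),
                       n_folds = 10, capacity = NULL) {
  entity <- match.arg(entity)
  stopifnot(n_folds >= 2)
  ids <- if (entity == "compound") records$compound_id else records$target_id
  n <- length(ids)
  ents <- sort(unique(ids))
  if (length(ents) < n_folds) {
    stop("cold split needs at least as many distinct ", entity,
         "s (", length(ents), ") as folds (", n_folds, ")")
  }
  if (is.null(capacity)) capacity <- ceiling(n / n_folds * 1.007)
  cnt <- table(ids)[ents]
  ord <- ents[order(-as.integer(cnt), ents)]
  fold_sizes <- integer(n_folds)
  fold_of <- integer(n)
  flags <- character(0)
  cur <- 1L
  for (e in ord) {
    sz <- as.integer(cnt[[e]])
    if (sz > capacity) {
      f <- which.min(fold_sizes)
      flags <- c(flags, e)
    } else {
      # walk folds cyclically from the cursor, skipping full folds
      tried <- 0L
      f <- NA_integer_
      probe <- cur
      while (tried < n_folds) {
        if (fold_sizes[probe] + sz <= capacity) { f <- probe; break }
        probe <- (probe %% n_folds) + 1L
        tried <- tried + 1L
      }
      if (is.na(f)) f <- which.min(fold_sizes)  # everything full: least bad
      cur <- (f %% n_folds) + 1L
    }
    fold_of[ids == e] <- f
    fold_sizes[f] <- fold_sizes[f] + sz
  }
  scen <- if (entity == "compound") "COLD_COMPOUND" else "COLD_TARGET"
  new_fold_assignment(scen, n_folds, fold_of, capacity = capacity,
                      flags = flags)
}

#' Normalized Needleman-Wunsch sequence similarity
#'
#' Global alignment score between two amino-acid sequences, normalized to
#' `[0, 1]` by the maximum attainable self-alignment score of the longer
#' sequence. With the default identity scoring (match 1, mismatch 0, gap 0)
#' this equals the number of aligned identical residues divided by the
#' longer length, so identical sequences score 1 and unrelated ones near 0.
#' Symmetric in its arguments.
#'
#' @param seq_a,seq_b Amino-acid sequences (non-empty).
#' @param substitution Either `"identity"` (default) or the name of a
#'   substitution matrix available to Biostrings (e.g. `"BLOSUM62"`).
#' @param gap_opening,gap_extension Gap penalties (non-negative; defaults 0
#'   under identity scoring).
#' @return Similarity in `[0, 1]`.
#' @export
nw_similarity <- function(seq_a, seq_b, substitution = "identity",
                          gap_opening = 0, gap_extension = 0) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  if (identical(substitution, "identity")) {
    ab <- aa_alphabet()
    mat <- diag(1, length(ab))
    dimnames(mat) <- list(ab, ab)
  } else {
    mat <- substitution
  }
  sc <- function(a, b) {
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      type = "global", substitutionMatrix = mat,
      gapOpening = gap_opening, gapExtension = gap_extension,
      scoreOnly = TRUE)
  }
  longer <- if (nchar(seq_a) >= nchar(seq_b)) seq_a else seq_b
  denom <- sc(longer, longer)
  if (denom <= 0) stop("self-alignment score of the longer sequence is not positive")
  max(0, min(1, sc(seq_a, seq_b) / denom))
}

#' Mutation-aware train/test split
#'
#' Partitions records by the variant flag: training contains only
#' wild-type target records and testing only mutant target records. The
#' accompanying similarity report lists, for every mutant target, the
#' `top_n` most similar wild-type targets under [nw_similarity()] together
#' with the number of training records each contributes - the information
#' needed to judge how close the test targets sit to the training
#' distribution.
#'
#' @param records A `cti_records` table with variant flags set.
#' @param top_n Wild-type neighbours reported per mutant (default 10).
#' @return A list with `train`, `test` (both `cti_records`) and
#'   `similarity_report` (data frame: mutant_target, wild_target,
#'   similarity, wild_records, rank; rows sorted by mutant then descending
#'   similarity).
#' @export
mutation_split <- function(records, top_n = 10) {
  validate_cti_records(records)
  is_mut <- records$variant == "MUTANT"
  is_wild <- records$variant == "WILD"
  if (!any(is_mut)) stop("no MUTANT records; mutation-aware split undefined")
  if (!any(is_wild)) stop("no WILD records; mutation-aware split undefined")
  train <- records[is_wild, , drop = FALSE]
  test <- records[is_mut, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  class(train) <- class(test) <- c("cti_records", "data.frame")

  wild_seq <- tapply(train$sequence, train$target_id, `[`, 1)
  wild_cnt <- table(train$target_id)
  mut_seq <- tapply(test$sequence, test$target_id, `[`, 1)
  rows <- lapply(names(mut_seq), function(mt) {
    sims <- vapply(names(wild_seq), function(wt) {
      nw_similarity(mut_seq[[mt]], wild_seq[[wt]])
    }, numeric(1))
    ord <- order(-sims, names(wild_seq))[seq_len(min(top_n, length(sims)))]
    data.frame(mutant_target = mt,
               wild_target = names(wild_seq)[ord],
               similarity = unname(sims[ord]),
               wild_records = as.integer(wild_cnt[names(wild_seq)[ord]]),
               rank = seq_along(ord),
               stringsAsFactors = FALSE)
  })
  list(train = train, test = test,
       similarity_report = do.call(rbind, rows))
}

#' Validate a label-reversal experiment
#'
#' In a label-reversal design a compound that occurs with one label in the
#' training set must appear only with the opposite label in the test set;
#' models that memorize compound identity instead of learning interaction
#' features then fail. This checker lists, per compound occurring in both
#' sets, its train/test occurrence counts and flags every compound whose
#' test labels are not the exact complement of its train labels.
#'
#' @param train,test Labelled `cti_records` tables.
#' @return A list with `pass` (logical), `violations` (character vector of
#'   offending compound ids) and `per_compound` (data frame: compound_id,
#'   n_train, n_test, train_labels, test_labels, reversed).
#' @export
verify_label_reversal <- function(train, test) {
  shared <- intersect(unique(train$compound_id), unique(test$compound_id))
  rows <- lapply(shared, function(cid) {
    tr <- sort(unique(train$label[train$compound_id == cid]))
    te <- sort(unique(test$label[test$compound_id == cid]))
    reversed <- length(tr) == 1 && length(te) == 1 && tr != te
    data.frame(compound_id = cid,
               n_train = sum(train$compound_id == cid),
               n_test = sum(test$compound_id == cid),
               train_labels = paste(tr, collapse = ","),
               test_labels = paste(te, collapse = ","),
               reversed = reversed,
               stringsAsFactors = FALSE)
  })
  per_compound <- if (length(rows)) do.call(rbind, rows) else
    data.frame(compound_id = character(0), n_train = integer(0),
               n_test = integer(0), train_labels = character(0),
               test_labels = character(0), reversed = logical(0))
  violations <- per_compound$compound_id[!per_compound$reversed]
  list(pass = length(violations) == 0, violations = violations,
       per_compound = per_compound)
}

#' Write a fold assignment to disk
#'
#' Records go to a TSV (`record_index`, `fold`); the scenario, seed and
#' capacity go to a JSON sidecar of the same stem.
#'
#' @param fa A `fold_assignment`.
#' @param path TSV output path (sidecar is `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_fold_assignment <- function(fa, path) {
  utils::write.table(
    data.frame(record_index = seq_along(fa$fold_of), fold = fa$fold_of),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(scenario = fa$scenario, n_folds = fa$n_folds, seed = fa$seed,
         capacity = fa$capacity, flags = fa$flags),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fold assignment written by [write_fold_assignment()]
#' @param path TSV path.
#' @return A `fold_assignment`.
#' @export
read_fold_assignment <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_fold_assignment(meta$scenario, meta$n_folds,
                      tab$fold[order(tab$record_index)],
                      seed = meta$seed,
                      capacity = if (is.null(meta$capacity)) NA else meta$capacity,
                      flags = meta$flags %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
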
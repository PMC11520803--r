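# Gold-standard dataset construction: Tanimoto max-min negative sampling
# and rotatable-bond dataset filters.

#' Tanimoto similarity between two binary fingerprints
#'
#' `|A intersect B| / |A union B|` over the set bits of two equal-length
#' binary vectors. Two all-zero vectors are identical, so their similarity
#' is defined as 1.
#'
#' @param fp_a,fp_b Binary (0/1) integer vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto_similarity <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) {
    stop("fingerprint length mismatch: ", length(fp_a), " vs ", length(fp_b))
  }
  a <- fp_a != 0
  b <- fp_b != 0
  uni <- sum(a | b)
  if (uni == 0) return(1)
  sum(a & b) / uni
}

#' Negative sampling specification
#'
#' Parameters for max-min Tanimoto negative generation: `k` negatives per
#' target, the fingerprint scheme used for compound-compound similarity,
#' and a deterministic tie-break. When `k` is `NULL` it is derived per
#' target as `min(n_candidates, round(ratio * n_binders))`, which places
#' the global negative:positive ratio near `ratio`.
#'
#' @param k Negatives per target (positive integer), or `NULL` to derive
#'   from `ratio`.
#' @param ratio Target negative:positive ratio used when `k` is `NULL`
#'   (default 2.5, the middle of the 1.9-3 band typical of curated CTI
#'   benchmarks).
#' @param fingerprint Function mapping a character vector of SMILES to a
#'   binary fingerprint matrix; default Morgan radius 2, 2048 bits.
#' @return A list of class `negative_sampling_spec`.
#' @export
negative_sampling_spec <- function(k = NULL, ratio = 2.5,
                                   fingerprint = function(s) fp_morgan(s, 2048)) {
  if (!is.null(k)) stopifnot(k >= 1)
  stopifnot(ratio > 0)
  structure(list(k = k, ratio = ratio, fingerprint = fingerprint),
            class = "negative_sampling_spec")
}

#' Max-min Tanimoto negative generation for one target
#'
#' Given the compounds known to bind a target (`binders`) and a candidate
#' pool that does not (`candidates`), computes for every candidate its
#' Tanimoto distance to the binder set (the minimum over binders of
#' 1 - Tanimoto) and selects the `k` candidates with the largest
#' distance-to-set, i.e. the candidates most dissimilar from everything
#' known to bind. Ties are broken by lexicographic compound id so the
#' selection is deterministic.
#'
#' @param target_id Target identifier for the emitted records.
#' @param binders Named character vector of binder SMILES (names are
#'   compound ids).
#' @param candidates Named character vector of candidate SMILES.
#' @param spec A [negative_sampling_spec()].
#' @param sequence Target sequence copied onto the emitted records
#'   (optional; defaults to a placeholder "A").
#' @return A list with `records` (a [cti_records()] table of `k` label-0
#'   pairs, ranked by decreasing distance) and `distances` (named vector of
#'   distance-to-set for every candidate).
#' @export
generate_negatives <- function(target_id, binders, candidates, spec,
                               sequence = "A") {
  if (length(binders) == 0) stop("binder set is empty; distance undefined")
  if (length(candidates) == 0) stop("candidate set is empty")
  if (is.null(names(binders))) names(binders) <- sprintf("b%d", seq_along(binders))
  if (is.null(names(candidates))) names(candidates) <- sprintf("c%d", seq_along(candidates))
  k <- spec$k
  if (is.null(k)) k <- min(length(candidates), max(1L, round(spec$ratio * length(binders))))
  if (k > length(candidates)) {
    stop("k (", k, ") exceeds candidate pool size (", length(candidates), ")")
  }
  fp_b <- spec$fingerprint(binders)
  fp_c <- spec$fingerprint(candidates)
  dist_to_set <- vapply(seq_len(nrow(fp_c)), function(i) {
    min(vapply(seq_len(nrow(fp_b)), function(j) {
      1 - tanimoto_similarity(fp_b[j, ], fp_c[i, ])
    }, numeric(1)))
  }, numeric(1))
  names(dist_to_set) <- names(candidates)
  ord <- order(-dist_to_set, names(candidates))
  sel <- ord[seq_len(k)]
  recs <- cti_records(
    compound_id = names(candidates)[sel],
    smiles = unname(candidates[sel]),
    target_id = target_id,
    sequence = sequence,
    affinity_value = NA_real_,
    measure = "BINARY",
    label = 0L,
    source = "SYNTHETIC",
    variant = "UNKNOWN",
    validate = FALSE
  )
  list(records = recs, distances = dist_to_set)
}

#' Generate negatives for every target of a positives-only table
#'
#' Applies [generate_negatives()] target by target: for each target the
#' binder set is its positive compounds and the candidate pool is every
#' other compound in `compounds` (so a generated negative pair never
#' duplicates a positive pair of that target).
#'
#' @param positives A `cti_records` table of label-1 records.
#' @param compounds Named character vector of all available compound SMILES.
#' @param spec A [negative_sampling_spec()].
#' @return A `cti_records` table of generated label-0 records.
#' @export
generate_negatives_all <- function(positives, compounds, spec) {
  validate_cti_records(positives)
  stopifnot(!is.null(names(compounds)))
  targets <- unique(positives$target_id)
  out <- lapply(targets, function(t) {
    rows <- positives[positives$target_id == t, , drop = FALSE]
    binder_ids <- unique(rows$compound_id)
    binders <- compounds[intersect(names(compounds), binder_ids)]
    cand <- compounds[setdiff(names(compounds), binder_ids)]
    if (length(binders) == 0 || length(cand) == 0) return(NULL)
    sp <- spec
    if (!is.null(sp$k)) sp$k <- min(sp$k, length(cand))
    generate_negatives(t, binders, cand, sp,
                       sequence = rows$sequence[1])$records
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  class(res) <- c("cti_records", "data.frame")
  res
}

#' Rotatable-bond profile of a compound
#'
#' Counts rotatable bonds under the strict definition - single, non-ring
#' bonds between two non-terminal heavy atoms, excluding amide C-N bonds
#' and bonds adjacent to triple bonds - plus the total heavy-atom bond
#' count and the rotatable bond fraction RBF = rotatable / total (defined
#' as 0 when the molecule has no bonds).
#'
#' @param smiles A single SMILES string.
#' @return A list of class `rotatable_bond_profile` with `n_rotatable`,
#'   `n_bonds`, `rbf`.
#' @export
rotatable_bond_profile <- function(smiles) {
  g <- mol_graph(smiles)
  atoms <- g$atoms
  bonds <- g$bonds
  n_bonds <- nrow(bonds)
  if (n_bonds == 0) {
    return(structure(list(n_rotatable = 0L, n_bonds = 0L, rbf = 0),
                     class = "rotatable_bond_profile"))
  }
  # atoms participating in a triple bond
  triple_atom <- rep(FALSE, nrow(atoms))
  tr <- bonds$order == 3
  triple_atom[c(bonds$i[tr], bonds$j[tr])] <- TRUE
  # carbonyl carbons: C with a double bond to O
  carbonyl <- rep(FALSE, nrow(atoms))
  for (b in which(bonds$order == 2)) {
    i <- bonds$i[b]; j <- bonds$j[b]
    if (atoms$element[i] == "C" && atoms$element[j] == "O") carbonyl[i] <- TRUE
    if (atoms$element[j] == "C" && atoms$element[i] == "O") carbonyl[j] <- TRUE
  }
  rot <- vapply(seq_len(n_bonds), function(b) {
    i <- bonds$i[b]; j <- bonds$j[b]
    if (bonds$order[b] != 1 || bonds$in_ring[b]) return(FALSE)
    if (atoms$degree[i] < 2 || atoms$degree[j] < 2) return(FALSE)
    if (triple_atom[i] || triple_atom[j]) return(FALSE)
    # amide: C(=O)-N
    amide <- (carbonyl[i] && atoms$element[j] == "N") ||
             (carbonyl[j] && atoms$element[i] == "N")
    !amide
  }, logical(1))
  n_rot <- sum(rot)
  structure(list(n_rotatable = as.integer(n_rot),
                 n_bonds = as.integer(n_bonds),
                 rbf = n_rot / n_bonds),
            class = "rotatable_bond_profile")
}

rb_profiles <- function(records) {
  smi <- unique(records$smiles)
  prof <- lapply(smi, rotatable_bond_profile)
  idx <- match(records$smiles, smi)
  list(n_rotatable = vapply(prof, `[[`, 0L, "n_rotatable")[idx],
       rbf = vapply(prof, `[[`, 0, "rbf")[idx])
}

#' Limited-rotatable-bonds (LRB) filter
#'
#' Keeps records whose compound has at most `max_rotatable` rotatable bonds
#' (default 10, the oral-bioavailability rule of thumb). Order-preserving
#' and idempotent.
#'
#' @param records A `cti_records` table.
#' @param max_rotatable Inclusive rotatable-bond cut-off.
#' @return The kept records.
#' @export
filter_lrb <- function(records, max_rotatable = 10) {
  if (nrow(records) == 0) return(records)
  keep <- rb_profiles(records)$n_rotatable <= max_rotatable
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cti_records", "data.frame")
  out
}

#' Ratio-based rotatable-bonds (RRB) filter
#'
#' Keeps records whose compound has a rotatable bond fraction (rotatable
#' bonds / total bonds) at most `max_rbf`; the default 0.184 matches the
#' cut that yields an RRB dataset of comparable size to the LRB dataset on
#' the large aggregated benchmark. Inclusive at the threshold.
#'
#' @param records A `cti_records` table.
#' @param max_rbf Inclusive RBF cut-off (default 0.184).
#' @return The kept records.
#' @export
filter_rrb <- function(records, max_rbf = 0.184) {
  if (nrow(records) == 0) return(records)
  keep <- rb_profiles(records)$rbf <= max_rbf
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cti_records", "data.frame")
  out
}
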
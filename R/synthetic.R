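# Synthetic fixture generation: compounds from a fragment grammar, targets
# with planted motifs and point mutants, interaction tables with a planted
# compound-substructure x target-motif signal, and typed residue contacts.

# Fragment grammar: every fragment is a complete, parseable SMILES unit
# that can be concatenated head-to-tail. Ring fragments close their ring
# numbers internally, so concatenation stays valid.
synthetic_fragments <- function() {
  list(
    rigid = c("c1ccccc1", "c1ccncc1", "C1CCCCC1", "C1CCNCC1", "c1ccsc1",
              "C1CC1"),
    flexible = c("CC", "CCC", "CCCC", "CCO", "CCN", "COC", "CCCCC",
                 "CCOCC", "CCCCCC"),
    polar = c("C(=O)O", "C(=O)N", "CO", "CN", "C(C)O")
  )
}

#' The planted compound substructure
#'
#' Sulfonamide fragment used as the positive-signal substructure in
#' synthetic interaction data; it is clearly visible to circular
#' fingerprints.
#'
#' @return A SMILES fragment string.
#' @export
planted_fragment <- function() "S(=O)(=O)N"

#' The planted target motif
#'
#' Tryptophan/histidine-rich motif inserted into positive-signal synthetic
#' targets; it shifts the residue composition enough to be visible to
#' composition-based target features.
#'
#' @return An amino-acid motif string.
#' @export
planted_motif <- function() "WHWHWCC"

#' Generate synthetic compounds
#'
#' Assembles `n` valid SMILES from a fragment grammar. About half the
#' compounds carry the planted sulfonamide fragment, and chain-fragment
#' counts vary so rotatable-bond counts span roughly 0-20 (both sides of
#' the LRB/RRB filters are populated). Deterministic under the seed.
#'
#' @param n Number of compounds.
#' @param seed RNG seed.
#' @param frag_fraction Fraction carrying the planted fragment (default
#'   0.5).
#' @return Named character vector of canonical SMILES (names `cmp0001`,
#'   ...), with attribute `has_fragment` (logical vector).
#' @export
gen_compounds <- function(n, seed = 1, frag_fraction = 0.5) {
  stopifnot(n >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fr <- synthetic_fragments()
  has_frag <- seq_len(n) <= round(n * frag_fraction)
  gen_one <- function(with_frag) {
    n_flex <- sample(0:6, 1)
    n_rigid <- sample(1:2, 1)
    parts <- c(sample(fr$rigid, n_rigid, replace = TRUE),
               sample(fr$flexible, n_flex, replace = TRUE),
               sample(fr$polar, sample(0:2, 1), replace = TRUE))
    parts <- sample(parts)
    if (with_frag) {
      # anchor the fragment mid-chain so it is never a dangling terminus
      parts <- c("C", planted_fragment(), "C", parts)
    }
    paste(parts, collapse = "")
  }
  smi <- vapply(seq_len(n), function(i) gen_one(has_frag[i]), "")
  can <- smiles_canonical(smi)
  # distinct molecules only: regenerate any canonical collision
  tries <- 0
  while (anyDuplicated(can) && tries < 50) {
    for (i in which(duplicated(can))) {
      smi[i] <- gen_one(has_frag[i])
      can[i] <- smiles_canonical(smi[i])
    }
    tries <- tries + 1
  }
  names(can) <- sprintf("cmp%04d", seq_len(n))
  attr(can, "has_fragment") <- stats::setNames(has_frag, names(can))
  can
}

#' Generate synthetic targets
#'
#' Random sequences over the canonical alphabet. About half carry the
#' planted motif at a random interior position; a `mutant_fraction` of the
#' targets are single-point substitutions of a generated wild-type (the
#' mutant keeps its parent's motif status and is flagged `MUTANT`).
#'
#' @param n Number of targets.
#' @param length_range Sequence length bounds (default `c(150, 400)`, at
#'   most 1400).
#' @param mutant_fraction Fraction of targets that are point mutants of
#'   wild-types (default 0).
#' @param seed RNG seed.
#' @param motif_fraction Fraction carrying the planted motif (default
#'   0.5).
#' @return Data frame: `target_id`, `sequence`, `variant`, `has_motif`,
#'   `parent_id` (NA for wild-types).
#' @export
gen_targets <- function(n, length_range = c(150, 400), mutant_fraction = 0,
                        seed = 1, motif_fraction = 0.5) {
  stopifnot(n >= 1, length_range[2] <= 1400)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_mut <- round(n * mutant_fraction)
  n_wild <- n - n_mut
  if (n_mut > 0 && n_wild == 0) stop("mutants need at least one wild-type parent")
  ab <- aa_alphabet()
  motif_flags <- seq_len(n_wild) <= round(n_wild * motif_fraction)
  wild <- lapply(seq_len(n_wild), function(i) {
    len <- sample(length_range[1]:length_range[2], 1)
    s <- paste(sample(ab, len, replace = TRUE), collapse = "")
    if (motif_flags[i]) {
      m <- planted_motif()
      pos <- sample(seq_len(len - nchar(m) + 1), 1)
      substr(s, pos, pos + nchar(m) - 1) <- m
    }
    list(sequence = s, has_motif = motif_flags[i])
  })
  ids_w <- sprintf("tgt%04d", seq_len(n_wild))
  rows <- data.frame(
    target_id = ids_w,
    sequence = vapply(wild, `[[`, "", "sequence"),
    variant = "WILD",
    has_motif = vapply(wild, `[[`, TRUE, "has_motif"),
    parent_id = NA_character_,
    stringsAsFactors = FALSE)
  if (n_mut > 0) {
    parents <- sample(seq_len(n_wild), n_mut, replace = TRUE)
    mut <- lapply(parents, function(p) {
      s <- rows$sequence[p]
      pos <- sample(nchar(s), 1)
      cur <- substr(s, pos, pos)
      repl <- sample(setdiff(ab, cur), 1)
      substr(s, pos, pos) <- repl
      s
    })
    rows <- rbind(rows, data.frame(
      target_id = sprintf("tgt%04dm%02d", parents, seq_len(n_mut)),
      sequence = unlist(mut),
      variant = "MUTANT",
      has_motif = rows$has_motif[parents],
      parent_id = rows$target_id[parents],
      stringsAsFactors = FALSE))
  }
  rownames(rows) <- NULL
  rows
}

#' Synthetic interaction specification
#'
#' @param n_pairs Number of compound-target pairs to draw.
#' @param prevalence Target fraction of positive labels (default 0.289,
#'   matching the class balance of large aggregated CTI benchmarks).
#' @param label_noise Probability of flipping a label (in `[0, 0.5)`).
#' @param measure Affinity measure for the generated records.
#' @param seed RNG seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pairs = 1000, prevalence = 0.289,
                           label_noise = 0, measure = "KIBA_SCORE",
                           seed = 1) {
  stopifnot(label_noise >= 0, label_noise < 0.5,
            prevalence > 0, prevalence < 1)
  structure(list(n_pairs = n_pairs, prevalence = prevalence,
                 label_noise = label_noise, measure = measure, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic interaction table
#'
#' Draws compound-target pairs whose label follows the planted rule: a
#' pair is positive iff its compound carries the planted fragment AND its
#' target carries the planted motif (then flipped with probability
#' `label_noise`). Pair sampling is stratified so the positive fraction
#' lands at `spec$prevalence`. Affinities are drawn consistently with the
#' label under the declared measure (e.g. KiBA scores <= 3 for hits,
#' > 3 otherwise; Kd below/above 10 uM), so binarizing the affinity
#' reproduces the label.
#'
#' @param compounds Output of [gen_compounds()].
#' @param targets Output of [gen_targets()].
#' @param spec A [synthetic_spec()].
#' @return A [cti_records()] table.
#' @export
gen_interactions <- function(compounds, targets, spec) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  has_frag <- attr(compounds, "has_fragment")
  stopifnot(!is.null(has_frag))
  pos_c <- names(compounds)[has_frag]
  neg_c <- names(compounds)[!has_frag]
  pos_t <- targets$target_id[targets$has_motif]
  neg_t <- targets$target_id[!targets$has_motif]
  if (length(pos_c) == 0 || length(pos_t) == 0) {
    stop("need at least one fragment-bearing compound and one motif-bearing target")
  }
  n_pos <- round(spec$n_pairs * spec$prevalence)
  n_neg <- spec$n_pairs - n_pos
  # draw unique (compound, target) pairs from a stratum's grid, so the
  # generated table contains no duplicate records and passes
  # deduplication unchanged
  draw <- function(cs, ts, m) {
    grid_n <- length(cs) * length(ts)
    if (m > grid_n) {
      stop("stratum grid (", grid_n, " pairs) cannot supply ", m,
           " unique pairs; increase n_compounds/n_targets or lower n_pairs")
    }
    idx <- sample.int(grid_n, m) - 1L
    data.frame(compound_id = cs[idx %% length(cs) + 1L],
               target_id = ts[idx %/% length(cs) + 1L],
               stringsAsFactors = FALSE)
  }
  pos_pairs <- draw(pos_c, pos_t, n_pos)
  # negatives from the two non-co-occurring strata, split evenly but
  # respecting each stratum's grid capacity
  cap1 <- length(compounds) * length(neg_t)
  cap2 <- length(neg_c) * length(pos_t)
  if (cap1 + cap2 < n_neg) {
    stop("negative strata (", cap1 + cap2, " pairs) cannot supply ",
         n_neg, " unique pairs; increase n_compounds/n_targets or lower n_pairs")
  }
  m1 <- min(ceiling(n_neg / 2), cap1)
  m2 <- n_neg - m1
  if (m2 > cap2) {
    m1 <- m1 + (m2 - cap2)
    m2 <- cap2
  }
  negs <- rbind(
    if (m1 > 0) draw(names(compounds), neg_t, m1),
    if (m2 > 0) draw(neg_c, pos_t, m2))
  pairs <- rbind(pos_pairs, negs)
  rule <- has_frag[pairs$compound_id] &
    targets$has_motif[match(pairs$target_id, targets$target_id)]
  label <- as.integer(rule)
  flip <- stats::runif(nrow(pairs)) < spec$label_noise
  label[flip] <- 1L - label[flip]
  affinity <- switch(spec$measure,
    KIBA_SCORE = ifelse(label == 1, stats::runif(nrow(pairs), 0, 3),
                        stats::runif(nrow(pairs), 3.001, 15)),
    KD_MICROMOLAR = ifelse(label == 1, stats::runif(nrow(pairs), 0.001, 9.99),
                           stats::runif(nrow(pairs), 10, 100)),
    BINARY = as.numeric(label),
    stop("unknown measure: ", spec$measure))
  ti <- match(pairs$target_id, targets$target_id)
  recs <- cti_records(
    compound_id = pairs$compound_id,
    smiles = unname(compounds[pairs$compound_id]),
    target_id = pairs$target_id,
    sequence = targets$sequence[ti],
    affinity_value = affinity,
    measure = spec$measure,
    label = label,
    source = "SYNTHETIC",
    variant = targets$variant[ti])
  ord <- sample.int(nrow(recs))
  recs <- recs[ord, , drop = FALSE]
  rownames(recs) <- NULL
  class(recs) <- c("cti_records", "data.frame")
  recs
}

#' Generate a typed residue contact list for one sequence
#'
#' Random geometric-style contacts: residues close in sequence are more
#' likely to touch, with contact types drawn over the six interaction
#' categories. Disulfide contacts are only emitted between cysteine
#' pairs. No self-loops; indices are 1-based and within range.
#'
#' @param sequence Amino-acid sequence.
#' @param seed RNG seed.
#' @param density Expected contacts per residue (default 1.5).
#' @return Data frame: `res_i`, `res_j`, `type`.
#' @export
gen_contacts <- function(sequence, seed = 1, density = 1.5) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nchar(sequence)
  res <- strsplit(sequence, "")[[1]]
  m <- max(1L, round(n * density))
  i <- sample(n, m, replace = TRUE)
  span <- pmax(1, stats::rgeom(m, prob = 0.15) + 1)
  j <- pmin(n, i + span)
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  types <- sample(setdiff(names(residue_interaction_energies()), "disulfide"),
                  length(i), replace = TRUE,
                  prob = c(0.1, 0.3, 0.05, 0.1, 0.45))
  cys <- res[i] == "C" & res[j] == "C"
  types[cys & stats::runif(length(i)) < 0.5] <- "disulfide"
  unique(data.frame(res_i = pmin(i, j), res_j = pmax(i, j), type = types,
                    stringsAsFactors = FALSE))
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper tying the generators together: compounds, targets,
#' an interaction table, and per-target contact lists, all deterministic
#' under one seed.
#'
#' @param n_compounds,n_targets,n_pairs Sizes.
#' @param mutant_fraction Fraction of mutant targets.
#' @param prevalence Positive fraction.
#' @param label_noise Label flip probability.
#' @param measure Affinity measure.
#' @param seed Master seed.
#' @return A list: `compounds`, `targets`, `records`, `spec`.
#' @export
synthetic_dataset <- function(n_compounds = 30, n_targets = 20,
                              n_pairs = 200, mutant_fraction = 0,
                              prevalence = 0.289, label_noise = 0,
                              measure = "KIBA_SCORE", seed = 1) {
  cmp <- gen_compounds(n_compounds, seed = seed)
  tgt <- gen_targets(n_targets, mutant_fraction = mutant_fraction,
                     seed = seed + 1)
  spec <- synthetic_spec(n_pairs = n_pairs, prevalence = prevalence,
                         label_noise = label_noise, measure = measure,
                         seed = seed + 2)
  recs <- gen_interactions(cmp, tgt, spec)
  list(compounds = cmp, targets = tgt, records = recs, spec = spec)
}
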
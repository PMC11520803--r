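# Compound representations: SMILES one-hot, concatenated 2D fingerprints,
# conformer (3D) fingerprints and the annotated atom interaction graph.

#' The frozen 98-character SMILES vocabulary
#'
#' Character table for SMILES one-hot encoding: the 94 printable non-space
#' ASCII characters (digits, both letter cases - two-letter element symbols
#' are encoded per character - brackets, ring-closure digits and `%`, bond
#' and stereo marks, charge signs) plus the four whitespace characters
#' space, tab, CR and LF that raw table exports occasionally leak into a
#' SMILES field. Exactly 98 symbols; column order is fixed. Characters
#' outside the table are rejected by the encoder rather than remapped,
#' since silent remapping corrupts one-hot semantics.
#'
#' @return Character vector of length 98.
#' @export
smiles_vocabulary <- function() {
  c(vapply(33:126, function(i) rawToChar(as.raw(i)), ""),
    " ", "\t", "\r", "\n")
}

#' One-hot encode a SMILES string
#'
#' Encodes each character of the SMILES as a one-hot row over the frozen
#' 98-character vocabulary, zero-padded to `max_len` rows.
#'
#' @param smiles A single SMILES string of length at most `max_len`.
#' @param max_len Matrix height (default 348).
#' @param vocab Character table (default [smiles_vocabulary()]).
#' @return A binary matrix of dim `(max_len, length(vocab))` with attribute
#'   `true_length` (the unpadded length).
#' @export
encode_smiles_onehot <- function(smiles, max_len = 348,
                                 vocab = smiles_vocabulary()) {
  stopifnot(length(smiles) == 1)
  chars <- strsplit(smiles, "")[[1]]
  if (length(chars) > max_len) {
    stop("SMILES length ", length(chars), " exceeds encoder height ", max_len)
  }
  idx <- match(chars, vocab)
  if (anyNA(idx)) {
    stop("SMILES character(s) outside the vocabulary: ",
         paste(unique(chars[is.na(idx)]), collapse = " "))
  }
  m <- matrix(0L, max_len, length(vocab))
  if (length(chars) > 0) m[cbind(seq_along(chars), idx)] <- 1L
  attr(m, "true_length") <- length(chars)
  m
}

#' Concatenated 2D fingerprint vector (3239 bits)
#'
#' The standard 2D compound representation: Morgan radius-2 (1024) +
#' MACCS keys (167) + topological path fingerprint (1024) + atom-pair
#' fingerprint (1024), concatenated to 3239 bits. Identical molecules give
#' identical vectors regardless of SMILES spelling (everything is computed
#' on the canonical form).
#'
#' @param smiles Character vector of SMILES.
#' @return Binary integer matrix with 3239 columns and attribute
#'   `segments`: named list of column index ranges per fingerprint.
#' @export
encode_2dfp <- function(smiles) {
  m <- cbind(fp_morgan(smiles, 1024),
             fp_maccs(smiles),
             fp_path(smiles, 1024),
             fp_atompair(smiles, 1024))
  stopifnot(ncol(m) == 3239)
  attr(m, "segments") <- list(
    morgan = 1:1024, maccs = 1025:1191,
    path = 1192:2215, atompair = 2216:3239)
  rownames(m) <- names(smiles)
  m
}

# Deterministic 32-bit-ish integer hash of an integer vector (polynomial
# rolling hash). Used by the conformer fingerprint.
hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% 1000003)) %% 2147483647
  as.integer(h)
}

# Shell-hash a 3D conformer into identifiers (an E3FP-style iterative
# spherical expansion over heavy atoms): each atom starts from a hash of
# its element/charge/aromatic invariants, then at every level absorbs the
# identifiers of atoms within a growing radius, distance-binned.
conformer_identifiers <- function(coords, invariants, n_levels = 5,
                                  shell_step = 1.718) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  ids <- vapply(seq_len(n), function(i) hash_ints(invariants[i, ]), 0L)
  all_ids <- ids
  for (lev in seq_len(n_levels)) {
    radius <- shell_step * lev
    new_ids <- vapply(seq_len(n), function(i) {
      nb <- setdiff(which(d[i, ] <= radius), i)
      if (length(nb) == 0) return(ids[i])
      key <- as.integer(round(d[i, nb] / 0.5))
      ord <- order(ids[nb], key)
      hash_ints(c(lev, ids[i], as.integer(rbind(ids[nb][ord], key[ord]))))
    }, 0L)
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  unique(all_ids)
}

#' Conformer-based 3D fingerprints
#'
#' Embeds the molecule in 3D with ETKDG distance geometry at a fixed seed
#' (see [embed_conformers()]), and hashes each of up to `max_conformers`
#' conformers with an iterative spherical-shell scheme over the heavy
#' atoms - identifiers start from per-atom invariants and repeatedly
#' absorb distance-binned neighbour identifiers within a growing radius -
#' folded to an `nbits`-wide binary vector per conformer. Rows beyond the
#' number of conformers actually generated are zero.
#'
#' @param smiles A single SMILES string.
#' @param max_conformers Conformer rows (default 3).
#' @param nbits Bits per conformer (default 2048).
#' @param seed Conformer-generation seed (default 1102).
#' @return Binary integer matrix of dim `(max_conformers, nbits)` with
#'   attribute `n_conformers`.
#' @export
encode_e3fp <- function(smiles, max_conformers = 3, nbits = 2048,
                        seed = 1102) {
  confs <- embed_conformers(smiles, seed = seed,
                            n_conformers = max_conformers)[[1]]
  if (is.null(confs)) {
    stop("3D embedding failed for SMILES: ", smiles)
  }
  n_conf <- min(length(confs), max_conformers)
  out <- matrix(0L, max_conformers, nbits)
  for (c_i in seq_len(n_conf)) {
    cf <- confs[[c_i]]
    coords <- as.matrix(cf[, c("x", "y", "z")])
    elem_code <- match(cf$element,
                       c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
                       nomatch = 10L)
    inv <- cbind(elem_code, cf$charge, cf$aromatic)
    ids <- conformer_identifiers(coords, inv)
    out[c_i, (ids %% nbits) + 1L] <- 1L
  }
  attr(out, "n_conformers") <- n_conf
  out
}

# Fixed one-hot bin tables for the atom feature vector.
atom_feature_groups <- function() {
  list(atom_type = c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "other"),
       degree = 0:6,           # clamped above 6
       formal_charge = 1,      # binary: charged or not
       hybridization = c("SP", "SP2", "SP3", "SP3D", "SP3D2", "other"),
       chirality = 1,
       radical = 1,
       aromatic = 1,
       configuration = c("R", "S"),
       h_count = 0:4)          # clamped above 4
}

#' Build the annotated atom interaction graph of a compound
#'
#' Nodes are the heavy atoms of the canonical molecule, each carrying a
#' 34-dimensional feature vector: atom type one-hot (10: C, N, O, F, P, S,
#' Cl, Br, I, other), heavy-atom degree one-hot (7 bins, 0-6, clamped),
#' formal-charge flag (1), hybridization one-hot (6: SP, SP2, SP3, SP3D,
#' SP3D2, other), chiral-center flag (1), radical flag (1), aromatic flag
#' (1), tetrahedral configuration one-hot (2; assigned from the canonical
#' SMILES parity mark, an approximation of CIP R/S), and attached-hydrogen
#' one-hot (5 bins, 0-4, clamped). Edges are the undirected bonds.
#'
#' @param smiles A single SMILES string.
#' @param degree_mode `"heavy"` (default: all heavy neighbours) or
#'   `"carbon"` (count only carbon neighbours).
#' @return A list of class `atom_graph`: `features` (n_atoms x 34 matrix),
#'   `adjacency` (symmetric 0/1 matrix), `edges` (bond data frame),
#'   `clamped` (ids of atoms whose degree or H-count hit the last bin).
#' @export
build_atom_graph <- function(smiles, degree_mode = c("heavy", "carbon")) {
  degree_mode <- match.arg(degree_mode)
  g <- mol_graph(smiles)
  atoms <- g$atoms
  n <- nrow(atoms)
  grp <- atom_feature_groups()

  deg <- atoms$degree
  if (degree_mode == "carbon") {
    deg <- vapply(seq_len(n), function(i) {
      nb <- c(g$bonds$j[g$bonds$i == i], g$bonds$i[g$bonds$j == i])
      sum(atoms$element[nb] == "C")
    }, 0L)
  }
  clamped <- character(0)
  feats <- matrix(0L, n, 34)
  for (i in seq_len(n)) {
    v <- integer(0)
    # atom type (10)
    at <- match(atoms$element[i], grp$atom_type[1:9], nomatch = 10L)
    v <- c(v, as.integer(seq_len(10) == at))
    # degree (7), clamped at 6
    d <- min(deg[i], 6L)
    if (deg[i] > 6L) clamped <- c(clamped, sprintf("atom%d:degree", i))
    v <- c(v, as.integer(0:6 == d))
    # formal charge flag (1)
    v <- c(v, as.integer(atoms$charge[i] != 0))
    # hybridization (6)
    hy <- switch(as.character(atoms$hybridization[i]),
                 "1" = 1L, "2" = 2L, "3" = 3L, "5" = 4L, "6" = 5L, 6L)
    v <- c(v, as.integer(seq_len(6) == hy))
    # chirality flag (1)
    v <- c(v, as.integer(nzchar(atoms$stereo[i])))
    # radical flag (1)
    v <- c(v, atoms$radical[i])
    # aromatic flag (1)
    v <- c(v, as.integer(atoms$aromatic[i]))
    # configuration (2): parity mark of the canonical SMILES
    v <- c(v, as.integer(atoms$stereo[i] == "@@"),
           as.integer(atoms$stereo[i] == "@"))
    # attached hydrogens (5), clamped at 4
    h <- min(atoms$n_h[i], 4L)
    if (atoms$n_h[i] > 4L) clamped <- c(clamped, sprintf("atom%d:h_count", i))
    v <- c(v, as.integer(0:4 == h))
    feats[i, ] <- v
  }
  adj <- matrix(0L, n, n)
  if (nrow(g$bonds) > 0) {
    adj[cbind(g$bonds$i, g$bonds$j)] <- 1L
    adj[cbind(g$bonds$j, g$bonds$i)] <- 1L
  }
  structure(list(features = feats, adjacency = adj, edges = g$bonds,
                 canonical_smiles = g$canonical_smiles, clamped = clamped),
            class = "atom_graph")
}
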
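# Target representations: sequence one-hot, physicochemical PCA lookup,
# weighted residue interaction graphs and external embedding loading.

#' One-hot encode an amino-acid sequence
#'
#' Row i is the one-hot vector of residue i over the canonical 20-letter
#' alphabet (see [aa_alphabet()] for the column order); rows beyond the
#' sequence length are zero padding.
#'
#' @param seq Amino-acid sequence of length at most `max_len`.
#' @param max_len Matrix height (default 1400).
#' @return Binary matrix of dim `(max_len, 20)` with attribute
#'   `true_length`.
#' @export
encode_sequence_onehot <- function(seq, max_len = 1400) {
  stopifnot(length(seq) == 1)
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) > max_len) {
    stop("sequence length ", length(chars), " exceeds encoder height ", max_len)
  }
  idx <- match(chars, aa_alphabet())
  if (anyNA(idx)) {
    stop("non-canonical residue(s): ",
         paste(unique(chars[is.na(idx)]), collapse = " "))
  }
  m <- matrix(0L, max_len, 20)
  if (length(chars) > 0) m[cbind(seq_along(chars), idx)] <- 1L
  attr(m, "true_length") <- length(chars)
  m
}

#' Synthetic amino-acid property table
#'
#' Generates a reproducible stand-in for a catalogue of per-residue
#' physicochemical indices (AAindex-style): a 20 x P matrix of correlated
#' Gaussian properties, one row per canonical residue. It is synthetic -
#' the values carry no chemical meaning - but has the shape, scale
#' diversity and inter-property correlation structure the PCA pipeline
#' expects, so the whole target featurization stack can be exercised
#' without an external download.
#'
#' @param n_properties Number of property columns P (default 512).
#' @param seed RNG seed.
#' @return Numeric matrix with rownames [aa_alphabet()].
#' @export
synthetic_aa_properties <- function(n_properties = 512, seed = 42) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  # latent low-dimensional residue traits + property-specific mixing
  latent <- matrix(stats::rnorm(20 * 8), 20, 8)
  mixing <- matrix(stats::rnorm(8 * n_properties), 8, n_properties)
  noise <- matrix(stats::rnorm(20 * n_properties, sd = 0.3), 20, n_properties)
  scales <- stats::runif(n_properties, 0.5, 20)
  m <- sweep(latent %*% mixing + noise, 2, scales, `*`)
  rownames(m) <- aa_alphabet()
  colnames(m) <- sprintf("prop%03d", seq_len(n_properties))
  m
}

#' Fit the physicochemical PCA projection
#'
#' Standardizes a 20 x P residue property table (z-score per property) and
#' fits a PCA reducing the P properties to `n_components` dimensions. The
#' fit population is the 20 residue types themselves, so the projection is
#' a sequence-independent per-residue lookup. Component signs are fixed by
#' convention (largest-magnitude loading positive) so the projection is
#' fully deterministic.
#'
#' @param property_table Numeric 20 x P matrix, rownames the residue
#'   letters.
#' @param n_components Output dimensionality (default 20).
#' @return A list of class `physchem_projection`: `rotation` (P x
#'   n_components), `center`, `scale`, `explained_variance_ratio`,
#'   `residue_matrix` (20 x n_components lookup, rownames residues).
#' @export
fit_physchem_pca <- function(property_table, n_components = 20) {
  stopifnot(nrow(property_table) == 20)
  if (ncol(property_table) < n_components) {
    stop("need at least ", n_components, " properties, got ",
         ncol(property_table))
  }
  if (anyNA(property_table)) stop("property table contains missing values")
  if (is.null(rownames(property_table))) rownames(property_table) <- aa_alphabet()
  ctr <- colMeans(property_table)
  scl <- apply(property_table, 2, stats::sd)
  if (any(scl == 0)) scl[scl == 0] <- 1
  z <- scale(property_table, center = ctr, scale = scl)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  # column centering removes one dimension from a 20-row table, so when
  # n_components equals the row count the last component necessarily has
  # (numerically) zero variance; tolerate exactly that one null direction
  # and error on any deeper rank deficiency.
  informative <- min(n_components, nrow(property_table) - 1)
  if (length(pc$sdev) < n_components ||
      pc$sdev[informative] < .Machine$double.eps^0.5 * pc$sdev[1]) {
    stop("property table has rank below ", informative,
         "; request fewer components")
  }
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-|loading| entry of each component is positive
  for (k in seq_len(ncol(rot))) {
    m <- which.max(abs(rot[, k]))
    if (rot[m, k] < 0) rot[, k] <- -rot[, k]
  }
  scores <- z %*% rot
  ev <- pc$sdev^2
  structure(list(rotation = rot, center = ctr, scale = scl,
                 explained_variance_ratio = ev / sum(ev),
                 residue_matrix = scores),
            class = "physchem_projection")
}

#' Encode a sequence as a physicochemical matrix
#'
#' Row i is the `n_components`-dimensional projected property vector of
#' residue i (looked up from the fitted projection), zero-padded to
#' `max_len` rows.
#'
#' @param seq Amino-acid sequence.
#' @param projection A [fit_physchem_pca()] result.
#' @param max_len Matrix height (default 1400).
#' @return Numeric matrix `(max_len, n_components)` with attribute
#'   `true_length`.
#' @export
encode_physchem <- function(seq, projection, max_len = 1400) {
  stopifnot(inherits(projection, "physchem_projection"))
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) > max_len) {
    stop("sequence length ", length(chars), " exceeds encoder height ", max_len)
  }
  idx <- match(chars, rownames(projection$residue_matrix))
  if (anyNA(idx)) {
    stop("non-canonical residue(s): ",
         paste(unique(chars[is.na(idx)]), collapse = " "))
  }
  m <- matrix(0, max_len, ncol(projection$residue_matrix))
  if (length(chars) > 0) m[seq_along(chars), ] <- projection$residue_matrix[idx, ]
  attr(m, "true_length") <- length(chars)
  m
}

#' Residue interaction types and their dissociation energies
#'
#' The fixed weight table for residue interaction networks: disulfide
#' bridges 167, ionic bonds 20, hydrogen bonds 17, pi-cation 9.6, pi-pi
#' stacking 9.4, van der Waals 6 (dissociation energies as assigned by
#' RING-style contact typing).
#'
#' @return Named numeric vector.
#' @export
residue_interaction_energies <- function() {
  c(disulfide = 167, ionic = 20, hydrogen = 17,
    pi_cation = 9.6, pi_pi = 9.4, vdw = 6)
}

#' Build a weighted residue interaction graph
#'
#' Nodes are residues with projected physicochemical feature vectors;
#' edges come from a typed contact list and are weighted solely by the
#' interaction type via the fixed dissociation-energy table
#' ([residue_interaction_energies()]). Undirected, no self-loops.
#'
#' @param seq Amino-acid sequence.
#' @param contacts Data frame with columns `res_i`, `res_j` (1-based
#'   residue indices) and `type` (one of the six interaction types).
#' @param projection A [fit_physchem_pca()] result for node features.
#' @param max_len Padded node count (default 1400); residues beyond the
#'   sequence are zero-feature isolated nodes.
#' @return A list of class `residue_graph`: `features`, `edges` (res_i,
#'   res_j, type, weight), `true_length`.
#' @export
build_residue_graph <- function(seq, contacts, projection, max_len = 1400) {
  n <- nchar(seq)
  energies <- residue_interaction_energies()
  if (nrow(contacts) > 0) {
    bad_type <- !(contacts$type %in% names(energies))
    if (any(bad_type)) {
      stop("unknown interaction type(s): ",
           paste(unique(contacts$type[bad_type]), collapse = ", "))
    }
    if (any(contacts$res_i < 1 | contacts$res_i > n |
            contacts$res_j < 1 | contacts$res_j > n)) {
      stop("contact indices out of range 1..", n)
    }
    if (any(contacts$res_i == contacts$res_j)) {
      stop("self-loop contacts are not allowed")
    }
  }
  feats <- encode_physchem(seq, projection, max_len = max_len)
  edges <- data.frame(
    res_i = contacts$res_i, res_j = contacts$res_j,
    type = contacts$type,
    weight = unname(energies[contacts$type]),
    stringsAsFactors = FALSE)
  structure(list(features = feats, edges = edges, true_length = n),
            class = "residue_graph")
}

#' Read a typed residue contact list
#'
#' TSV with columns `target_id`, `res_i`, `res_j`, `type`; indices are
#' 1-based residue positions.
#'
#' @param path TSV path.
#' @return Data frame of contacts.
#' @export
read_contacts <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write a typed residue contact list
#' @param contacts Data frame with `target_id`, `res_i`, `res_j`, `type`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(contacts, path) {
  utils::write.table(contacts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Expected dimensionalities of supported protein embedding schemes
#' @return Named integer vector (`UNIREP` 1900, `BERT` 768).
#' @export
embedding_schemes <- function() c(UNIREP = 1900L, BERT = 768L)

#' Load per-target protein embeddings
#'
#' Reads a tabular embedding file (TSV: first column `target_id`, then one
#' column per dimension) and validates every vector against the declared
#' scheme length - 1900 for UniRep-style, 768 for BERT-style, or any
#' explicit integer for other schemes.
#'
#' @param path TSV path.
#' @param scheme `"UNIREP"`, `"BERT"`, or an integer dimensionality.
#' @return Numeric matrix, rownames target ids; attribute `scheme`.
#' @export
load_embedding <- function(path, scheme) {
  expected <- if (is.numeric(scheme)) as.integer(scheme)
              else unname(embedding_schemes()[toupper(scheme)])
  if (length(expected) != 1 || is.na(expected)) {
    stop("unknown embedding scheme: ", scheme)
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  ids <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (ncol(m) != expected) {
    stop("embedding dimension mismatch: scheme ", scheme, " expects ",
         expected, ", file has ", ncol(m))
  }
  rownames(m) <- ids
  attr(m, "scheme") <- scheme
  m
}

#' Write per-target protein embeddings
#' @param embeddings Numeric matrix with rownames = target ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embeddings, path) {
  df <- data.frame(target_id = rownames(embeddings), embeddings,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
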
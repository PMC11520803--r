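# Chemistry backend: SMILES parsing, canonicalization, molecular graphs and
# 2D fingerprints via ChemmineR / ChemmineOB (Open Babel).

.chem_cache <- new.env(parent = emptyenv())

cache_get <- function(key) {
  if (exists(key, envir = .chem_cache, inherits = FALSE)) {
    get(key, envir = .chem_cache, inherits = FALSE)
  } else NULL
}
cache_set <- function(key, value) {
  assign(key, value, envir = .chem_cache)
  value
}

ob_convert <- function(from, to, source, options = NULL) {
  if (is.null(options)) {
    ChemmineOB::convertFormat(from, to, source)
  } else {
    ChemmineOB::convertFormat(from, to, source, options = options)
  }
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the Open Babel canonical form, so that different
#' spellings of the same molecule map to the same string. Unparseable
#' inputs either error (default) or come back as `NA`.
#'
#' @param smiles Character vector of SMILES.
#' @param error_on_fail Error on unparseable input instead of returning NA?
#' @return Character vector of canonical SMILES (with `NA` for failures
#'   when `error_on_fail = FALSE`).
#' @export
smiles_canonical <- function(smiles, error_on_fail = TRUE) {
  out <- vapply(smiles, function(s) {
    key <- paste0("can\r", s)
    hit <- cache_get(key)
    if (!is.null(hit)) return(hit)
    res <- tryCatch({
      txt <- suppressWarnings(suppressMessages(
        utils::capture.output(
          v <- ob_convert("SMI", "CAN", paste0(s, "\tx")),
          type = "message")))
      v <- sub("\t.*$", "", sub("\n$", "", v))
      v <- strsplit(v, "\n")[[1]][1]
      if (is.null(v) || is.na(v) || !nzchar(v)) NA_character_ else v
    }, error = function(e) NA_character_)
    cache_set(key, res)
  }, character(1), USE.NAMES = FALSE)
  if (error_on_fail && any(is.na(out))) {
    stop("unparseable SMILES: ",
         paste(utils::head(smiles[is.na(out)], 5), collapse = ", "))
  }
  out
}

#' Test whether SMILES strings are parseable
#' @param smiles Character vector.
#' @return Logical vector.
#' @export
smiles_parseable <- function(smiles) {
  !is.na(smiles_canonical(smiles, error_on_fail = FALSE))
}

# Tokenize a SMILES string into atom tokens, in order of appearance.
# Returns a data frame with columns: symbol (element, capitalized),
# aromatic (lowercase in source), stereo ("", "@", "@@").
# Atom order matches the atom order Open Babel uses when converting the
# same string to SDF.
smiles_atom_tokens <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  sym <- character(0); arom <- logical(0); stereo <- character(0)
  i <- 1
  two_letter <- c("Cl", "Br")
  organic <- c("B", "C", "N", "O", "P", "S", "F", "I")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1
      body <- paste(chars[(i + 1):(j - 1)], collapse = "")
      # strip isotope
      body2 <- sub("^[0-9]*", "", body)
      m <- regmatches(body2, regexpr("^([A-Z][a-z]?|[a-z]{1,2}|\\*)", body2))
      st <- if (grepl("@@", body2)) "@@" else if (grepl("@", body2)) "@" else ""
      is_ar <- grepl("^[a-z]", m)
      sym <- c(sym, if (m == "*") "*" else paste0(toupper(substr(m, 1, 1)),
                                                 substring(m, 2)))
      arom <- c(arom, is_ar)
      stereo <- c(stereo, st)
      i <- j + 1
    } else if (i < n && paste0(ch, chars[i + 1]) %in% two_letter) {
      sym <- c(sym, paste0(ch, chars[i + 1]))
      arom <- c(arom, FALSE); stereo <- c(stereo, "")
      i <- i + 2
    } else if (ch %in% organic || ch == "*") {
      sym <- c(sym, ch); arom <- c(arom, FALSE); stereo <- c(stereo, "")
      i <- i + 1
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      sym <- c(sym, toupper(ch)); arom <- c(arom, TRUE); stereo <- c(stereo, "")
      i <- i + 1
    } else {
      i <- i + 1
    }
  }
  data.frame(symbol = sym, aromatic = arom, stereo = stereo,
             stringsAsFactors = FALSE)
}

# Parse a V2000 SDF/MOL text block into atoms (element, x, y, z, charge,
# radical) and bonds (i, j, order). Only the first molecule is read.
parse_molblock <- function(txt) {
  lines <- strsplit(txt, "\n")[[1]]
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  at <- lines[4 + seq_len(natoms)]
  element <- trimws(substr(at, 32, 34))
  x <- as.numeric(substr(at, 1, 10))
  y <- as.numeric(substr(at, 11, 20))
  z <- as.numeric(substr(at, 21, 30))
  bd <- if (nbonds > 0) lines[4 + natoms + seq_len(nbonds)] else character(0)
  bi <- as.integer(substr(bd, 1, 3))
  bj <- as.integer(substr(bd, 4, 6))
  bo <- as.integer(substr(bd, 7, 9))
  charge <- integer(natoms)
  radical <- integer(natoms)
  for (ln in grep("^M  (CHG|RAD)", lines, value = TRUE)) {
    fields <- strsplit(trimws(substring(ln, 7)), "\\s+")[[1]]
    k <- as.integer(fields[1])
    prop <- substr(ln, 4, 6)
    for (e in seq_len(k)) {
      idx <- as.integer(fields[2 * e])
      val <- as.integer(fields[2 * e + 1])
      if (prop == "CHG") charge[idx] <- val else radical[idx] <- val
    }
  }
  list(atoms = data.frame(element = element, x = x, y = y, z = z,
                          charge = charge, radical = radical,
                          stringsAsFactors = FALSE),
       bonds = data.frame(i = bi, j = bj, order = bo))
}

# Parse Open Babel "molreport" output: per-atom type and hybridization.
parse_molreport <- function(txt) {
  lines <- strsplit(txt, "\n")[[1]]
  at <- grep("^ATOM:", lines, value = TRUE)
  type <- sub(".*TYPE: *([^ ]+).*", "\\1", at)
  hyb <- as.integer(sub(".*HYB: *([0-9]+).*", "\\1", at))
  data.frame(type = type, hyb = hyb, stringsAsFactors = FALSE)
}

#' Parse a SMILES string into an annotated molecular graph
#'
#' Builds the heavy-atom graph of a molecule with per-atom annotations
#' (element, aromaticity, hybridization, formal charge, radical flag,
#' attached hydrogen count, heavy-atom degree, tetrahedral stereo mark) and
#' per-bond annotations (order, ring membership). The atom order is the
#' canonical order of the Open Babel canonical SMILES, so the result is
#' invariant to the input spelling.
#'
#' @param smiles A single SMILES string.
#' @return A list of class `mol_graph` with elements `atoms` (data frame),
#'   `bonds` (data frame with columns `i`, `j`, `order`, `in_ring`),
#'   `canonical_smiles`.
#' @export
mol_graph <- function(smiles) {
  stopifnot(length(smiles) == 1)
  can <- smiles_canonical(smiles)
  key <- paste0("graph\r", can)
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)

  toks <- smiles_atom_tokens(can)
  sdf_h <- ob_convert("SMI", "SDF", paste0(can, "\tm"),
                      options = data.frame(names = "h", args = ""))
  mb <- parse_molblock(sdf_h)
  rep_txt <- ob_convert("SMI", "molreport", paste0(can, "\tm"))
  mr <- parse_molreport(rep_txt)

  heavy <- which(mb$atoms$element != "H")
  n_heavy <- length(heavy)
  if (n_heavy != nrow(toks)) {
    stop("atom bookkeeping mismatch for SMILES: ", smiles)
  }
  # explicit H counting: H neighbours of each heavy atom in the H-added SDF
  nH <- integer(n_heavy)
  heavy_pos <- match(seq_len(nrow(mb$atoms)), heavy)  # sdf idx -> heavy idx
  deg <- integer(n_heavy)
  keep_bond <- logical(nrow(mb$bonds))
  for (b in seq_len(nrow(mb$bonds))) {
    i <- mb$bonds$i[b]; j <- mb$bonds$j[b]
    ei <- mb$atoms$element[i]; ej <- mb$atoms$element[j]
    if (ei == "H" && ej != "H") {
      nH[heavy_pos[j]] <- nH[heavy_pos[j]] + 1L
    } else if (ej == "H" && ei != "H") {
      nH[heavy_pos[i]] <- nH[heavy_pos[i]] + 1L
    } else if (ei != "H" && ej != "H") {
      keep_bond[b] <- TRUE
      deg[heavy_pos[i]] <- deg[heavy_pos[i]] + 1L
      deg[heavy_pos[j]] <- deg[heavy_pos[j]] + 1L
    }
  }
  bonds <- mb$bonds[keep_bond, , drop = FALSE]
  bonds$i <- heavy_pos[bonds$i]
  bonds$j <- heavy_pos[bonds$j]
  rownames(bonds) <- NULL

  # ring membership: a bond is in a ring iff it is not a bridge
  in_ring <- rep(FALSE, nrow(bonds))
  if (nrow(bonds) > 0) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = bonds$i, to = bonds$j),
      directed = FALSE,
      vertices = data.frame(name = seq_len(n_heavy)))
    br <- igraph::bridges(g)
    in_ring <- !(seq_len(nrow(bonds)) %in% as.integer(br))
  }
  bonds$in_ring <- in_ring

  hyb <- if (nrow(mr) == n_heavy) mr$hyb else rep(3L, n_heavy)
  atoms <- data.frame(
    element = toks$symbol,
    aromatic = toks$aromatic,
    hybridization = hyb,
    charge = mb$atoms$charge[heavy],
    radical = as.integer(mb$atoms$radical[heavy] > 0),
    n_h = nH,
    degree = deg,
    stereo = toks$stereo,
    stringsAsFactors = FALSE
  )
  out <- structure(list(atoms = atoms, bonds = bonds,
                        canonical_smiles = can),
                   class = "mol_graph")
  cache_set(key, out)
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d heavy atoms, %d bonds (%d in rings)\n",
              x$canonical_smiles, nrow(x$atoms), nrow(x$bonds),
              sum(x$bonds$in_ring)))
  invisible(x)
}

# OR-fold a binary matrix of width w to `nbits` columns (w multiple of nbits
# or nbits > w, in which case the matrix is zero-padded).
fold_bits <- function(mat, nbits) {
  w <- ncol(mat)
  if (w == nbits) return(mat)
  if (w < nbits) {
    return(cbind(mat, matrix(0L, nrow(mat), nbits - w)))
  }
  stopifnot(w %% nbits == 0)
  out <- matrix(0L, nrow(mat), nbits)
  for (blk in seq_len(w / nbits)) {
    out <- pmax(out, mat[, (blk - 1) * nbits + seq_len(nbits), drop = FALSE])
  }
  out
}

ob_fingerprint <- function(smiles, name) {
  vapply_rows <- function(s) {
    key <- paste0("fp", name, "\r", s)
    hit <- cache_get(key)
    if (!is.null(hit)) return(hit)
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(s, "m")))
    fp <- ChemmineR::fingerprintOB(sdf, name)
    cache_set(key, as.integer(methods::slot(fp, "fpma")[1, ]))
  }
  can <- smiles_canonical(smiles)
  mat <- t(vapply(can, vapply_rows, integer(
    switch(name, FP2 = 1024L, MACCS = 256L, ECFP4 = 4096L,
           stop("unknown OB fingerprint: ", name))),
    USE.NAMES = FALSE))
  rownames(mat) <- names(smiles)
  mat
}

#' Morgan (circular, radius 2) fingerprints
#'
#' Extended-connectivity fingerprints of diameter 4 (radius 2), computed by
#' Open Babel and OR-folded to `nbits`.
#'
#' @param smiles Character vector of SMILES.
#' @param nbits Folded width (default 2048).
#' @return Binary integer matrix, one row per molecule.
#' @export
fp_morgan <- function(smiles, nbits = 2048) {
  fold_bits(ob_fingerprint(smiles, "ECFP4"), nbits)
}

#' MACCS structural key fingerprints (167 bits)
#'
#' @param smiles Character vector of SMILES.
#' @return Binary integer matrix with 167 columns.
#' @export
fp_maccs <- function(smiles) {
  ob_fingerprint(smiles, "MACCS")[, 1:167, drop = FALSE]
}

#' Topological path-based fingerprints (1024 bits)
#'
#' Linear-fragment (path) fingerprints up to length 7, hashed to 1024 bits
#' (Open Babel FP2).
#'
#' @param smiles Character vector of SMILES.
#' @param nbits Folded width (default 1024).
#' @return Binary integer matrix.
#' @export
fp_path <- function(smiles, nbits = 1024) {
  fold_bits(ob_fingerprint(smiles, "FP2"), nbits)
}

# The most frequent atom-pair descriptors shipped with ChemmineR, used as
# the fixed bit assignment of the atom-pair fingerprint.
ap_descnames <- function(nbits) {
  key <- paste0("apdesc", nbits)
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)
  e <- new.env()
  utils::data("apfp", package = "ChemmineR", envir = e)
  cache_set(key, as.character(e$apfp$AP)[seq_len(nbits)])
}

#' Atom-pair fingerprints (1024 bits)
#'
#' Atom-pair descriptors hashed to a fixed-width binary fingerprint.
#' Molecules too small to define an atom pair give an all-zero row.
#'
#' @param smiles Character vector of SMILES.
#' @param nbits Width (default 1024).
#' @return Binary integer matrix.
#' @export
fp_atompair <- function(smiles, nbits = 1024) {
  can <- smiles_canonical(smiles)
  rows <- lapply(can, function(s) {
    key <- paste0("fpAP", nbits, "\r", s)
    hit <- cache_get(key)
    if (!is.null(hit)) return(hit)
    v <- tryCatch({
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(s, "m")))
      ap <- suppressWarnings(ChemmineR::sdf2ap(sdf))
      m <- ChemmineR::desc2fp(ap, descnames = ap_descnames(nbits),
                              type = "matrix")
      as.integer(m[1, ])
    }, error = function(e) integer(nbits))
    if (length(v) != nbits) v <- integer(nbits)
    cache_set(key, v)
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(smiles)
  mat
}

#' Generate deterministic 3D conformers for molecules
#'
#' Embeds each molecule in 3D with the ETKDG distance-geometry method
#' (RDKit backend, invoked through its command-line interpreter) at a
#' fixed random seed, so repeated calls give identical coordinates. Up to
#' `n_conformers` distinct conformers are returned per molecule; heavy
#' atoms only.
#'
#' @param smiles Character vector of SMILES.
#' @param seed Embedding seed (default 1102).
#' @param n_conformers Maximum conformers per molecule (default 3).
#' @return A named list (by input name or SMILES); each element is a list
#'   of conformers, each a data frame with `element`, `charge`,
#'   `aromatic`, `x`, `y`, `z`. Molecules that fail embedding are `NULL`.
#' @export
embed_conformers <- function(smiles, seed = 1102, n_conformers = 3) {
  can <- smiles_canonical(smiles)
  ids <- names(smiles)
  if (is.null(ids)) ids <- can
  keys <- paste0("conf", seed, "x", n_conformers, "\r", can)
  out <- stats::setNames(vector("list", length(can)), ids)
  todo <- integer(0)
  for (i in seq_along(can)) {
    hit <- cache_get(keys[i])
    if (!is.null(hit)) out[[i]] <- hit$value else todo <- c(todo, i)
  }
  if (length(todo) > 0) {
    helper <- system.file("python", "embed_conformers.py",
                          package = "ctibench")
    if (!nzchar(helper)) stop("conformer helper script not found")
    infile <- tempfile(fileext = ".tsv")
    on.exit(unlink(infile), add = TRUE)
    writeLines(paste(seq_along(todo), can[todo], sep = "\t"), infile)
    res <- suppressWarnings(
      system2("python", c(helper, infile, seed, n_conformers),
              stdout = TRUE, stderr = FALSE))
    status <- attr(res, "status")
    if (!is.null(status) && status != 0) {
      stop("conformer embedding backend failed (exit ", status, ")")
    }
    parts <- strsplit(res[nzchar(res)], "\t", fixed = TRUE)
    ok <- vapply(parts, function(p) length(p) == 9, logical(1))
    tab <- NULL
    if (any(ok)) {
      m <- do.call(rbind, parts[ok])
      tab <- data.frame(idx = as.integer(m[, 1]),
                        conf = as.integer(m[, 2]),
                        atom = as.integer(m[, 3]),
                        element = m[, 4],
                        charge = as.integer(m[, 5]),
                        aromatic = as.integer(m[, 6]),
                        x = as.numeric(m[, 7]), y = as.numeric(m[, 8]),
                        z = as.numeric(m[, 9]),
                        stringsAsFactors = FALSE)
    }
    for (t in seq_along(todo)) {
      i <- todo[t]
      sub <- if (is.null(tab)) NULL else tab[tab$idx == t, , drop = FALSE]
      confs <- NULL
      if (!is.null(sub) && nrow(sub) > 0) {
        confs <- lapply(sort(unique(sub$conf)), function(ci) {
          s <- sub[sub$conf == ci, ]
          s <- s[order(s$atom), ]
          data.frame(element = s$element, charge = s$charge,
                     aromatic = s$aromatic, x = s$x, y = s$y, z = s$z,
                     stringsAsFactors = FALSE)
        })
      }
      cache_set(keys[i], list(value = confs))
      out[[i]] <- confs
    }
  }
  out
}
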
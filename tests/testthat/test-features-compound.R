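test_that("SMILES one-hot encoding is exact and strict", {
  expect_length(smiles_vocabulary(), 98)
  expect_false(any(duplicated(smiles_vocabulary())))

  m <- encode_smiles_onehot("CC")
  expect_equal(dim(m), c(348, 98))
  expect_equal(attr(m, "true_length"), 2L)
  ccol <- match("C", smiles_vocabulary())
  expect_equal(which(m[1, ] == 1), ccol)
  expect_equal(which(m[2, ] == 1), ccol)
  expect_true(all(m[3:348, ] == 0))
  expect_equal(rowSums(m[1:2, ]), c(1, 1))

  expect_error(encode_smiles_onehot("Cé"), "vocabulary")
  expect_error(encode_smiles_onehot(strrep("C", 349)), "exceeds")
})

test_that("the concatenated 2D fingerprint has the canonical layout", {
  smi <- c(benzene = "c1ccccc1", aspirin = "CC(=O)Oc1ccccc1C(=O)O")
  fp <- encode_2dfp(smi)
  expect_equal(ncol(fp), 3239)
  expect_true(all(fp %in% c(0L, 1L)))
  seg <- attr(fp, "segments")
  expect_equal(lengths(seg), c(morgan = 1024L, maccs = 167L,
                               path = 1024L, atompair = 1024L))
  # MACCS segment can never exceed its 167 keys
  expect_lte(max(rowSums(fp[, seg$maccs, drop = FALSE])), 167)

  # two spellings of one molecule give identical vectors
  a <- encode_2dfp(c(x = "OCC"))
  b <- encode_2dfp(c(x = "C(O)C"))
  expect_identical(a[1, ], b[1, ])

  # the Morgan segment preserves Morgan Tanimoto exactly
  seg_t <- tanimoto_similarity(fp[1, seg$morgan], fp[2, seg$morgan])
  direct <- fp_morgan(smi, 1024)
  expect_equal(seg_t, tanimoto_similarity(direct[1, ], direct[2, ]))
})

test_that("conformer fingerprints pad, seed and fail as contracted", {
  e <- encode_e3fp("c1ccccc1")
  expect_equal(dim(e), c(3, 2048))
  expect_equal(attr(e, "n_conformers"), 1L)   # rigid: a single conformer
  expect_true(all(e[2:3, ] == 0))
  expect_gt(sum(e[1, ]), 0)

  flex <- encode_e3fp("CCOCCN")
  expect_equal(dim(flex), c(3, 2048))
  expect_true(all(flex %in% c(0L, 1L)))

  # determinism: a fresh computation (cache cleared) reproduces the bits
  cache <- ctibench:::.chem_cache
  snapshot <- encode_e3fp("CCOCC")
  rm(list = ls(envir = cache), envir = cache)
  expect_identical(encode_e3fp("CCOCC"), snapshot)

  expect_error(encode_e3fp("C1CC"), "unparseable")
})

test_that("atom graphs carry 34-d features with coherent one-hot groups", {
  ag <- build_atom_graph("c1ccccc1")
  expect_equal(ncol(ag$features), 34)
  expect_equal(nrow(ag$features), 6)
  # benzene: 2-regular, symmetric adjacency
  expect_identical(ag$adjacency, t(ag$adjacency))
  expect_true(all(rowSums(ag$adjacency) == 2))

  grp_cols <- list(atom_type = 1:10, degree = 11:17, charge = 18,
                   hybrid = 19:24, chiral = 25, radical = 26,
                   aromatic = 27, config = 28:29, h_count = 30:34)
  f <- ag$features[1, ]
  expect_equal(which(f[grp_cols$atom_type] == 1), 1)     # carbon
  expect_equal(which(f[grp_cols$degree] == 1) - 1, 2)    # two heavy nbrs
  expect_equal(which(f[grp_cols$hybrid] == 1), 2)        # SP2
  expect_equal(f[[grp_cols$aromatic]], 1L)
  expect_equal(which(f[grp_cols$h_count] == 1) - 1, 1)   # one hydrogen

  # mandatory groups are exactly one-hot on every atom of varied molecules
  for (smi in c("CC(=O)Nc1ccc(O)cc1", "C[N+](C)(C)C", "ClCBr")) {
    feats <- build_atom_graph(smi)$features
    for (g in c("atom_type", "degree", "hybrid", "h_count")) {
      expect_true(all(rowSums(feats[, grp_cols[[g]], drop = FALSE]) == 1),
                  label = paste(smi, g))
    }
    for (g in c("config")) {
      expect_true(all(rowSums(feats[, grp_cols[[g]], drop = FALSE]) <= 1))
    }
  }

  # charged atom raises the formal-charge flag
  fq <- build_atom_graph("CC(=O)[O-]")$features
  expect_equal(sum(fq[, grp_cols$charge]), 1)

  # invariance to the input spelling
  g1 <- build_atom_graph("OCC")
  g2 <- build_atom_graph("C(O)C")
  expect_identical(g1$features, g2$features)
  expect_identical(g1$adjacency, g2$adjacency)
})

test_that("a stereocentre sets the chirality flag and one parity bit", {
  ag <- build_atom_graph("C[C@H](N)C(=O)O")   # L-alanine
  chiral_rows <- which(ag$features[, 25] == 1)
  expect_length(chiral_rows, 1)
  expect_equal(sum(ag$features[chiral_rows, 28:29]), 1)
})
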
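test_that("sequence one-hot encoding is shaped and padded correctly", {
  m <- encode_sequence_onehot("ACD")
  expect_equal(dim(m), c(1400, 20))
  expect_equal(attr(m, "true_length"), 3L)
  expect_equal(rowSums(m[1:3, ]), c(1, 1, 1))
  expect_true(all(m[4:1400, ] == 0))
  expect_equal(which(m[1, ] == 1), match("A", aa_alphabet()))

  expect_error(encode_sequence_onehot("ACX"), "non-canonical")
  expect_error(encode_sequence_onehot(strrep("A", 1401)), "exceeds")
})

test_that("physicochemical PCA yields an orthonormal, ordered projection", {
  proj <- fix_projection()
  rot <- proj$rotation
  expect_equal(dim(rot), c(512, 20))
  expect_equal(t(rot) %*% rot, diag(20), tolerance = 1e-8,
               ignore_attr = TRUE)
  evr <- proj$explained_variance_ratio
  expect_true(all(diff(evr) <= 1e-12))

  # deterministic including component signs
  proj2 <- fit_physchem_pca(synthetic_aa_properties(seed = 42))
  expect_equal(proj2$rotation, rot)

  expect_error(fit_physchem_pca(matrix(1, 20, 10)), "properties|rank")
})

test_that("PCA recovers a planted dominant direction", {
  # one latent direction explains almost all variance; the leading
  # loading must align with the known mixing vector (eigen oracle)
  set.seed(5)
  direction <- rnorm(64)
  direction <- direction / sqrt(sum(direction^2))
  scores <- rnorm(20, sd = 10)
  tab <- outer(scores, direction) + matrix(rnorm(20 * 64, sd = 0.01), 20, 64)
  rownames(tab) <- aa_alphabet()
  proj <- fit_physchem_pca(tab, n_components = 19)
  z <- scale(tab)
  oracle_v <- eigen(crossprod(z) / 19)$vectors[, 1]
  expect_gt(abs(sum(proj$rotation[, 1] * oracle_v)), 0.999)
  expect_gt(proj$explained_variance_ratio[1], 0.95)
})

test_that("projection round-trip loses only out-of-basis variance", {
  proj <- fix_projection()
  tab <- synthetic_aa_properties(seed = 42)
  z <- scale(tab, center = proj$center, scale = proj$scale)
  recon <- proj$residue_matrix %*% t(proj$rotation)
  resid <- z - recon
  total <- sum(z^2)
  kept <- sum(proj$explained_variance_ratio[1:20])
  expect_equal(sum(resid^2) / total, 1 - kept, tolerance = 1e-8)
})

test_that("physicochemical encoding is a per-residue lookup", {
  proj <- fix_projection()
  m <- encode_physchem("ACDA", proj)
  expect_equal(dim(m), c(1400, 20))
  expect_equal(m[1, ], m[4, ])                       # same residue letter
  expect_true(all(m[5:1400, ] == 0))
  # row equals the projection applied to the raw property vector
  tab <- synthetic_aa_properties(seed = 42)
  raw_c <- (tab["C", ] - proj$center) / proj$scale
  expect_equal(m[2, ], as.numeric(raw_c %*% proj$rotation),
               tolerance = 1e-10)
  # same residue, different sequence and position: identical rows
  m2 <- encode_physchem("WWC", proj)
  expect_equal(m2[3, ], m[2, ])
})

test_that("residue graphs weight edges solely by interaction type", {
  proj <- fix_projection()
  rg <- build_residue_graph("ACCDE",
                            data.frame(res_i = c(2, 1), res_j = c(3, 5),
                                       type = c("disulfide", "vdw")),
                            proj)
  expect_equal(rg$edges$weight, c(167, 6))
  expect_equal(sort(unname(residue_interaction_energies())),
               sort(c(167, 20, 17, 9.6, 9.4, 6)))

  empty <- build_residue_graph("ACD", data.frame(res_i = integer(0),
                                                 res_j = integer(0),
                                                 type = character(0)), proj)
  expect_equal(nrow(empty$edges), 0)

  expect_error(build_residue_graph("ACD",
                                   data.frame(res_i = 1, res_j = 2,
                                              type = "covalent"), proj),
               "unknown interaction")
  expect_error(build_residue_graph("ACD",
                                   data.frame(res_i = 1, res_j = 9,
                                              type = "vdw"), proj),
               "out of range")
  expect_error(build_residue_graph("ACD",
                                   data.frame(res_i = 2, res_j = 2,
                                              type = "vdw"), proj),
               "self-loop")
})

test_that("embedding files validate against their declared scheme", {
  emb <- matrix(rnorm(3 * 768), 3, 768,
                dimnames = list(c("t1", "t2", "t3"), NULL))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_embedding(emb, path)
  back <- load_embedding(path, "BERT")
  expect_equal(dim(back), c(3, 768))
  expect_equal(rownames(back), c("t1", "t2", "t3"))
  expect_equal(unname(back), unname(emb), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(attr(back, "scheme"), "BERT")

  expect_error(load_embedding(path, "UNIREP"), "1900.*768|mismatch")
  expect_equal(ncol(load_embedding(path, 768)), 768)
  expect_error(load_embedding(path, "WORD2VEC"), "unknown")
})
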
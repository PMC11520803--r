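test_that("Tanimoto similarity matches set arithmetic", {
  expect_equal(tanimoto_similarity(c(1, 1, 1, 0), c(1, 1, 1, 0)), 1)
  expect_equal(tanimoto_similarity(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  # A = {1,2,3}, B = {2,3,4}: intersection 2, union 4
  expect_equal(tanimoto_similarity(c(1, 1, 1, 0), c(0, 1, 1, 1)), 0.5)
  # two all-zero vectors are identical by convention
  expect_equal(tanimoto_similarity(c(0, 0), c(0, 0)), 1)
  expect_error(tanimoto_similarity(c(1, 0), c(1, 0, 1)), "mismatch")
})

test_that("negative generation selects the most distant candidates", {
  # binders {d1}; candidates at Tanimoto 0.9 / 0.1 / 0.5 from d1, via
  # crafted bit patterns: 9/10, 1/10 (one shared of ten), 5/10
  fp_table <- rbind(
    d1 = c(rep(1, 10), rep(0, 10)),
    c_sim = c(rep(1, 9), 0, 1, rep(0, 9)),     # 9/11
    c_far = c(1, rep(0, 9), rep(1, 9), 0),     # 1/19
    c_mid = c(rep(1, 5), rep(0, 5), rep(1, 5), rep(0, 5)))  # 5/15
  lookup_fp <- function(s) fp_table[s, , drop = FALSE]
  spec <- negative_sampling_spec(k = 1, fingerprint = lookup_fp)
  res <- generate_negatives("t", c(d1 = "d1"),
                            c(c_sim = "c_sim", c_far = "c_far",
                              c_mid = "c_mid"), spec)
  expect_equal(res$records$compound_id, "c_far")
  expect_true(all(res$records$label == 0L))

  spec2 <- negative_sampling_spec(k = 2, fingerprint = lookup_fp)
  res2 <- generate_negatives("t", c(d1 = "d1"),
                             c(c_sim = "c_sim", c_far = "c_far",
                               c_mid = "c_mid"), spec2)
  expect_equal(res2$records$compound_id, c("c_far", "c_mid"))

  # a candidate identical to a binder has distance 0 and is never taken
  # while better candidates remain
  fp3 <- rbind(fp_table, c_same = fp_table["d1", ])
  spec3 <- negative_sampling_spec(k = 3,
                                  fingerprint = function(s) fp3[s, , drop = FALSE])
  res3 <- generate_negatives("t", c(d1 = "d1"),
                             c(c_same = "c_same", c_sim = "c_sim",
                               c_far = "c_far", c_mid = "c_mid"), spec3)
  expect_false("c_same" %in% res3$records$compound_id)

  expect_error(generate_negatives("t", character(0), c(a = "x"), spec),
               "empty")
  expect_error(generate_negatives("t", c(d1 = "d1"), c(c_sim = "c_sim"),
                                  negative_sampling_spec(k = 5,
                                                         fingerprint = lookup_fp)),
               "exceeds")
})

test_that("negative generation agrees with the brute-force oracle", {
  set.seed(1509)
  for (trial in 1:60) {
    m <- sample(1:30, 1); n <- sample(2:30, 1); k <- sample(seq_len(n), 1)
    fpb <- matrix(rbinom(m * 64, 1, 0.3), m, 64,
                  dimnames = list(sprintf("b%02d", seq_len(m)), NULL))
    fpc <- matrix(rbinom(n * 64, 1, 0.3), n, 64,
                  dimnames = list(sprintf("c%02d", seq_len(n)), NULL))
    all_fp <- rbind(fpb, fpc)
    spec <- negative_sampling_spec(
      k = k, fingerprint = function(s) all_fp[s, , drop = FALSE])
    res <- generate_negatives(
      "t", setNames(rownames(fpb), rownames(fpb)),
      setNames(rownames(fpc), rownames(fpc)), spec)
    expected <- rownames(fpc)[negatives_oracle(fpb, fpc, k)]
    expect_equal(res$records$compound_id, expected)
  }
})

test_that("generated negatives never duplicate a target's positives", {
  ds <- fix_dataset()
  pos <- ds$records[ds$records$label == 1L, ][1:40, ]
  class(pos) <- c("cti_records", "data.frame")
  neg <- generate_negatives_all(pos, ds$compounds,
                                negative_sampling_spec(k = 3))
  expect_true(all(neg$label == 0L))
  key_pos <- paste(pos$target_id, pos$compound_id)
  key_neg <- paste(neg$target_id, neg$compound_id)
  expect_length(intersect(key_pos, key_neg), 0)
})

test_that("derived k lands the negative:positive ratio in the expected band", {
  # the derived k needs a candidate pool comfortably larger than each
  # target's binder set, as in a positives-only database
  cmp <- gen_compounds(80, seed = 19)
  tgt <- gen_targets(10, seed = 20)
  pos <- gen_interactions(cmp, tgt,
                          synthetic_spec(n_pairs = 120, prevalence = 0.35,
                                         seed = 21))
  pos <- pos[pos$label == 1L, ]
  class(pos) <- c("cti_records", "data.frame")
  neg <- generate_negatives_all(pos, cmp, negative_sampling_spec(ratio = 2.5))
  ratio <- nrow(neg) / nrow(pos)
  expect_gte(ratio, 1.9)
  expect_lte(ratio, 3)
})

test_that("rotatable bond counting follows the strict definition", {
  p <- rotatable_bond_profile("CCCC")      # butane: one central bond
  expect_equal(p$n_rotatable, 1L)
  expect_equal(p$n_bonds, 3L)
  expect_equal(p$rbf, 1 / 3)

  expect_equal(rotatable_bond_profile("C")$n_rotatable, 0L)
  expect_equal(rotatable_bond_profile("C")$rbf, 0)      # 0/0 convention
  expect_equal(rotatable_bond_profile("c1ccccc1")$n_rotatable, 0L)
  # amide C-N bond is not rotatable; all other single bonds terminal
  expect_equal(rotatable_bond_profile("CC(=O)NC")$n_rotatable, 0L)
  # n-alkane with c carbons has c - 3 rotatable bonds
  expect_equal(rotatable_bond_profile(strrep("C", 13))$n_rotatable, 10L)
  expect_error(rotatable_bond_profile("C1CC"), "unparseable")
})

test_that("LRB and RRB filters cut at their thresholds inclusively", {
  recs <- cti_records(
    compound_id = c("ten", "eleven", "rigid"),
    smiles = c(strrep("C", 13), strrep("C", 14), "c1ccccc1"),
    target_id = "t", sequence = "ACD", label = 1L)

  kept <- filter_lrb(recs, max_rotatable = 10)
  expect_equal(kept$compound_id, c("ten", "rigid"))
  expect_equal(filter_lrb(recs[0, ], 10), recs[0, ])

  # rbf of tridecane is 10/12; inclusive at exactly that value
  rbf10 <- rotatable_bond_profile(strrep("C", 13))$rbf
  kept_r <- filter_rrb(recs, max_rbf = rbf10)
  expect_true("ten" %in% kept_r$compound_id)
  kept_r2 <- filter_rrb(recs, max_rbf = rbf10 - 1e-9)
  expect_false("ten" %in% kept_r2$compound_id)
  expect_true("rigid" %in% kept_r2$compound_id)  # rbf 0 always kept

  # idempotent and order-preserving
  twice <- filter_lrb(filter_lrb(recs, 10), 10)
  expect_equal(as.data.frame(twice), as.data.frame(kept))
})
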
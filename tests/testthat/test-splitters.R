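test_that("warm split spreads each entity across folds", {
  # one compound with 20 records over 2 folds: 10 and 10
  recs <- cti_records(compound_id = rep("c1", 20), smiles = "CCO",
                      target_id = sprintf("t%d", 1:20), sequence = "ACD",
                      label = rep(c(0L, 1L), 10))
  fa <- warm_split(recs, "compound", n_folds = 2, seed = 3)
  expect_equal(unname(tabulate(fa$fold_of, 2)), c(10, 10))

  # an entity with exactly n_folds records appears once per fold
  recs10 <- cti_records(compound_id = rep("c1", 10), smiles = "CCO",
                        target_id = sprintf("t%d", 1:10), sequence = "ACD",
                        label = 1L)
  fa10 <- warm_split(recs10, "compound", n_folds = 10, seed = 5)
  expect_equal(sort(fa10$fold_of), 1:10)

  # determinism under the seed
  ds <- fix_dataset()
  expect_identical(warm_split(ds$records, "target", 5, seed = 9)$fold_of,
                   warm_split(ds$records, "target", 5, seed = 9)$fold_of)

  # every entity with >= n_folds records hits every fold
  fa5 <- warm_split(ds$records, "compound", 5, seed = 2)
  cnt <- table(ds$records$compound_id)
  for (e in names(cnt)[cnt >= 5]) {
    expect_setequal(unique(fa5$fold_of[ds$records$compound_id == e]), 1:5)
  }
})

test_that("cold split blocks entities and respects capacity", {
  # counts [5,4,3,2,1], 2 folds, capacity 8: {c1,c3} and {c2,c4,c5}
  recs <- cti_records(
    compound_id = rep(paste0("c", 1:5), times = c(5, 4, 3, 2, 1)),
    smiles = "CCO", target_id = sprintf("t%d", 1:15), sequence = "ACD",
    label = 1L)
  fa <- cold_split(recs, "compound", n_folds = 2, capacity = 8)
  fold_of_entity <- tapply(fa$fold_of, recs$compound_id, unique)
  expect_length(unlist(fold_of_entity), 5)  # no entity spans folds
  expect_setequal(names(which(fold_of_entity == fold_of_entity[["c1"]])),
                  c("c1", "c3"))
  expect_equal(sort(unname(tabulate(fa$fold_of, 2))), c(7, 8))

  expect_error(cold_split(recs[1:5, ], "compound", n_folds = 2),
               "at least as many")
})

test_that("cold split keeps fold entity sets disjoint on random data", {
  for (seed in c(11, 12)) {
    n <- sample(c(50, 400, 2000), 1)
    ids <- sprintf("c%03d", sample(40, n, replace = TRUE))
    recs <- cti_records(compound_id = ids, smiles = "CCO",
                        target_id = "t1", sequence = "ACD", label = 1L)
    fa <- cold_split(recs, "compound", n_folds = 5)
    sets <- lapply(1:5, function(f) unique(ids[fa$fold_of == f]))
    for (i in 1:4) for (j in (i + 1):5) {
      expect_length(intersect(sets[[i]], sets[[j]]), 0)
    }
    # capacity respected except for flagged oversized entities
    sizes <- tabulate(fa$fold_of, 5)
    if (length(fa$flags) == 0) expect_true(all(sizes <= fa$capacity))
  }
})

test_that("an oversized entity is isolated and flagged", {
  ids <- c(rep("big", 30), sprintf("s%d", 1:10))
  recs <- cti_records(compound_id = ids, smiles = "CCO", target_id = "t1",
                      sequence = "ACD", label = 1L)
  fa <- cold_split(recs, "compound", n_folds = 4, capacity = 10)
  expect_equal(fa$flags, "big")
  expect_length(unique(fa$fold_of[ids == "big"]), 1)
})

test_that("normalized alignment similarity behaves like the DP oracle", {
  expect_equal(nw_similarity("ACDE", "ACDE"), 1)
  expect_equal(nw_similarity("AAAA", "CCCC"), 0)
  expect_equal(nw_similarity("ACDE", "ACE"), nw_oracle("ACDE", "ACE"))
  expect_error(nw_similarity("", "ACD"), "non-empty")

  set.seed(77)
  ab <- aa_alphabet()
  for (trial in 1:12) {
    a <- paste(sample(ab, sample(3:12, 1), replace = TRUE), collapse = "")
    b <- paste(sample(ab, sample(3:12, 1), replace = TRUE), collapse = "")
    expect_equal(nw_similarity(a, b), nw_oracle(a, b), tolerance = 1e-9)
    expect_equal(nw_similarity(a, b), nw_similarity(b, a))
  }
})

test_that("mutation-aware split partitions by variant with a ranked report", {
  ds <- synthetic_dataset(n_compounds = 15, n_targets = 12, n_pairs = 120,
                          mutant_fraction = 0.25, seed = 31)
  ms <- mutation_split(ds$records, top_n = 5)
  expect_true(all(ms$train$variant == "WILD"))
  expect_true(all(ms$test$variant == "MUTANT"))
  expect_equal(nrow(ms$train) + nrow(ms$test), nrow(ds$records))

  rep <- ms$similarity_report
  for (mt in unique(rep$mutant_target)) {
    sims <- rep$similarity[rep$mutant_target == mt]
    expect_true(all(diff(sims) <= 1e-12))  # descending
  }
  # each mutant is one substitution from its parent: top similarity ~ 1
  expect_true(all(tapply(rep$similarity, rep$mutant_target, max) > 0.95))

  no_mut <- ds$records[ds$records$variant == "WILD", ]
  class(no_mut) <- c("cti_records", "data.frame")
  expect_error(mutation_split(no_mut), "MUTANT")
})

test_that("the label-reversal validator flags planted violations", {
  train <- cti_records(compound_id = c("a", "a", "b", "c"), smiles = "CCO",
                       target_id = sprintf("t%d", 1:4), sequence = "ACD",
                       label = c(1L, 1L, 0L, 1L))
  test_ok <- cti_records(compound_id = c("a", "b"), smiles = "CCO",
                         target_id = c("t9", "t8"), sequence = "ACD",
                         label = c(0L, 1L))
  res <- verify_label_reversal(train, test_ok)
  expect_true(res$pass)
  expect_equal(res$per_compound$n_train[res$per_compound$compound_id == "a"], 2L)

  test_bad <- cti_records(compound_id = "a", smiles = "CCO",
                          target_id = "t9", sequence = "ACD", label = 1L)
  res_bad <- verify_label_reversal(train, test_bad)
  expect_false(res_bad$pass)
  expect_equal(res_bad$violations, "a")

  # disjoint compound sets pass vacuously
  test_new <- cti_records(compound_id = "z", smiles = "CCO",
                          target_id = "t9", sequence = "ACD", label = 1L)
  res_vac <- verify_label_reversal(train, test_new)
  expect_true(res_vac$pass)
  expect_equal(nrow(res_vac$per_compound), 0)
})

test_that("fold assignments round-trip through disk", {
  ds <- fix_dataset()
  fa <- cold_split(ds$records, "target", n_folds = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fold_assignment(fa, path)
  back <- read_fold_assignment(path)
  expect_equal(back$fold_of, fa$fold_of)
  expect_equal(back$scenario, fa$scenario)
  expect_equal(back$capacity, fa$capacity)
})
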
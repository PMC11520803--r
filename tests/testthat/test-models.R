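test_that("graph attention matches the scalar oracle on small graphs", {
  set.seed(404)
  for (trial in 1:25) {
    n <- sample(2:6, 1)
    d_in <- sample(2:4, 1); d_out <- sample(2:4, 1)
    A <- matrix(rbinom(n * n, 1, 0.5), n, n)
    A <- (A + t(A)) > 0; diag(A) <- 0
    X <- matrix(rnorm(n * d_in), n, d_in)
    p <- gatv2_params(d_in, d_out, seed = trial)
    got <- gatv2_layer(X, A, p)
    want <- gatv2_oracle(X, A, p$W, p$a)
    expect_equal(unclass(got), want, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("attention weights are a proper softmax over neighbourhoods", {
  set.seed(9)
  X <- matrix(rnorm(12), 4, 3)
  A <- matrix(0, 4, 4); A[1, 2] <- A[2, 1] <- 1  # nodes 3, 4 isolated
  p <- gatv2_params(3, 2, seed = 2)
  out <- gatv2_layer(X, A, p)
  al <- attr(out, "alpha")
  expect_equal(rowSums(al), rep(1, 4))
  # a single neighbour gets attention 1, update sigma(W_r f_j)
  expect_equal(al[1, 2], 1)
  Wr <- p$W[, 4:6]
  z <- as.numeric(Wr %*% X[2, ])
  expect_equal(out[1, ], ifelse(z > 0, z, exp(z) - 1), tolerance = 1e-10)
  # isolated nodes attend to themselves
  expect_equal(al[3, 3], 1)
})

test_that("edge weights rescale attention logits", {
  set.seed(10)
  X <- matrix(rnorm(9), 3, 3)
  A <- matrix(1, 3, 3); diag(A) <- 0
  p <- gatv2_params(3, 2, seed = 4)
  w <- matrix(1, 3, 3); w[1, 2] <- 100
  out_w <- gatv2_layer(X, A, p, edge_weights = w)
  out_u <- gatv2_layer(X, A, p)
  expect_false(isTRUE(all.equal(attr(out_w, "alpha")[1, ],
                                attr(out_u, "alpha")[1, ])))
})

test_that("two stacked attention layers produce the 5600-d target code", {
  proj <- fix_projection()
  seq <- paste(sample(aa_alphabet(), 60, replace = TRUE), collapse = "")
  contacts <- gen_contacts(seq, seed = 3)
  rg <- build_residue_graph(seq, contacts, proj, max_len = 1400)
  adj <- matrix(0, 1400, 1400)
  adj[cbind(rg$edges$res_i, rg$edges$res_j)] <- 1
  adj <- pmax(adj, t(adj))
  h1 <- gatv2_layer(rg$features, adj, gatv2_params(20, 8, seed = 1))
  h2 <- gatv2_layer(h1, adj, gatv2_params(8, 4, seed = 2))
  expect_equal(length(as.numeric(h2)), 5600)
})

test_that("convolution and pooling follow the output-shape rule", {
  # hand-checkable case: 6x6 input, 3x3 kernel of ones, no padding
  x <- matrix(1, 6, 6)
  k <- matrix(1, 3, 3)
  out <- conv2d(x, k)
  expect_equal(dim(out), c(4, 4))
  expect_true(all(out == 9))
  out_p <- conv2d(x, k, padding = 1)
  expect_equal(dim(out_p), c(6, 6))
  expect_equal(out_p[1, 1], 4)  # corner sees a 2x2 patch

  pooled <- maxpool2d(matrix(1:16, 4, 4), c(2, 2), stride = c(2, 2))
  expect_equal(dim(pooled), c(2, 2))
  expect_equal(pooled[2, 2], 16)

  expect_error(conv2d(matrix(1, 2, 2), matrix(1, 5, 5)), "larger")
  expect_error(maxpool2d(matrix(1, 2, 2), c(5, 5)), "larger")
})

test_that("the target and conformer towers reduce to their printed widths", {
  tshape <- conv_pool_shapes(c(1400, 20), phygratt_target_stages())
  expect_equal(tshape$shapes$conv1, c(800, 15))
  expect_equal(tshape$shapes$pool1, c(600, 12))
  expect_equal(tshape$shapes$conv2, c(300, 8))
  expect_equal(tshape$shapes$pool2, c(200, 5))
  expect_equal(tshape$flat_length, 1000)

  eshape <- conv_pool_shapes(c(3, 2048), e3fp_tower_stages())
  expect_equal(eshape$shapes$conv1, c(3, 1550))
  expect_equal(eshape$shapes$pool1, c(1, 310))
  expect_equal(eshape$flat_length, 310)

  # the actual forward pass agrees with the shape calculator
  v <- conv_pool_tower(matrix(rnorm(3 * 2048), 3, 2048),
                       e3fp_tower_stages(), seed = 3)
  expect_length(v, 310)

  # identity spec: 1x1 kernel of weight 1, no pooling, flattens the input
  x <- matrix(rnorm(12), 3, 4)
  ident <- conv_pool_tower(x, list(conv_pool_stage(c(1, 1), padding = 0)),
                           kernels = list(matrix(1, 1, 1)))
  expect_equal(as.numeric(ident), as.numeric(t(x)))
})

test_that("the fingerprint MLP tower matches a direct matrix oracle", {
  p <- fp_mlp_params(seed = 8)
  expect_equal(p$dims, c(3239, 2048, 512, 128))
  x <- rnorm(3239)
  got <- fp_mlp_tower(x, p)
  expect_length(got, 128)
  # independent evaluation with explicit matrix arithmetic
  h1 <- pmax(as.numeric(p$W[[1]] %*% x + p$b[[1]]), 0)
  h2 <- pmax(as.numeric(p$W[[2]] %*% h1 + p$b[[2]]), 0)
  want <- as.numeric(p$W[[3]] %*% h2 + p$b[[3]])
  expect_equal(got, want, tolerance = 1e-10)

  # zero input: pure bias propagation
  z <- fp_mlp_tower(numeric(3239), p)
  hb <- pmax(pmax(p$b[[1]], 0) %*% t(p$W[[2]]) + p$b[[2]], 0)
  wb <- as.numeric(hb %*% t(p$W[[3]])) + p$b[[3]]
  expect_equal(z, wb, tolerance = 1e-10)

  expect_error(fp_mlp_tower(rnorm(100), p), "match")
})

test_that("the global-window tower masks padding and sums filter counts", {
  proj <- fix_projection()
  emb <- phys_init_embeddings(proj)
  v <- deepconv_target_tower("ACDEFGHIKL", emb, windows = c(3, 5),
                             n_filters = 7, max_len = 50, seed = 2)
  expect_length(v, 14)

  # constant sequence: every window position responds identically, so a
  # longer constant sequence cannot change the max
  v1 <- deepconv_target_tower(strrep("A", 20), emb, windows = 4,
                              n_filters = 5, max_len = 50, seed = 2)
  v2 <- deepconv_target_tower(strrep("A", 40), emb, windows = 4,
                              n_filters = 5, max_len = 50, seed = 2)
  expect_equal(v1, v2, tolerance = 1e-10)

  # masking: padding length is irrelevant
  v3 <- deepconv_target_tower("ACDEFGHIKL", emb, windows = c(3, 5),
                              n_filters = 7, max_len = 300, seed = 2)
  expect_equal(v, v3, tolerance = 1e-10)

  expect_error(deepconv_target_tower("ACD", emb, windows = 99,
                                     max_len = 50), "exceeds")
})

test_that("embedding initialization modes are reproducible and defined", {
  proj <- fix_projection()
  tab <- phys_init_embeddings(proj)
  expect_equal(dim(tab), c(21, 20))
  expect_equal(unname(tab["pad", ]), rep(0, 20))
  # lookup('A') equals the normalized projected property vector
  a <- proj$residue_matrix["A", ]
  expect_equal(unname(tab["A", ]), unname(a / sqrt(sum(a^2))))
  expect_equal(vapply(seq_len(20), function(i) sum(tab[i, ]^2), 0),
               rep(1, 20), tolerance = 1e-10)

  r1 <- init_residue_embeddings("RANDOM_UNIFORM", dim = 16, seed = 5)
  r2 <- init_residue_embeddings("RANDOM_UNIFORM", dim = 16, seed = 5)
  expect_identical(r1, r2)
  expect_error(init_residue_embeddings("PHYSCHEM", dim = 16,
                                       projection = proj), "width")
})

test_that("cross-entropy has its closed-form values", {
  expect_lt(cross_entropy(1, 1 - 1e-7), 1e-6)
  expect_equal(cross_entropy(1, 0.5), log(2))
  expect_equal(cross_entropy(0, 0.5), log(2))
  expect_equal(cross_entropy(c(1, 0), c(0.5, 0.5)), log(2))
  # clipping keeps the loss finite at the boundaries
  expect_true(is.finite(cross_entropy(1, 0)))
})

test_that("training is seeded, restartable and capacity-checked", {
  set.seed(2024)
  n <- 60
  Xc <- matrix(rnorm(n * 30), n, 30)
  Xt <- matrix(rnorm(n * 10), n, 10)
  y <- as.integer(Xc[, 1] + Xt[, 1] > 0)
  factory <- function() cti_model(
    dense_stack_small(30), dense_stack_small(10), seed = 3)
  dense_stack_small <- function(d) {
    embedding_mlp_params(d, seed = d)
  }
  cfg <- train_config(epochs = 3, seed = 11, batch_size = 16)
  f1 <- train_cti(factory(), Xc, Xt, y, cfg)
  f2 <- train_cti(factory(), Xc, Xt, y, cfg)
  expect_identical(f1$model, f2$model)
  expect_equal(nrow(f1$history), 3)
  expect_true(all(is.finite(f1$history$loss)))

  f0 <- train_cti(factory(), Xc, Xt, y, train_config(epochs = 0))
  expect_identical(f0$model, factory())
  expect_equal(nrow(f0$history), 0)

  p <- predict_cti(f1$model, Xc, Xt)
  expect_true(all(p >= 0 & p <= 1))
})
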
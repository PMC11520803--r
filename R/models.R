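# Reference model architectures: graph attention v2 layers, 2D
# convolution + max-pooling towers, fingerprint and embedding MLP towers,
# a global-window sequence tower, and a seeded SGD training loop for the
# dense pathways.

relu <- function(x) pmax(x, 0)
leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
elu <- function(x, alpha = 1) ifelse(x > 0, x, alpha * (exp(x) - 1))

apply_activation <- function(x, act) {
  switch(act,
         relu = relu(x),
         elu = elu(x),
         linear = x,
         sigmoid = 1 / (1 + exp(-x)),
         tanh = tanh(x),
         stop("unknown activation: ", act))
}

# Glorot-uniform initialization, seeded.
glorot <- function(n_out, n_in, rng) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(rng(n_out * n_in, -lim, lim), n_out, n_in)
}

#' Initialize GATv2 layer parameters
#'
#' A layer holds a shared linear map `W` over the concatenation of the two
#' endpoint feature vectors (an `out_dim x 2*in_dim` matrix, left block
#' applied to the centre node, right block to the neighbour) and an
#' attention vector `a` of length `out_dim`.
#'
#' @param in_dim,out_dim Feature dimensions.
#' @param seed RNG seed.
#' @return A list of class `gatv2_params` (`W`, `a`, `in_dim`, `out_dim`).
#' @export
gatv2_params <- function(in_dim, out_dim, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  structure(list(W = glorot(out_dim, 2 * in_dim, stats::runif),
                 a = stats::runif(out_dim, -0.5, 0.5),
                 in_dim = in_dim, out_dim = out_dim),
            class = "gatv2_params")
}

#' One graph attention v2 layer
#'
#' For each node i, attention logits over its neighbourhood are
#' `e(f_i, f_j) = a' LeakyReLU(W [f_i || f_j])`, normalized with a softmax
#' over the neighbours of i, and the updated feature is
#' `f'_i = act(sum_j alpha_ij * (W_r f_j))` where `W_r` is the
#' neighbour-side block of `W`. Isolated nodes receive a self-loop so the
#' softmax is defined. Optional edge weights scale the attention logits
#' multiplicatively before the softmax.
#'
#' @param features `n x in_dim` node feature matrix.
#' @param adjacency Symmetric 0/1 `n x n` matrix.
#' @param params A [gatv2_params()].
#' @param leaky_slope Negative slope of the LeakyReLU scorer (default 0.2).
#' @param activation Output nonlinearity (default `"elu"`).
#' @param edge_weights Optional `n x n` weight matrix (e.g. dissociation
#'   energies); `NULL` disables weighting.
#' @return `n x out_dim` matrix of updated features; attribute `alpha` is
#'   the attention matrix (rows sum to 1 over each neighbourhood).
#' @export
gatv2_layer <- function(features, adjacency, params, leaky_slope = 0.2,
                        activation = "elu", edge_weights = NULL) {
  n <- nrow(features)
  if (ncol(features) != params$in_dim) {
    stop("feature dim ", ncol(features), " does not match layer in_dim ",
         params$in_dim)
  }
  W <- params$W
  Wl <- W[, seq_len(params$in_dim), drop = FALSE]
  Wr <- W[, params$in_dim + seq_len(params$in_dim), drop = FALSE]
  Hl <- features %*% t(Wl)   # n x out
  Hr <- features %*% t(Wr)   # n x out
  A <- adjacency != 0
  iso <- rowSums(A) == 0
  if (any(iso)) A[cbind(which(iso), which(iso))] <- TRUE
  alpha <- matrix(0, n, n)
  out <- matrix(0, n, params$out_dim)
  for (i in seq_len(n)) {
    nb <- which(A[i, ])
    s <- leaky_relu(sweep(Hr[nb, , drop = FALSE], 2, Hl[i, ], `+`),
                    leaky_slope)
    e <- as.numeric(s %*% params$a)
    if (!is.null(edge_weights)) {
      w <- edge_weights[i, nb]
      w[nb == i] <- 1
      e <- e * w
    }
    e <- e - max(e)
    al <- exp(e) / sum(exp(e))
    alpha[i, nb] <- al
    out[i, ] <- as.numeric(al %*% Hr[nb, , drop = FALSE])
  }
  out <- apply_activation(out, activation)
  attr(out, "alpha") <- alpha
  out
}

# ---- 2D convolution / max-pooling ------------------------------------

conv_output_shape <- function(input, kernel, padding = 0, stride = 1) {
  out <- floor((input - kernel + 2 * padding) / stride) + 1
  if (any(out < 1)) {
    stop("kernel (", paste(kernel, collapse = "x"),
         ") larger than padded input (", paste(input, collapse = "x"), ")")
  }
  out
}

#' Single-channel 2D convolution
#'
#' Valid cross-correlation of one kernel over a zero-padded matrix;
#' `out[i,j] = sum(patch * kernel) + bias`.
#'
#' @param x Input matrix.
#' @param kernel Kernel matrix.
#' @param padding Symmetric zero padding (scalar, both axes).
#' @param stride Stride (scalar, both axes).
#' @param bias Scalar bias (default 0).
#' @return Output matrix of the standard shape
#'   `floor((n - k + 2p)/s) + 1` per axis.
#' @export
conv2d <- function(x, kernel, padding = 0, stride = 1, bias = 0) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  if (padding > 0) {
    xp <- matrix(0, nrow(x) + 2 * padding, ncol(x) + 2 * padding)
    xp[padding + seq_len(nrow(x)), padding + seq_len(ncol(x))] <- x
    x <- xp
  }
  oh <- floor((nrow(x) - kh) / stride) + 1
  ow <- floor((ncol(x) - kw) / stride) + 1
  if (oh < 1 || ow < 1) {
    stop("kernel ", kh, "x", kw, " larger than padded input ",
         nrow(x), "x", ncol(x))
  }
  out <- matrix(0, oh, ow)
  for (a in seq_len(oh)) {
    ra <- (a - 1) * stride + seq_len(kh)
    for (b in seq_len(ow)) {
      rb <- (b - 1) * stride + seq_len(kw)
      out[a, b] <- sum(x[ra, rb] * kernel) + bias
    }
  }
  out
}

#' 2D max pooling
#'
#' @param x Input matrix.
#' @param kernel Pool window `c(h, w)`.
#' @param stride Pool stride `c(h, w)` (default `c(1, 1)`; set equal to
#'   `kernel` for non-overlapping pooling).
#' @return Pooled matrix.
#' @export
maxpool2d <- function(x, kernel, stride = c(1, 1)) {
  if (length(stride) == 1) stride <- rep(stride, 2)
  oh <- floor((nrow(x) - kernel[1]) / stride[1]) + 1
  ow <- floor((ncol(x) - kernel[2]) / stride[2]) + 1
  if (oh < 1 || ow < 1) {
    stop("pool window ", kernel[1], "x", kernel[2], " larger than input ",
         nrow(x), "x", ncol(x))
  }
  out <- matrix(0, oh, ow)
  for (a in seq_len(oh)) {
    ra <- (a - 1) * stride[1] + seq_len(kernel[1])
    for (b in seq_len(ow)) {
      rb <- (b - 1) * stride[2] + seq_len(kernel[2])
      out[a, b] <- max(x[ra, rb])
    }
  }
  out
}

#' Convolution + pooling stage specification
#'
#' @param conv_kernel Convolution kernel `c(h, w)`.
#' @param padding Symmetric zero padding for the convolution.
#' @param conv_stride Convolution stride.
#' @param pool_kernel Max-pool window `c(h, w)`.
#' @param pool_stride Max-pool stride `c(h, w)`, or `"kernel"` for
#'   non-overlapping pooling.
#' @return A list describing the stage.
#' @export
conv_pool_stage <- function(conv_kernel, padding = 1, conv_stride = 1,
                            pool_kernel = NULL, pool_stride = c(1, 1)) {
  if (identical(pool_stride, "kernel")) pool_stride <- pool_kernel
  list(conv_kernel = conv_kernel, padding = padding,
       conv_stride = conv_stride, pool_kernel = pool_kernel,
       pool_stride = pool_stride)
}

#' Shape trace of a convolution-pooling tower
#'
#' Applies the output-shape rule `floor((n - k + 2p)/s) + 1` stage by
#' stage without touching data.
#'
#' @param input_dim Input matrix shape `c(h, w)`.
#' @param stages List of [conv_pool_stage()]s.
#' @return A list with `shapes` (matrix of per-stage shapes) and
#'   `flat_length` (product of the final shape).
#' @export
conv_pool_shapes <- function(input_dim, stages) {
  cur <- input_dim
  shapes <- list(input = cur)
  for (s in seq_along(stages)) {
    st <- stages[[s]]
    cur <- conv_output_shape(cur, st$conv_kernel, st$padding, st$conv_stride)
    shapes[[paste0("conv", s)]] <- cur
    if (!is.null(st$pool_kernel)) {
      cur <- floor((cur - st$pool_kernel) / st$pool_stride) + 1
      if (any(cur < 1)) stop("pool window larger than its input")
      shapes[[paste0("pool", s)]] <- cur
    }
  }
  list(shapes = shapes, flat_length = prod(cur))
}

#' Run a convolution-pooling tower
#'
#' Applies each stage's convolution (with its kernel parameters) and max
#' pooling to a single-channel input matrix and flattens the result
#' row-wise.
#'
#' @param x Input matrix.
#' @param stages List of [conv_pool_stage()]s.
#' @param kernels Optional list of kernel matrices (one per stage); when
#'   `NULL`, seeded Glorot kernels are drawn.
#' @param seed Seed for default kernels.
#' @return Numeric vector (flattened final feature map), with attribute
#'   `shape` (the final matrix shape).
#' @export
conv_pool_tower <- function(x, stages, kernels = NULL, seed = 1) {
  if (is.null(kernels)) {
    old <- .Random.seed_save()
    set.seed(seed)
    kernels <- lapply(stages, function(st) {
      glorot(st$conv_kernel[1], st$conv_kernel[2], stats::runif)
    })
    .Random.seed_restore(old)
  }
  cur <- x
  for (s in seq_along(stages)) {
    st <- stages[[s]]
    cur <- conv2d(cur, kernels[[s]], padding = st$padding,
                  stride = st$conv_stride)
    if (!is.null(st$pool_kernel)) {
      cur <- maxpool2d(cur, st$pool_kernel, st$pool_stride)
    }
  }
  out <- as.numeric(t(cur))
  attr(out, "shape") <- dim(cur)
  out
}

#' Canonical tower stage lists
#'
#' `phygratt_target_stages()`: the two-stage tower applied to the
#' `(1400, 20)` physicochemical target matrix - conv `(603, 8)` padding 1,
#' pool `(201, 4)` stride 1, conv `(303, 7)` padding 1, pool `(101, 4)`
#' stride 1 - whose output flattens to 1000 dimensions.
#' `e3fp_tower_stages()`: the single-stage tower applied to the
#' `(3, 2048)` conformer fingerprint matrix - conv `(3, 501)` padding 1,
#' non-overlapping pool `(3, 5)` - whose output flattens to 310
#' dimensions.
#'
#' @return List of [conv_pool_stage()]s.
#' @export
phygratt_target_stages <- function() {
  list(conv_pool_stage(c(603, 8), padding = 1, pool_kernel = c(201, 4),
                       pool_stride = c(1, 1)),
       conv_pool_stage(c(303, 7), padding = 1, pool_kernel = c(101, 4),
                       pool_stride = c(1, 1)))
}

#' @rdname phygratt_target_stages
#' @export
e3fp_tower_stages <- function() {
  list(conv_pool_stage(c(3, 501), padding = 1, pool_kernel = c(3, 5),
                       pool_stride = "kernel"))
}

# ---- dense stacks with backprop --------------------------------------

dense_stack <- function(dims, activations, seed = 1) {
  stopifnot(length(activations) == length(dims) - 1)
  old <- .Random.seed_save()
  set.seed(seed)
  W <- list(); b <- list()
  for (k in seq_len(length(dims) - 1)) {
    W[[k]] <- glorot(dims[k + 1], dims[k], stats::runif)
    b[[k]] <- numeric(dims[k + 1])
  }
  .Random.seed_restore(old)
  structure(list(W = W, b = b, activations = activations, dims = dims),
            class = "dense_stack")
}

dense_forward <- function(stack, X) {
  caches <- list()
  cur <- X
  for (k in seq_along(stack$W)) {
    pre <- cur %*% t(stack$W[[k]])
    pre <- sweep(pre, 2, stack$b[[k]], `+`)
    post <- apply_activation(pre, stack$activations[k])
    caches[[k]] <- list(input = cur, pre = pre)
    cur <- post
  }
  list(out = cur, caches = caches)
}

activation_grad <- function(pre, act) {
  switch(act,
         relu = (pre > 0) * 1,
         elu = ifelse(pre > 0, 1, exp(pre)),
         linear = array(1, dim(pre)),
         stop("no gradient for activation: ", act))
}

dense_backward <- function(stack, caches, dOut) {
  L <- length(stack$W)
  dW <- vector("list", L); db <- vector("list", L)
  grad <- dOut
  for (k in rev(seq_len(L))) {
    grad <- grad * activation_grad(caches[[k]]$pre, stack$activations[k])
    dW[[k]] <- t(grad) %*% caches[[k]]$input
    db[[k]] <- colSums(grad)
    grad <- grad %*% stack$W[[k]]
  }
  list(dX = grad, dW = dW, db = db)
}

#' Fingerprint MLP tower (forward pass)
#'
#' The 2D-fingerprint compound tower: 3239 -> 2048 -> 512 -> 128 with ReLU
#' on the two hidden layers and an affine (no activation) output, emitting
#' the 128-dimensional compound representative vector.
#'
#' @param x Numeric vector of length 3239, or an `n x 3239` matrix.
#' @param params A `dense_stack` from [fp_mlp_params()] (or compatible).
#' @return 128-vector (or `n x 128` matrix for matrix input).
#' @export
fp_mlp_tower <- function(x, params = fp_mlp_params()) {
  single <- is.null(dim(x))
  X <- if (single) matrix(x, 1) else x
  if (ncol(X) != params$dims[1]) {
    stop("input length ", ncol(X), " does not match tower input ",
         params$dims[1])
  }
  out <- dense_forward(params, X)$out
  if (single) as.numeric(out) else out
}

#' @rdname fp_mlp_tower
#' @param seed RNG seed for initialization.
#' @export
fp_mlp_params <- function(seed = 1) {
  dense_stack(c(3239, 2048, 512, 128), c("relu", "relu", "linear"), seed)
}

#' Embedding MLP tower parameters
#'
#' Dense tower for precomputed protein embeddings (UniRep 1900-d, BERT
#' 768-d, or any declared width): in -> 512 -> 128, ReLU then affine.
#'
#' @param in_dim Input embedding width.
#' @param seed RNG seed.
#' @return A `dense_stack`.
#' @export
embedding_mlp_params <- function(in_dim, seed = 1) {
  dense_stack(c(in_dim, 512, 128), c("relu", "linear"), seed)
}

# ---- global-window sequence tower ------------------------------------

#' Residue embedding table initialization
#'
#' Either seeded uniform values (`mode = "RANDOM_UNIFORM"`) or the
#' physicochemical initialization: row r of the table is the L2-normalized
#' projected property vector of residue r, so the embedding starts from
#' chemistry rather than noise (it remains trainable thereafter). A zero
#' padding row is appended last.
#'
#' @param mode `"RANDOM_UNIFORM"` or `"PHYSCHEM"`.
#' @param dim Embedding width (must be `ncol(residue_matrix)` for
#'   PHYSCHEM).
#' @param projection A [fit_physchem_pca()] result (PHYSCHEM mode).
#' @param seed RNG seed (RANDOM_UNIFORM mode).
#' @return `(21 x dim)` matrix: 20 residue rows (rownames the alphabet)
#'   plus a zero `pad` row.
#' @export
init_residue_embeddings <- function(mode = c("RANDOM_UNIFORM", "PHYSCHEM"),
                                    dim = 20, projection = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "PHYSCHEM") {
    if (is.null(projection)) stop("PHYSCHEM mode needs a fitted projection")
    m <- projection$residue_matrix
    if (ncol(m) != dim) {
      stop("embedding width ", dim, " does not match projection width ",
           ncol(m))
    }
    nrm <- sqrt(rowSums(m^2))
    nrm[nrm == 0] <- 1
    tab <- m / nrm
  } else {
    old <- .Random.seed_save()
    set.seed(seed)
    tab <- matrix(stats::runif(20 * dim, -0.05, 0.05), 20, dim,
                  dimnames = list(aa_alphabet(), NULL))
    .Random.seed_restore(old)
  }
  rbind(tab, pad = rep(0, dim))
}

#' @rdname init_residue_embeddings
#' @export
phys_init_embeddings <- function(projection) {
  init_residue_embeddings("PHYSCHEM", dim = ncol(projection$residue_matrix),
                          projection = projection)
}

#' Global-window convolutional sequence tower (forward pass)
#'
#' The DeepConv-style target tower: each residue is looked up in a
#' trainable embedding table, 1-D convolution filters of several window
#' sizes slide over the full sequence, each filter is globally max-pooled,
#' and the per-window maxima are concatenated. Padded positions are
#' masked out of the max. Output length is `sum(n_filters)` before the
#' final dense reduction.
#'
#' @param seq Amino-acid sequence.
#' @param embeddings `(21 x d)` table from [init_residue_embeddings()].
#' @param windows Integer vector of window sizes (default `c(8, 12, 16)`).
#' @param n_filters Filters per window (default 32).
#' @param max_len Padded sequence length (default 1400).
#' @param seed Seed for the filter weights.
#' @return Numeric vector of length `length(windows) * n_filters`.
#' @export
deepconv_target_tower <- function(seq, embeddings, windows = c(8, 12, 16),
                                  n_filters = 32, max_len = 1400, seed = 1) {
  n <- nchar(seq)
  if (any(windows > max_len)) {
    stop("window size exceeds the maximum sequence length ", max_len)
  }
  idx <- match(strsplit(seq, "")[[1]], rownames(embeddings)[1:20])
  if (anyNA(idx)) stop("non-canonical residue in sequence")
  d <- ncol(embeddings)
  E <- matrix(0, max_len, d)
  E[seq_len(n), ] <- embeddings[idx, , drop = FALSE]
  old <- .Random.seed_save()
  set.seed(seed)
  out <- numeric(0)
  for (w in windows) {
    filt <- lapply(seq_len(n_filters), function(f) glorot(w, d, stats::runif))
    n_pos <- n - w + 1  # positions fully inside the true sequence
    if (n_pos < 1) {
      out <- c(out, rep(0, n_filters))
      next
    }
    resp <- vapply(filt, function(K) {
      max(vapply(seq_len(n_pos), function(p) {
        sum(E[p + seq_len(w) - 1, ] * K)
      }, numeric(1)))
    }, numeric(1))
    out <- c(out, resp)
  }
  .Random.seed_restore(old)
  out
}

# ---- loss, model, training -------------------------------------------

#' Binary cross-entropy loss
#'
#' `-[y log y' + (1 - y) log(1 - y')]`, averaged over the batch, with
#' predictions clipped to `(eps, 1 - eps)`.
#'
#' @param y 0/1 labels.
#' @param y_pred Predicted positive-class probabilities.
#' @param eps Clipping constant (default 1e-7).
#' @return Non-negative scalar loss.
#' @export
cross_entropy <- function(y, y_pred, eps = 1e-7) {
  p <- pmin(pmax(y_pred, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Training configuration
#'
#' @param learning_rate SGD learning rate (default 0.01).
#' @param momentum SGD momentum (default 0.9).
#' @param batch_size Minibatch size (default 32).
#' @param epochs Training epochs (default 50).
#' @param seed Seed controlling initialization and batch order.
#' @param early_stop_mcc Stop when the training MCC reaches this value
#'   (`NULL` to disable).
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, momentum = 0.9,
                         batch_size = 32, epochs = 50, seed = 1,
                         early_stop_mcc = NULL) {
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 batch_size = batch_size, epochs = epochs, seed = seed,
                 early_stop_mcc = early_stop_mcc),
            class = "train_config")
}

#' Build a two-tower interaction classifier
#'
#' A compound tower and a target tower each emit a 128-dimensional
#' representative vector; the concatenated 256-dimensional pair
#' representation passes through the fully-connected head (default
#' 256 -> 64 -> 2) ending in two softmax neurons (non-interaction,
#' interaction). Both towers must be dense stacks (fingerprint or
#' embedding MLPs) for gradient training; the convolutional and graph
#' towers of this package are feature extractors whose outputs can be fed
#' in through an identity/dense tower.
#'
#' @param compound_tower,target_tower `dense_stack` towers emitting 128-d
#'   vectors (e.g. [fp_mlp_params()], [embedding_mlp_params()]).
#' @param head_hidden Hidden widths of the head (default 64).
#' @param seed RNG seed for head initialization.
#' @return A list of class `cti_model`.
#' @export
cti_model <- function(compound_tower, target_tower, head_hidden = 64,
                      seed = 1) {
  stopifnot(inherits(compound_tower, "dense_stack"),
            inherits(target_tower, "dense_stack"))
  rep_dim <- utils::tail(compound_tower$dims, 1) +
    utils::tail(target_tower$dims, 1)
  head <- dense_stack(c(rep_dim, head_hidden, 2),
                      c(rep("relu", length(head_hidden)), "linear"),
                      seed = seed + 1000)
  structure(list(compound_tower = compound_tower,
                 target_tower = target_tower, head = head),
            class = "cti_model")
}

model_forward <- function(model, Xc, Xt) {
  fc <- dense_forward(model$compound_tower, Xc)
  ft <- dense_forward(model$target_tower, Xt)
  H <- cbind(fc$out, ft$out)
  fh <- dense_forward(model$head, H)
  logits <- fh$out
  m <- apply(logits, 1, max)
  ex <- exp(logits - m)
  probs <- ex / rowSums(ex)
  list(probs = probs, fc = fc, ft = ft, fh = fh, H = H)
}

#' Predict interaction probabilities
#'
#' @param model A trained [cti_model()].
#' @param Xc,Xt Compound / target input feature matrices (one row per
#'   pair).
#' @return Numeric vector of positive-class probabilities.
#' @export
predict_cti <- function(model, Xc, Xt) {
  model_forward(model, Xc, Xt)$probs[, 2]
}

sgd_update <- function(stack, grads, vel, lr, mom) {
  for (k in seq_along(stack$W)) {
    vel$W[[k]] <- mom * vel$W[[k]] - lr * grads$dW[[k]]
    vel$b[[k]] <- mom * vel$b[[k]] - lr * grads$db[[k]]
    stack$W[[k]] <- stack$W[[k]] + vel$W[[k]]
    stack$b[[k]] <- stack$b[[k]] + vel$b[[k]]
  }
  list(stack = stack, vel = vel)
}

zero_velocity <- function(stack) {
  list(W = lapply(stack$W, function(w) w * 0),
       b = lapply(stack$b, function(b) b * 0))
}

#' Train a two-tower interaction classifier with SGD
#'
#' Minimizes the softmax cross-entropy over minibatches with momentum SGD.
#' Fully seeded: the same seed reproduces initialization, batch order and
#' final parameters exactly. With `epochs = 0` the initialized model is
#' returned unchanged. Training aborts with diagnostics if the loss stops
#' being finite.
#'
#' @param model A [cti_model()].
#' @param Xc,Xt Input feature matrices (rows are pairs).
#' @param y 0/1 labels.
#' @param config A [train_config()].
#' @return A list: `model` (trained), `history` (data frame of per-epoch
#'   loss and training MCC), `config`.
#' @export
train_cti <- function(model, Xc, Xt, y, config = train_config()) {
  stopifnot(nrow(Xc) == nrow(Xt), nrow(Xc) == length(y))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  n <- length(y)
  Y <- cbind(1 - y, y)
  vel <- list(c = zero_velocity(model$compound_tower),
              t = zero_velocity(model$target_tower),
              h = zero_velocity(model$head))
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        mcc = numeric(0))
  if (config$epochs == 0) {
    return(list(model = model, history = history, config = config))
  }
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      fw <- model_forward(model, Xc[bt, , drop = FALSE],
                          Xt[bt, , drop = FALSE])
      p <- pmin(pmax(fw$probs[, 2], 1e-7), 1 - 1e-7)
      loss <- cross_entropy(y[bt], p)
      if (!is.finite(loss)) {
        stop("non-finite loss at epoch ", ep,
             "; last finite epoch losses: ",
             paste(round(utils::tail(history$loss, 3), 4), collapse = ", "))
      }
      ep_loss <- ep_loss + loss * length(bt)
      dlogits <- (fw$probs - Y[bt, , drop = FALSE]) / length(bt)
      gh <- dense_backward(model$head, fw$fh$caches, dlogits)
      dc <- utils::tail(model$compound_tower$dims, 1)
      gc <- dense_backward(model$compound_tower, fw$fc$caches,
                           gh$dX[, seq_len(dc), drop = FALSE])
      gt <- dense_backward(model$target_tower, fw$ft$caches,
                           gh$dX[, -seq_len(dc), drop = FALSE])
      up <- sgd_update(model$head, gh, vel$h, config$learning_rate,
                       config$momentum)
      model$head <- up$stack; vel$h <- up$vel
      up <- sgd_update(model$compound_tower, gc, vel$c,
                       config$learning_rate, config$momentum)
      model$compound_tower <- up$stack; vel$c <- up$vel
      up <- sgd_update(model$target_tower, gt, vel$t,
                       config$learning_rate, config$momentum)
      model$target_tower <- up$stack; vel$t <- up$vel
    }
    scores <- predict_cti(model, Xc, Xt)
    m <- mcc_score(as.integer(scores >= 0.5), y)
    history <- rbind(history,
                     data.frame(epoch = ep, loss = ep_loss / n, mcc = m))
    if (!is.null(config$early_stop_mcc) && m >= config$early_stop_mcc) break
  }
  list(model = model, history = history, config = config)
}
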
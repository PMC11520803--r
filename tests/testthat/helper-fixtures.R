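# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

fix_compounds <- function() {
  fixture("compounds", function() gen_compounds(16, seed = 101))
}

fix_projection <- function() {
  fixture("projection", function() {
    fit_physchem_pca(synthetic_aa_properties(seed = 42))
  })
}

fix_dataset <- function() {
  fixture("dataset", function() {
    synthetic_dataset(n_compounds = 30, n_targets = 16, n_pairs = 300,
                      prevalence = 0.3, seed = 7)
  })
}

# Independent textbook Needleman-Wunsch oracle: identity scoring
# (match 1, mismatch 0, gap 0), plain dynamic programming.
nw_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  D <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- max(D[i, j] + (x[i] == y[j]),
                             D[i, j + 1], D[i + 1, j])
    }
  }
  D[n + 1, m + 1] / max(n, m)
}

# Independent scalar implementation of the graph-attention update:
# explicit loops, no matrix algebra shared with the package path.
gatv2_oracle <- function(X, A, W, a, slope = 0.2) {
  n <- nrow(X)
  d_in <- ncol(X)
  d_out <- nrow(W)
  Adj <- A != 0
  for (i in seq_len(n)) if (!any(Adj[i, ])) Adj[i, i] <- TRUE
  out <- matrix(0, n, d_out)
  for (i in seq_len(n)) {
    nb <- which(Adj[i, ])
    e <- numeric(length(nb))
    for (t in seq_along(nb)) {
      j <- nb[t]
      cat_vec <- c(X[i, ], X[j, ])
      s <- numeric(d_out)
      for (r in seq_len(d_out)) {
        z <- sum(W[r, ] * cat_vec)
        s[r] <- if (z > 0) z else slope * z
      }
      e[t] <- sum(a * s)
    }
    e <- e - max(e)
    al <- exp(e) / sum(exp(e))
    for (t in seq_along(nb)) {
      j <- nb[t]
      wr_fj <- numeric(d_out)
      for (r in seq_len(d_out)) {
        wr_fj[r] <- sum(W[r, d_in + seq_len(d_in)] * X[j, ])
      }
      out[i, ] <- out[i, ] + al[t] * wr_fj
    }
  }
  ifelse(out > 0, out, exp(out) - 1)  # ELU
}

# Exhaustive confusion-matrix metric oracle at threshold 0.5.
metrics_oracle <- function(scores, labels) {
  pred <- as.integer(scores >= 0.5)
  tp <- sum(pred & labels); tn <- sum(!pred & !labels)
  fp <- sum(pred & !labels); fn <- sum(!pred & labels)
  acc <- (tp + tn) / length(labels)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(accuracy = acc, f1 = f1, mcc = mcc)
}

# Brute-force max-min negative selection oracle over precomputed
# fingerprint rows (set arithmetic only).
negatives_oracle <- function(fp_binders, fp_cands, k) {
  d <- numeric(nrow(fp_cands))
  for (i in seq_len(nrow(fp_cands))) {
    best <- Inf
    for (j in seq_len(nrow(fp_binders))) {
      a <- fp_binders[j, ] != 0; b <- fp_cands[i, ] != 0
      u <- sum(a | b)
      sim <- if (u == 0) 1 else sum(a & b) / u
      best <- min(best, 1 - sim)
    }
    d[i] <- best
  }
  order(-d, rownames(fp_cands))[seq_len(k)]
}
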
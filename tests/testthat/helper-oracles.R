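# Shared fixtures and independent oracles for the test suite.

# Random soft support tensor values: n x p x l, every (instance, classifier)
# slice nonnegative and summing to 1.
rand_xi_values <- function(n, p, l, seed) {
  withr::with_seed(seed, {
    vals <- array(stats::rexp(n * p * l), c(n, p, l))
    for (j in seq_len(l)) {
      m <- matrix(vals[, , j], n, p)
      vals[, , j] <- m / rowSums(m)
    }
    vals
  })
}

rand_soft_tensor <- function(n, p, l, seed) {
  support_tensor(rand_xi_values(n, p, l, seed), paste0("c", seq_len(p)))
}

# Hard one-hot tensor from an n x l matrix of voted class indices.
hard_tensor_from_votes <- function(votes, p) {
  n <- nrow(votes); l <- ncol(votes)
  vals <- array(0, c(n, p, l))
  for (j in seq_len(l)) vals[cbind(seq_len(n), votes[, j], j)] <- 1
  support_tensor(vals, paste0("c", seq_len(p)), mode = "hard")
}

# Assemble a bitfusion model object around given weights, without training.
make_model <- function(wt, delta = 0.9, config = NULL) {
  cfg <- config %||% fusion_config(delta = delta)
  cfg$delta <- delta
  structure(list(weights = wt, config = cfg,
                 class_set = paste0("c", seq_len(nrow(wt))),
                 classifier_ids = paste0("clf", seq_len(ncol(wt))),
                 mse_trace = 0, bits_fired = 0L, n_train = 1L),
            class = "bitfusion")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent scalar (triple-loop) implementation of the fused predictor:
# weighted activation, strict thresholding, per-class bit counts, then the
# fallback chain (magnitude-weighted support sum with strictly positive
# unique maximum; majority vote with unique maximum; lowest index among
# vote leaders). Deliberately written with explicit loops, sharing no code
# with the package internals.
oracle_predict <- function(vals, wt, delta) {
  n <- dim(vals)[1]; p <- dim(vals)[2]; l <- dim(vals)[3]
  out <- integer(n)
  for (i in seq_len(n)) {
    bits <- numeric(p)
    gsum <- numeric(p)
    for (r in seq_len(p)) {
      for (j in seq_len(l)) {
        f <- vals[i, r, j] * wt[r, j]
        if (f > delta) bits[r] <- bits[r] + 1
        gsum[r] <- gsum[r] + vals[i, r, j] * abs(wt[r, j])
      }
    }
    pick <- NA_integer_
    bmax <- max(bits)
    if (bmax > 0 && sum(bits == bmax) == 1L) pick <- which(bits == bmax)
    if (is.na(pick)) {
      gmax <- max(gsum)
      if (gmax > 0 && sum(gsum == gmax) == 1L) pick <- which(gsum == gmax)
    }
    if (is.na(pick)) {
      counts <- numeric(p)
      for (j in seq_len(l)) {
        best <- 1L
        for (r in seq_len(p)) if (vals[i, r, j] > vals[i, best, j]) best <- r
        counts[best] <- counts[best] + 1
      }
      cmax <- max(counts)
      if (sum(counts == cmax) == 1L) pick <- which(counts == cmax)
      else pick <- which(counts == cmax)[1]
    }
    out[i] <- pick
  }
  out
}

# Small separable two-feature dataset for classifier sanity checks.
toy_separable <- function(n_per = 10L, seed = 7L) {
  withr::with_seed(seed, {
    x1 <- cbind(stats::rnorm(n_per, -3, 0.3), stats::rnorm(n_per, -3, 0.3))
    x2 <- cbind(stats::rnorm(n_per, 3, 0.3), stats::rnorm(n_per, 3, 0.3))
  })
  tibble::tibble(f1 = c(x1[, 1], x2[, 1]), f2 = c(x1[, 2], x2[, 2]),
                 class = factor(rep(c("a", "b"), each = n_per), levels = c("a", "b")))
}
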
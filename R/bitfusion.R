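#' Configure the bit-fusion combiner
#'
#' The combiner weights each instance's p x l support slice elementwise,
#' thresholds the result at `delta` into a bit matrix, and learns the weights
#' by a multiplicative perceptron-style update driven by the bit error
#' against the one-hot true-class pattern. Two error-sign conventions ship:
#'
#' * `"target_minus_output"` (default): the update grows true-class weights
#'   whose bits failed to fire and shrinks wrong-row weights that fired, so
#'   activations climb across the threshold during training.
#' * `"output_minus_target"`: the literal published sign. From a fresh start
#'   (all bits zero) it shrinks true-class weights, so with `delta` near 1 no
#'   activation ever crosses the threshold and prediction is decided entirely
#'   by the fallback chain. It is kept for faithful replication of the
#'   published update.
#'
#' Two named regimes bundle the published constants:
#' `"benchmark"` (default) uses `eta = 0.5`, `mu = 0.2` — the published
#' per-dataset tuning range — with the trainable sign; `"reference"` uses the
#' published global constants `eta = 0.71`, `mu = 1e-5` with the literal sign.
#' Explicit arguments override the regime.
#'
#' @param delta Reliability threshold in (0, 1). Default 0.9.
#' @param eta Learning coefficient (> 0).
#' @param mu Accelerator coefficient (> 0).
#' @param epochs Training epochs (>= 1). Default 100.
#' @param seed Seed for weight initialization. Default 1.
#' @param error_sign `"target_minus_output"` or `"output_minus_target"`.
#' @param regime `"benchmark"` or `"reference"`.
#' @return A `"fusion_config"` list.
#' @export
fusion_config <- function(delta = 0.9, eta = NULL, mu = NULL, epochs = 100L,
                          seed = 1L,
                          error_sign = NULL,
                          regime = c("benchmark", "reference")) {
  regime <- match.arg(regime)
  defaults <- switch(regime,
    benchmark = list(eta = 0.5, mu = 0.2, error_sign = "target_minus_output"),
    reference = list(eta = 0.71, mu = 1e-5, error_sign = "output_minus_target"))
  eta <- eta %||% defaults$eta
  mu <- mu %||% defaults$mu
  error_sign <- match.arg(error_sign %||% defaults$error_sign,
                          c("target_minus_output", "output_minus_target"))
  if (delta <= 0 || delta >= 1) abort("delta must lie strictly in (0, 1)")
  if (eta <= 0 || mu <= 0) abort("eta and mu must be > 0")
  if (epochs < 1) abort("epochs must be >= 1")
  structure(list(delta = delta, eta = eta, mu = mu, epochs = as.integer(epochs),
                 seed = as.integer(seed), error_sign = error_sign,
                 regime = regime,
                 fallback_chain = c("bit_count", "support_sum",
                                    "majority_vote", "lowest_index")),
            class = "fusion_config")
}

#' Initialize a fusion weight matrix
#'
#' Entries are i.i.d. uniform on \[-0.5, 0.5\], reproducible per seed. The
#' matrix has one row per class and one column per base classifier.
#'
#' @param p Number of classes (>= 2).
#' @param l Number of base classifiers (>= 1).
#' @param seed Integer seed.
#' @return A p x l numeric matrix.
#' @export
init_weights <- function(p, l, seed = 1L) {
  if (p < 2 || l < 1) abort("need p >= 2 classes and l >= 1 classifiers")
  withr::with_seed(as.integer(seed),
                   matrix(runif(p * l, -0.5, 0.5), nrow = p, ncol = l))
}

#' Weighted activation of one support slice
#'
#' Elementwise product of an instance's p x l support slice with the weight
#' matrix; entry (i, j) is classifier j's support for class i scaled by its
#' learned reliability weight.
#'
#' @param xi_slice p x l support slice (classes in rows).
#' @param wt p x l weight matrix.
#' @return p x l activation matrix.
#' @export
fuse_forward <- function(xi_slice, wt) {
  if (!all(dim(xi_slice) == dim(wt))) abort("support slice and weights have different shapes")
  xi_slice * wt
}

#' Threshold activations into a bit matrix
#'
#' A bit is set where the activation strictly exceeds `delta`; an activation
#' exactly equal to `delta` yields 0.
#'
#' @param f p x l activation matrix.
#' @param delta Threshold in (0, 1).
#' @return p x l matrix of 0/1 bits.
#' @export
fuse_binarize <- function(f, delta) {
  if (delta <= 0 || delta >= 1) abort("delta must lie strictly in (0, 1)")
  (f > delta) * 1
}

#' Bit error of one instance against its true class
#'
#' The target pattern Omega is the p x l matrix whose true-class row is all
#' ones and whose other rows are zero (the one-hot class broadcast across
#' classifiers). `sign = "output_minus_target"` returns `B - Omega`;
#' `"target_minus_output"`
#' returns `Omega - B`. Entries are always in \{-1, 0, 1\}.
#'
#' @param B p x l bit matrix.
#' @param true_class Class identifier, a member of `class_set`.
#' @param class_set Ordered class identifiers (length p).
#' @param sign `"output_minus_target"` or `"target_minus_output"`.
#' @return p x l error matrix.
#' @export
fuse_error <- function(B, true_class, class_set,
                       sign = c("output_minus_target", "target_minus_output")) {
  sign <- match.arg(sign)
  r <- match(as.character(true_class), as.character(class_set))
  if (is.na(r)) abort(sprintf("unknown class '%s'", true_class))
  omega <- matrix(0, nrow(B), ncol(B))
  omega[r, ] <- 1
  if (sign == "output_minus_target") B - omega else omega - B
}

#' Multiplicative weight update
#'
#' `delta_wt = eta * wt * mu * E` elementwise, applied damped by the training
#' set size: `wt' = wt + delta_wt / n`, i.e.
#' `wt'[i,j] = wt[i,j] * (1 + eta * mu * E[i,j] / n)`. Because the step is
#' multiplicative in `wt`, zero weights are fixed points and (whenever
#' `eta * mu / n < 1`) no weight ever changes sign.
#'
#' @param wt p x l weight matrix.
#' @param E p x l error matrix.
#' @param eta,mu Learning and accelerator coefficients.
#' @param n Training-set size used as damping (>= 1).
#' @return Updated p x l weight matrix.
#' @export
fuse_update <- function(wt, E, eta, mu, n) {
  if (n < 1) abort("n must be >= 1")
  wt + (eta * wt * mu * E) / n
}

#' Train the bit-fusion combiner
#'
#' Runs `epochs` sweeps over the instances in dataset order. For each
#' instance: weighted activation, threshold binarization, bit error against
#' the one-hot class pattern, multiplicative weight update (online, damped by
#' 1/n). The per-epoch trace records phi, the mean over instances of the mean
#' squared bit-error entry, plus the number of bits fired.
#'
#' @param xi A `"support_tensor"` of training supports (out-of-fold supports
#'   recommended; see [build_xi()]).
#' @param labels Class labels, length n, all members of the tensor class set.
#' @param config A `"fusion_config"`.
#' @param verbose Emit a per-epoch message? Default `FALSE`.
#' @return A `"bitfusion"` model: weights, config, class/classifier
#'   dictionaries and the epoch trace. Methods: [predict.bitfusion()],
#'   [tidy.bitfusion()], [glance.bitfusion()], [autoplot.bitfusion()].
#' @export
train_bitfusion <- function(xi, labels, config = fusion_config(), verbose = FALSE) {
  stopifnot(inherits(xi, "support_tensor"), inherits(config, "fusion_config"))
  d <- dim(xi)
  n <- d[1]; p <- d[2]; l <- d[3]
  if (n < 1L) abort("empty support tensor")
  class_set <- attr(xi, "class_set")
  yidx <- match(as.character(labels), class_set)
  if (length(yidx) != n) abort("labels length must equal the tensor's instance count")
  if (anyNA(yidx)) abort("labels contain class(es) not in the tensor class set")

  vals <- unclass(xi)
  slices <- purrr::map(seq_len(n), function(i) matrix(vals[i, , ], p, l))
  omegas <- purrr::map(seq_len(p), function(r) {
    o <- matrix(0, p, l); o[r, ] <- 1; o
  })
  literal_sign <- config$error_sign == "output_minus_target"
  step <- config$eta * config$mu / n

  wt <- init_weights(p, l, config$seed)
  phi <- numeric(config$epochs)
  bits_fired <- integer(config$epochs)
  for (e in seq_len(config$epochs)) {
    sqerr <- 0
    fired <- 0L
    for (i in seq_len(n)) {
      f <- slices[[i]] * wt
      B <- (f > config$delta) * 1
      E <- if (literal_sign) B - omegas[[yidx[i]]] else omegas[[yidx[i]]] - B
      wt <- wt + step * (wt * E)
      sqerr <- sqerr + mean(E * E)
      fired <- fired + sum(B)
    }
    phi[e] <- sqerr / n
    bits_fired[e] <- fired
    if (verbose) {
      message(sprintf("epoch %d: phi = %.6f, bits fired = %d", e, phi[e], fired))
    }
  }
  structure(list(weights = wt, config = config, class_set = class_set,
                 classifier_ids = attr(xi, "classifier_ids"),
                 mse_trace = phi, bits_fired = bits_fired, n_train = n),
            class = "bitfusion")
}

# Decide one instance given its bit matrix, magnitude-weighted support
# matrix and base argmax votes; returns c(class index, fallback stage index).
decide_instance <- function(B, f, votes, p) {
  bs <- rowSums(B)
  if (max(bs) > 0) {
    idx <- unique_argmax(bs)
    if (!is.na(idx)) return(c(idx, 1L))
  }
  fs <- rowSums(f)
  if (max(fs) > 0) {
    idx <- unique_argmax(fs)
    if (!is.na(idx)) return(c(idx, 2L))
  }
  counts <- tabulate(votes, nbins = p)
  idx <- unique_argmax(counts)
  if (!is.na(idx)) return(c(idx, 3L))
  c(which.max(counts), 4L)
}

#' Predict with a trained bit-fusion model
#'
#' For each instance the trained weights produce an activation and bit
#' matrix; the per-class bit counts are summed across classifiers and the
#' class with the most bits wins. When no bit fires or the top count is
#' tied, a deterministic fallback chain decides: (1) the class with the
#' largest strictly positive magnitude-weighted support sum
#' `sum_j xi[i,j] * |wt[i,j]|` — weight polarity gates bit formation only,
#' so every channel still contributes reliability evidence here, and a
#' unanimous ensemble can never be overruled by a sign; (2) majority vote
#' of the base classifiers' crisp predictions; (3) the lowest class index
#' among the tied vote leaders. The stage that decided each instance is
#' reported.
#'
#' @param object A `"bitfusion"` model.
#' @param xi A `"support_tensor"` with matching class set and classifier
#'   order.
#' @param ... Unused.
#' @return Tibble with columns `instance`, `class` (factor over the model's
#'   class set), `stage` (factor: `bit_count`, `support_sum`,
#'   `majority_vote`, `lowest_index`), and `bits` (bits fired for the
#'   winning class).
#' @export
predict.bitfusion <- function(object, xi, ...) {
  stopifnot(inherits(xi, "support_tensor"))
  if (!identical(attr(xi, "class_set"), object$class_set)) {
    abort("tensor class set does not match the model")
  }
  if (dim(xi)[3] != ncol(object$weights)) {
    abort("tensor classifier count does not match the model")
  }
  d <- dim(xi)
  n <- d[1]; p <- d[2]
  vals <- unclass(xi)
  f_all <- sweep(vals, c(2, 3), object$weights, "*")
  B_all <- (f_all > object$config$delta) * 1
  g_all <- sweep(vals, c(2, 3), abs(object$weights), "*")
  am <- apply(vals, c(1, 3), which.max)
  if (is.null(dim(am))) am <- matrix(am, nrow = n)
  stages <- integer(n)
  cls <- integer(n)
  bits <- integer(n)
  for (i in seq_len(n)) {
    B <- matrix(B_all[i, , ], p)
    dec <- decide_instance(B, matrix(g_all[i, , ], p), am[i, ], p)
    cls[i] <- dec[1]
    stages[i] <- dec[2]
    bits[i] <- sum(B[dec[1], ])
  }
  tibble::tibble(
    instance = seq_len(n),
    class = factor(object$class_set[cls], levels = object$class_set),
    stage = factor(c("bit_count", "support_sum", "majority_vote",
                     "lowest_index")[stages],
                   levels = c("bit_count", "support_sum", "majority_vote",
                              "lowest_index")),
    bits = bits
  )
}

#' @export
print.bitfusion <- function(x, ...) {
  cat(sprintf("<bitfusion> %d classes x %d classifiers, %d epochs (regime: %s, sign: %s)\n",
              nrow(x$weights), ncol(x$weights), x$config$epochs,
              x$config$regime, x$config$error_sign))
  cat(sprintf("delta = %g, eta = %g, mu = %g, final phi = %.6f\n",
              x$config$delta, x$config$eta, x$config$mu,
              x$mse_trace[length(x$mse_trace)]))
  invisible(x)
}

#' Tidy the trained fusion weights
#'
#' @param x A `"bitfusion"` model.
#' @param ... Unused.
#' @return Tibble with columns `class`, `classifier`, `weight`.
#' @export
tidy.bitfusion <- function(x, ...) {
  tibble::tibble(
    class = rep(x$class_set, times = length(x$classifier_ids)),
    classifier = rep(x$classifier_ids, each = length(x$class_set)),
    weight = as.vector(x$weights)
  )
}

#' One-row summary of a trained fusion model
#'
#' @param x A `"bitfusion"` model.
#' @param ... Unused.
#' @return One-row tibble: dimensions, config, initial and final phi.
#' @export
glance.bitfusion <- function(x, ...) {
  tibble::tibble(
    n_classes = nrow(x$weights), n_classifiers = ncol(x$weights),
    n_train = x$n_train, epochs = x$config$epochs,
    delta = x$config$delta, eta = x$config$eta, mu = x$config$mu,
    error_sign = x$config$error_sign,
    phi_first = x$mse_trace[1], phi_final = x$mse_trace[length(x$mse_trace)]
  )
}

#' Plot the per-epoch training error trace
#'
#' @param object A `"bitfusion"` model.
#' @param ... Unused.
#' @return A ggplot of phi (mean squared bit error) against epoch.
#' @export
autoplot.bitfusion <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$mse_trace),
                       phi = object$mse_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$phi)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "epoch", y = expression(phi ~ "(mean squared bit error)"),
                  title = "Bit-fusion training error") +
    ggplot2::theme_minimal()
}

#' Serialize a trained fusion model to JSON
#'
#' @param model A `"bitfusion"` model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fusion_model <- function(model, path) {
  stopifnot(inherits(model, "bitfusion"))
  doc <- list(weights = model$weights,
              config = unclass(model$config),
              class_set = model$class_set,
              classifier_ids = model$classifier_ids,
              mse_trace = model$mse_trace,
              bits_fired = model$bits_fired,
              n_train = model$n_train)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a fusion model written by [write_fusion_model()]
#'
#' @param path JSON path.
#' @return A `"bitfusion"` model.
#' @export
read_fusion_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- doc$config
  config <- fusion_config(delta = cfg$delta, eta = cfg$eta, mu = cfg$mu,
                          epochs = cfg$epochs, seed = cfg$seed,
                          error_sign = cfg$error_sign, regime = cfg$regime)
  wt <- doc$weights
  if (!is.matrix(wt)) wt <- matrix(unlist(wt), nrow = length(doc$class_set))
  structure(list(weights = wt, config = config, class_set = doc$class_set,
                 classifier_ids = doc$classifier_ids,
                 mse_trace = doc$mse_trace, bits_fired = doc$bits_fired,
                 n_train = doc$n_train),
            class = "bitfusion")
}
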
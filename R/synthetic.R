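#' Generate a Gaussian-cluster classification dataset
#'
#' Draws `p` isotropic Gaussian clusters with unit within-class standard
#' deviation whose centroids sit on a regular simplex scaled so every pair
#' is `separation` apart — `separation` is therefore the inter-centroid
#' distance in units of the within-class spread. Classes are balanced to
#' within one instance. Deterministic per seed.
#'
#' @param n Number of instances.
#' @param classes Number of classes `p >= 2`.
#' @param features Feature dimension `d >= max(1, p - 1)` (the simplex needs
#'   `p - 1` dimensions).
#' @param separation Pairwise centroid distance, `>= 0`. `0` produces
#'   label-free noise.
#' @param seed Integer seed.
#' @return Tibble with numeric columns `f1..fd` and factor column `class`
#'   (levels `c1..cp`).
#' @examples
#' make_gaussian_dataset(30, classes = 3, features = 5, separation = 8, seed = 1)
#' @export
make_gaussian_dataset <- function(n, classes = 3L, features = 5L,
                                  separation = 4, seed = 1L) {
  p <- as.integer(classes); d <- as.integer(features)
  if (p < 2L || d < 1L) abort("need p >= 2 classes and d >= 1 features")
  if (separation < 0) abort("separation must be >= 0")
  if (d < p - 1L) abort("features must be at least classes - 1 for the simplex scaffold")
  cent <- simplex_centroids(p, d) * separation
  lab <- rep(seq_len(p), length.out = n)  # balanced +/- 1
  withr::with_seed(as.integer(seed), {
    lab <- sample(lab)
    x <- matrix(stats::rnorm(n * d), n, d) + cent[lab, , drop = FALSE]
  })
  out <- tibble::as_tibble(as.data.frame(x))
  names(out) <- paste0("f", seq_len(d))
  out$class <- factor(paste0("c", lab), levels = paste0("c", seq_len(p)))
  out
}

# Vertices of a regular unit-edge simplex with p vertices, embedded in d >=
# p-1 dimensions and centered at the origin. The scaled standard basis
# e_i / sqrt(2) has exactly unit pairwise distances; centering and rotating
# onto its principal axes drops it into p-1 coordinates without moving any
# distance. Deterministic geometry.
simplex_centroids <- function(p, d) {
  e <- diag(p) / sqrt(2)
  c0 <- sweep(e, 2, colMeans(e))
  rot <- svd(c0)$v[, seq_len(p - 1L), drop = FALSE]
  out <- matrix(0, p, d)
  out[, seq_len(p - 1L)] <- c0 %*% rot
  out
}

#' Simulate a raw base-classifier support tensor
#'
#' Generates labels and an `n x p x l` support tensor directly, with
#' controllable per-classifier accuracy and inter-classifier agreement —
#' the raw material for studying combiners without fitting any classifier.
#'
#' Per instance and classifier `j`, the classifier is correct with
#' probability `base_accuracies[j]`; otherwise a uniformly chosen wrong
#' class wins. A latent shared coin with weight `correlation` makes
#' classifiers reuse one shared correctness draw, so at `correlation = 1`
#' equally accurate classifiers err on exactly the same instances, and at
#' `0` they err independently. Soft slices are Dirichlet draws concentrated
#' on the winning class (concentration 10 on the winner, 1 elsewhere, fixed)
#' with the maximum coordinate guaranteed at the winner; hard slices are
#' one-hot.
#'
#' @param n Number of instances.
#' @param classes Number of classes `p >= 2`.
#' @param classifiers Number of classifiers `l >= 1`.
#' @param base_accuracies Length-l accuracies in (0, 1\] (recycled from a
#'   scalar). For fusion-learning studies keep them above chance `1/p`.
#' @param correlation Shared-error weight in \[0, 1\]. Default 0.
#' @param mode `"soft"` (default) or `"hard"`.
#' @param labels Optional true labels (length n, integer indices or factor
#'   over `c1..cp`); generated balanced at random when `NULL`.
#' @param seed Integer seed.
#' @return List with `xi` (a `"support_tensor"`) and `labels` (factor).
#' @export
make_synthetic_xi <- function(n, classes = 3L, classifiers = 5L,
                              base_accuracies = 0.7, correlation = 0,
                              mode = c("soft", "hard"), labels = NULL,
                              seed = 1L) {
  mode <- match.arg(mode)
  p <- as.integer(classes); l <- as.integer(classifiers)
  if (p < 2L || l < 1L) abort("need p >= 2 and l >= 1")
  acc <- rep(base_accuracies, length.out = l)
  if (any(acc <= 0 | acc > 1)) abort("base accuracies must lie in (0, 1]")
  if (correlation < 0 || correlation > 1) abort("correlation must lie in [0, 1]")
  class_set <- paste0("c", seq_len(p))
  withr::with_seed(as.integer(seed), {
    if (is.null(labels)) {
      lab <- sample(rep(seq_len(p), length.out = n))
    } else {
      lab <- if (is.numeric(labels)) as.integer(labels) else
        match(as.character(labels), class_set)
      if (anyNA(lab) || length(lab) != n) abort("invalid labels")
    }
    shared_u <- runif(n)          # shared correctness coin
    use_shared <- matrix(runif(n * l) < correlation, n, l)
    own_u <- matrix(runif(n * l), n, l)
    u <- ifelse(use_shared, shared_u, own_u)
    winner <- matrix(0L, n, l)
    for (j in seq_len(l)) {
      correct <- u[, j] < acc[j]
      wrong <- (lab - 1L + sample(p - 1L, n, replace = TRUE)) %% p + 1L
      winner[, j] <- ifelse(correct, lab, wrong)
    }
    vals <- array(0, c(n, p, l))
    if (mode == "hard") {
      for (j in seq_len(l)) vals[cbind(seq_len(n), winner[, j], j)] <- 1
    } else {
      for (j in seq_len(l)) {
        g <- matrix(rgamma(n * p, shape = 1), n, p)
        gw <- rgamma(n, shape = 10)
        # guarantee the winner coordinate is the maximum of its slice
        rowmax <- apply(g, 1, max)
        g[cbind(seq_len(n), winner[, j])] <- pmax(gw, rowmax + 1e-9)
        vals[, , j] <- g / rowSums(g)
      }
    }
  })
  list(xi = support_tensor(vals, class_set, mode = mode),
       labels = factor(class_set[lab], levels = class_set))
}

#' Write a support tensor with a JSON sidecar
#'
#' Stores the tensor as a long CSV (instance, class, classifier, support)
#' with a JSON sidecar recording shape, class set, classifier ids and mode,
#' so the pair round-trips through [read_xi()].
#'
#' @param xi A `"support_tensor"`.
#' @param path CSV path; the sidecar is written at `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_xi <- function(xi, path) {
  readr::write_csv(as_tibble(xi), path)
  jsonlite::write_json(list(shape = dim(xi),
                            class_set = attr(xi, "class_set"),
                            classifier_ids = attr(xi, "classifier_ids"),
                            mode = attr(xi, "mode")),
                       paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a support tensor written by [write_xi()]
#'
#' @param path CSV path with its `.json` sidecar alongside.
#' @return A `"support_tensor"`.
#' @export
read_xi <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  long <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  d <- meta$shape
  vals <- array(0, d)
  i <- long$instance
  r <- match(long$class, meta$class_set)
  j <- match(long$classifier, meta$classifier_ids)
  vals[cbind(i, r, j)] <- long$support
  support_tensor(vals, meta$class_set, meta$classifier_ids, mode = meta$mode)
}
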
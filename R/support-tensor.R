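#' Construct a support tensor
#'
#' The support tensor stacks, for every instance, the per-class degree of
#' support emitted by each base classifier: an `n x p x l` array with entries
#' in `[0, 1]`. In `soft` mode every p-vector slice (one instance, one
#' classifier) sums to 1; in `hard` mode every slice is one-hot, the crisp
#' label under the maximum-membership rule.
#'
#' @param values Numeric `n x p x l` array.
#' @param class_set Character vector of the p class identifiers, in order.
#' @param classifier_ids Character vector of the l classifier identifiers.
#' @param mode `"soft"` or `"hard"`.
#' @return A `"support_tensor"` object (the validated array with attributes).
#' @export
support_tensor <- function(values, class_set, classifier_ids = NULL,
                           mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  if (length(dim(values)) != 3L) abort("values must be a 3-d array (n x p x l)")
  d <- dim(values)
  if (length(class_set) != d[2]) abort("class_set length must equal dim 2 of values")
  if (is.null(classifier_ids)) classifier_ids <- paste0("clf", seq_len(d[3]))
  if (length(classifier_ids) != d[3]) abort("classifier_ids length must equal dim 3")
  if (anyNA(values) || any(values < -1e-12) || any(values > 1 + 1e-12)) {
    abort("support entries must lie in [0, 1]")
  }
  values <- pmin(pmax(values, 0), 1)
  if (mode == "soft") {
    sums <- apply(values, c(1, 3), sum)
    if (any(abs(sums - 1) > 1e-8)) {
      abort("in soft mode every instance-classifier slice must sum to 1")
    }
  } else {
    ok <- apply(values, c(1, 3), function(v) {
      all(v %in% c(0, 1)) && sum(v) == 1
    })
    if (!all(ok)) abort("in hard mode every instance-classifier slice must be one-hot")
  }
  structure(values,
            class_set = as.character(class_set),
            classifier_ids = as.character(classifier_ids),
            mode = mode,
            class = c("support_tensor", "array"))
}

#' @export
print.support_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<support_tensor> %d instances x %d classes x %d classifiers (%s)\n",
              d[1], d[2], d[3], attr(x, "mode")))
  cat("classes:    ", paste(attr(x, "class_set"), collapse = ", "), "\n")
  cat("classifiers:", paste(attr(x, "classifier_ids"), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a support tensor into long form
#'
#' @param x A `"support_tensor"`.
#' @param ... Unused.
#' @return Tibble with columns `instance`, `class`, `classifier`, `support`.
#' @export
as_tibble.support_tensor <- function(x, ...) {
  d <- dim(x)
  tibble::tibble(
    instance = rep(seq_len(d[1]), times = d[2] * d[3]),
    class = rep(rep(attr(x, "class_set"), each = d[1]), times = d[3]),
    classifier = rep(attr(x, "classifier_ids"), each = d[1] * d[2]),
    support = as.vector(unclass(x))
  )
}

#' Extract one instance's p x l support slice
#'
#' @param xi A `"support_tensor"`.
#' @param i Instance index.
#' @return A p x l matrix (classes in rows, classifiers in columns).
#' @export
xi_slice <- function(xi, i) {
  s <- unclass(xi)[i, , , drop = TRUE]
  m <- matrix(s, nrow = dim(xi)[2], ncol = dim(xi)[3])
  dimnames(m) <- list(attr(xi, "class_set"), attr(xi, "classifier_ids"))
  m
}

#' Crisp per-classifier predictions from a support tensor
#'
#' Applies the maximum-membership rule to every instance-classifier slice
#' (ties to the lowest class index).
#'
#' @param xi A `"support_tensor"`.
#' @return Integer n x l matrix of class indices into the tensor's class set.
#' @export
xi_argmax <- function(xi) {
  apply(unclass(xi), c(1, 3), which.max)
}

#' Project a soft tensor to hard (one-hot) mode
#'
#' @param xi A `"support_tensor"` in soft mode.
#' @return The equivalent hard-mode tensor: each slice one-hot at the
#'   maximum-membership class.
#' @export
xi_harden <- function(xi) {
  d <- dim(xi)
  am <- xi_argmax(xi)
  vals <- array(0, d)
  for (j in seq_len(d[3])) {
    vals[cbind(seq_len(d[1]), am[, j], j)] <- 1
  }
  support_tensor(vals, attr(xi, "class_set"), attr(xi, "classifier_ids"),
                 mode = "hard")
}
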
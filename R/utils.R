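#' @importFrom rlang abort warn .data
#' @importFrom stats predict rgamma runif setNames var
#' @importFrom tibble as_tibble
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
tibble::as_tibble

# Derive a reproducible child seed from a parent seed and a small offset,
# staying inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

# Split a data frame into a numeric feature matrix and a factor label vector
# whose levels are in first-appearance order.
split_features <- function(data, label) {
  stopifnot(is.data.frame(data))
  if (!label %in% names(data)) {
    abort(sprintf("label column '%s' not found in data", label))
  }
  y <- data[[label]]
  if (!is.factor(y)) y <- factor(y, levels = unique(as.character(y)))
  x <- data[setdiff(names(data), label)]
  bad <- !vapply(x, is.numeric, logical(1))
  if (any(bad)) {
    abort(sprintf("non-numeric feature column(s): %s",
                  paste(names(x)[bad], collapse = ", ")))
  }
  x <- as.matrix(x)
  if (anyNA(x) || any(!is.finite(x))) {
    idx <- which(is.na(x) | !is.finite(x), arr.ind = TRUE)[1, ]
    abort(sprintf("missing or non-finite feature value at row %d, column '%s'",
                  idx[1], colnames(x)[idx[2]]))
  }
  list(x = x, y = y)
}

# Lowest-index argmax, the crisp-label rule used throughout.
which_max1 <- function(v) which.max(v)

# Argmax that reports ties: returns index if the maximum is unique, NA otherwise.
unique_argmax <- function(v) {
  m <- max(v)
  idx <- which(v == m)
  if (length(idx) == 1L) idx else NA_integer_
}
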
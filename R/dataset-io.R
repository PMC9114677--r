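#' Read a delimited feature table with one label column
#'
#' Parses a delimited text file into a tibble of numeric features plus one
#' class-label column. The label column is converted to a factor whose levels
#' are ordered by first appearance in the file, so the class dictionary used
#' downstream (support tensors, fusion weights) is reproducible from the file
#' alone.
#'
#' @param path Path to a delimited text file, one row per instance.
#' @param label Label column, by name (character) or position (integer).
#'   Default `"class"`.
#' @param delim Field delimiter. Default `","`.
#' @param col_names Does the file have a header row? Default `TRUE`; when
#'   `FALSE`, columns are named `X1..Xm`.
#' @return A tibble with all feature columns numeric and the label column a
#'   factor (levels in first-appearance order). At least two distinct classes
#'   are required.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' readr::write_csv(tibble::tibble(f1 = c(1, 2, 3, 4), f2 = c(0, 1, 0, 1),
#'                                 class = c("a", "a", "b", "b")), tf)
#' load_table(tf)
#' @export
load_table <- function(path, label = "class", delim = ",", col_names = TRUE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_delim(path, delim = delim, col_names = col_names,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) < 1L) abort("empty table")
  if (is.numeric(label)) {
    if (label < 1L || label > ncol(raw)) abort("label column index out of range")
    label <- names(raw)[label]
  }
  if (!label %in% names(raw)) {
    abort(sprintf("label column '%s' not found; columns are: %s",
                  label, paste(names(raw), collapse = ", ")))
  }
  feats <- setdiff(names(raw), label)
  if (length(feats) < 1L) abort("table has no feature columns")
  out <- raw
  for (cn in feats) {
    cell <- raw[[cn]]
    missing_at <- which(is.na(cell) | cell == "")
    if (length(missing_at) > 0L) {
      abort(sprintf("missing value at row %d, column '%s'", missing_at[1], cn))
    }
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num))
    if (length(bad) > 0L) {
      abort(sprintf("non-numeric feature value '%s' at row %d, column '%s'",
                    cell[bad[1]], bad[1], cn))
    }
    out[[cn]] <- num
  }
  lab <- raw[[label]]
  if (anyNA(lab) || any(lab == "")) {
    abort(sprintf("missing label at row %d", which(is.na(lab) | lab == "")[1]))
  }
  classes <- unique(lab)
  if (length(classes) < 2L) abort("file contains a single class; need at least 2")
  out[[label]] <- factor(lab, levels = classes)
  out[c(feats, label)]
}

#' Write a feature table to delimited text
#'
#' Inverse of [load_table()]: writes the tibble so that re-reading it
#' round-trips the features and the first-appearance class order exactly.
#'
#' @param data A tibble as returned by [load_table()].
#' @param path Output file path.
#' @param delim Field delimiter. Default `","`.
#' @return `path`, invisibly.
#' @export
write_table <- function(data, path, delim = ",") {
  readr::write_delim(data, path, delim = delim)
  invisible(path)
}

#' Min-max normalization to the unit interval
#'
#' Rescales each feature column to `[0, 1]`: the column minimum maps to 0 and
#' the maximum to 1. The returned range record lets the identical affine map
#' be applied to held-out data with [minmax_apply()], so scaling can be fit on
#' training folds only.
#'
#' A constant column (max equal to min) is mapped to all zeros with a warning
#' rather than dividing by zero.
#'
#' @param x Numeric matrix or data frame of features (instances in rows).
#' @return A list with `values` (the rescaled matrix) and `ranges` (a tibble
#'   with columns `feature`, `min`, `max`).
#' @examples
#' minmax_normalize(cbind(a = c(2, 4, 6)))$values
#' @export
minmax_normalize <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x) || any(!is.finite(x))) abort("features must be finite")
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  constant <- maxs == mins
  if (any(constant)) {
    warn(sprintf("constant column(s) mapped to 0: %s",
                 paste(colnames(x)[constant] %||% which(constant), collapse = ", ")))
  }
  ranges <- tibble::tibble(
    feature = colnames(x) %||% paste0("V", seq_len(ncol(x))),
    min = unname(mins), max = unname(maxs)
  )
  list(values = minmax_apply(ranges, x), ranges = ranges)
}

#' Apply a fitted min-max range record to new data
#'
#' @param ranges The `ranges` tibble from [minmax_normalize()].
#' @param x Numeric matrix or data frame with the same columns, in order.
#' @return Rescaled matrix. Values outside the training range map outside
#'   `[0, 1]`; constant training columns map to 0.
#' @export
minmax_apply <- function(ranges, x) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(ranges)) abort("column count does not match the fitted ranges")
  span <- ranges$max - ranges$min
  out <- sweep(x, 2, ranges$min, "-")
  nz <- span > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, span[nz], "/")
  out[, !nz] <- 0
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a principal-component model for feature extraction
#'
#' Eigendecomposition of the `1/n` covariance matrix of (by default)
#' mean-centered features. The retained dimension is either a given integer
#' `k` or, for a fractional `retain`, the smallest `k` whose cumulative
#' eigenvalue fraction reaches it. Eigenvector signs follow the convention
#' that each vector's largest-magnitude component is positive, making the
#' decomposition deterministic.
#'
#' `center = FALSE` decomposes the raw second-moment matrix instead of the
#' covariance; the default centers first, which is standard practice.
#'
#' @param x Numeric feature matrix (n instances x m features), n >= 2.
#' @param retain Integer number of components, or a variance fraction in
#'   (0, 1). Default `0.95`.
#' @param center Subtract the column means first? Default `TRUE`.
#' @return An object of class `"pca_model"`: list with `mean` (length-m
#'   vector; zeros when `center = FALSE`), `rotation` (m x k orthonormal
#'   matrix), `eigenvalues` (nonincreasing, length k), and `k`.
#' @examples
#' x <- cbind(x = 1:5, y = 2 * (1:5))
#' pca_fit(x, retain = 2)$eigenvalues
#' @export
pca_fit <- function(x, retain = 0.95, center = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 2L) abort("need at least 2 instances to fit PCA")
  if (retain >= 1 && retain != as.integer(retain)) abort("retain must be an integer or a fraction in (0,1)")
  if (retain >= 1 && retain > m) abort(sprintf("retain k = %d exceeds feature count m = %d", as.integer(retain), m))
  mu <- if (center) colMeans(x) else rep(0, m)
  xc <- sweep(x, 2, mu)
  z <- crossprod(xc) / n
  eg <- eigen(z, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors
  # sign convention: largest-magnitude component of each eigenvector positive
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  k <- if (retain < 1) {
    frac <- cumsum(vals) / sum(vals)
    as.integer(which(frac >= retain)[1])
  } else {
    as.integer(retain)
  }
  structure(list(mean = mu, rotation = vecs[, seq_len(k), drop = FALSE],
                 eigenvalues = vals[seq_len(k)], k = k, m = m),
            class = "pca_model")
}

#' Project features onto a fitted principal-component basis
#'
#' @param model A `"pca_model"` from [pca_fit()].
#' @param x Numeric matrix with the same feature width the model was fit on.
#' @return An n x k matrix of scores: row i holds the projections
#'   `u_j' (x_i - mean)` for j = 1..k.
#' @export
pca_transform <- function(model, x) {
  stopifnot(inherits(model, "pca_model"))
  x <- as.matrix(x)
  if (ncol(x) != model$m) {
    abort(sprintf("feature width %d does not match the fitted width %d", ncol(x), model$m))
  }
  out <- sweep(x, 2, model$mean) %*% model$rotation
  colnames(out) <- paste0("PC", seq_len(model$k))
  out
}

#' Serialize preprocessing state to JSON
#'
#' Writes the min-max ranges and/or PCA model as a single JSON document so a
#' fitted preprocessing pipeline can be re-applied elsewhere.
#'
#' @param path Output path.
#' @param ranges Optional ranges tibble from [minmax_normalize()].
#' @param pca Optional `"pca_model"`.
#' @return `path`, invisibly.
#' @export
write_preprocess <- function(path, ranges = NULL, pca = NULL) {
  doc <- list()
  if (!is.null(ranges)) doc$minmax <- ranges
  if (!is.null(pca)) {
    doc$pca <- list(mean = pca$mean, rotation = pca$rotation,
                    eigenvalues = pca$eigenvalues, k = pca$k, m = pca$m)
  }
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read preprocessing state written by [write_preprocess()]
#'
#' @param path JSON path.
#' @return List with elements `ranges` (tibble or NULL) and `pca`
#'   (`"pca_model"` or NULL).
#' @export
read_preprocess <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(ranges = NULL, pca = NULL)
  if (!is.null(doc$minmax)) out$ranges <- tibble::as_tibble(doc$minmax)
  if (!is.null(doc$pca)) {
    rot <- doc$pca$rotation
    if (!is.matrix(rot)) rot <- matrix(unlist(rot), nrow = doc$pca$m)
    out$pca <- structure(list(mean = doc$pca$mean, rotation = rot,
                              eigenvalues = doc$pca$eigenvalues,
                              k = doc$pca$k, m = doc$pca$m),
                         class = "pca_model")
  }
  out
}
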
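#' Specify a base classifier
#'
#' Describes one of the five first-stage classifiers whose soft supports feed
#' the combiner: Gaussian naive Bayes, a CART decision tree (Gini), an
#' RBF-kernel SVM with pairwise-coupled probability calibration, k-nearest
#' neighbours (Euclidean, vote fractions), or a single-hidden-layer MLP.
#'
#' Hyperparameters (all optional, with field-standard defaults):
#' * `knn`: `k` (default 10 neighbours).
#' * `svm_rbf`: `C` (default 1), `gamma` (default `1/m`), `grid_search`
#'   (default `FALSE`; when `TRUE`, inner cross-validation searches
#'   `C` over `2^(-5..5)` and `gamma` over `2^(-15..-1)`).
#' * `mlp`: `hidden_units` (default `max(4, ceiling((m+p)/2))`), `eta`
#'   (weight decay, default 1e-4), `mu` (accepted for config compatibility),
#'   `maxit` (default 200).
#' * `decision_tree`: `minsplit` (default 2), `cp` (default 0.001, i.e. the
#'   tree is grown nearly unpruned).
#'
#' @param method One of `"naive_bayes"`, `"decision_tree"`, `"svm_rbf"`,
#'   `"knn"`, `"mlp"`. (The argument is called `method`, not `kind`, so that
#'   hyperparameters like `k` never partially match it.)
#' @param ... Hyperparameters as named values (see Details).
#' @param seed Integer seed for any stochastic parts of fitting.
#' @return A `"base_spec"` list.
#' @export
base_spec <- function(method = c("naive_bayes", "decision_tree", "svm_rbf", "knn", "mlp"),
                      ..., seed = 1L) {
  kind <- match.arg(method)
  hp <- list(...)
  if (kind == "knn" && !is.null(hp$k) && hp$k < 1) abort("knn.k must be >= 1")
  if (kind == "svm_rbf") {
    if (!is.null(hp$C) && hp$C <= 0) abort("svm.C must be > 0")
    if (!is.null(hp$gamma) && hp$gamma <= 0) abort("svm.gamma must be > 0")
  }
  structure(list(kind = kind, hyperparameters = hp, seed = as.integer(seed)),
            class = "base_spec")
}

#' The default five-classifier ensemble
#'
#' @param seed Base seed; each classifier gets a distinct derived seed.
#' @return List of five `"base_spec"` objects (naive Bayes, decision tree,
#'   RBF-SVM, 10-NN, MLP).
#' @export
default_base_specs <- function(seed = 1L) {
  kinds <- c("naive_bayes", "decision_tree", "svm_rbf", "knn", "mlp")
  setNames(purrr::map(seq_along(kinds),
                      ~ base_spec(kinds[.x], seed = derive_seed(seed, .x))),
           kinds)
}

svm_grid <- function() {
  list(C = 2^(-5:5), gamma = 2^(-15:-1))
}

# Inner-CV grid search for the RBF-SVM over the standard C/gamma grids.
# Falls back (with a warning) to defaults when a class is too small for the
# inner folds.
tune_svm <- function(x, y, seed, inner_k = 3L) {
  grid <- svm_grid()
  if (min(table(y)) < inner_k) {
    warn("a class has fewer instances than the inner folds; skipping grid search")
    return(list(C = 1, gamma = 1 / ncol(x)))
  }
  folds <- kfold_split(y, k = inner_k, stratified = TRUE, seed = seed)
  best <- c(Inf, 1, 1 / ncol(x))
  for (C in grid$C) for (g in grid$gamma) {
    err <- 0
    for (f in seq_len(inner_k)) {
      tr <- folds != f
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = C, gamma = g, scale = FALSE)
      err <- err + mean(predict(fit, x[!tr, , drop = FALSE]) != y[!tr])
    }
    if (err < best[1]) best <- c(err, C, g)
  }
  list(C = best[2], gamma = best[3])
}

#' Fit one base classifier
#'
#' @param spec A `"base_spec"`.
#' @param x Numeric feature matrix (training instances in rows).
#' @param y Factor of class labels; its levels define the class set over
#'   which supports are emitted.
#' @return A `"base_model"` able to emit class supports via [predict_soft()].
#' @export
fit_base <- function(spec, x, y) {
  stopifnot(inherits(spec, "base_spec"))
  x <- as.matrix(x)
  y <- if (is.factor(y)) droplevels(y) else factor(y, levels = unique(as.character(y)))
  if (nrow(x) < 1L || nlevels(y) < 2L) abort("need >= 1 instance of >= 2 classes")
  hp <- spec$hyperparameters
  m <- ncol(x); p <- nlevels(y)
  colnames(x) <- paste0("f", seq_len(m))
  fit <- withr::with_seed(spec$seed, switch(
    spec$kind,
    naive_bayes = e1071::naiveBayes(x, y),
    decision_tree = {
      df <- data.frame(x, .y = y)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(
                     minsplit = hp$minsplit %||% 2L,
                     cp = hp$cp %||% 0.001, xval = 0))
    },
    svm_rbf = {
      pars <- if (isTRUE(hp$grid_search)) {
        tune_svm(x, y, seed = derive_seed(spec$seed, 11L))
      } else {
        list(C = hp$C %||% 1, gamma = hp$gamma %||% (1 / m))
      }
      fit <- e1071::svm(x, y, kernel = "radial", cost = pars$C,
                        gamma = pars$gamma, probability = TRUE, scale = FALSE)
      attr(fit, "tuned") <- pars
      fit
    },
    knn = caret::knn3(x, y, k = min(hp$k %||% 10L, nrow(x))),
    mlp = {
      size <- hp$hidden_units %||% max(4L, ceiling((m + p) / 2))
      nnet::nnet(x, nnet::class.ind(y), size = size, softmax = p > 2,
                 entropy = p == 2, decay = hp$eta %||% 1e-4,
                 maxit = hp$maxit %||% 200L, trace = FALSE, MaxNWts = 5000L)
    }
  ))
  structure(list(spec = spec, fit = fit, class_set = levels(y), m = m),
            class = "base_model")
}

#' Soft class supports from a fitted base classifier
#'
#' Every row is a degree-of-support vector over the model's class set:
#' entries in `[0, 1]`, summing to 1. The crisp prediction is the row argmax
#' (maximum-membership rule, ties to the lowest class index).
#'
#' @param model A `"base_model"` from [fit_base()].
#' @param x Feature matrix with the same width the model was fit on.
#' @return An n x p matrix of supports, columns named by class.
#' @export
predict_soft <- function(model, x) {
  if (!inherits(model, "base_model")) abort("model is not a fitted base classifier")
  x <- as.matrix(x)
  if (ncol(x) != model$m) abort("feature width does not match the fitted model")
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  p <- length(model$class_set)
  pr <- switch(
    model$spec$kind,
    naive_bayes = predict(model$fit, x, type = "raw"),
    decision_tree = predict(model$fit, data.frame(x), type = "prob"),
    svm_rbf = attr(predict(model$fit, x, probability = TRUE), "probabilities"),
    knn = predict(model$fit, x, type = "prob"),
    mlp = {
      raw <- predict(model$fit, x)
      if (ncol(raw) == p) raw else cbind(1 - raw, raw)
    }
  )
  pr <- as.matrix(pr)
  if (is.null(colnames(pr)) || !all(model$class_set %in% colnames(pr))) {
    colnames(pr) <- model$class_set
  }
  pr <- pr[, model$class_set, drop = FALSE]
  dimnames(pr) <- list(NULL, model$class_set)
  # guard against numeric dust from the underlying libraries
  pr[pr < 0] <- 0
  rs <- rowSums(pr)
  zero <- rs <= 0
  if (any(zero)) pr[zero, ] <- 1 / p
  pr / pmax(rowSums(pr), .Machine$double.eps)
}

#' Build the support tensor of an ensemble
#'
#' Fits the listed base classifiers and assembles the `n x p x l` tensor of
#' their class supports. When scoring the training data itself,
#' `stacking = "out_of_fold"` (the default) produces each instance's supports
#' from models not trained on it, via an internal stratified split, which is
#' the unbiased input for combiner training; `"resubstitution"` scores the
#' training data with models trained on all of it.
#'
#' @param data Training tibble (features plus one label column).
#' @param label Name of the label column. Default `"class"`.
#' @param specs List of `"base_spec"` objects (default the standard five).
#' @param newdata Optional tibble or feature matrix to score instead of the
#'   training data (its label column, if present, is ignored for prediction
#'   but checked against the training class set).
#' @param mode `"soft"` (default) or `"hard"` (one-hot crisp labels).
#' @param stacking `"out_of_fold"` or `"resubstitution"`; only relevant when
#'   `newdata` is `NULL`.
#' @param inner_k Folds for the internal out-of-fold split. Default 5.
#' @param seed Seed for the internal split.
#' @return A list with `xi` (a `"support_tensor"`), `labels` (factor labels
#'   of the scored instances, or `NULL` when `newdata` has no label column),
#'   and `models` (the base models fitted on all of `data`).
#' @export
build_xi <- function(data, label = "class", specs = default_base_specs(),
                     newdata = NULL, mode = c("soft", "hard"),
                     stacking = c("out_of_fold", "resubstitution"),
                     inner_k = 5L, seed = 1L) {
  mode <- match.arg(mode)
  stacking <- match.arg(stacking)
  if (length(specs) < 1L) abort("need at least one base classifier spec")
  if (inherits(specs, "base_spec")) specs <- list(specs)
  tr <- split_features(data, label)
  class_set <- levels(tr$y)
  models <- purrr::map(specs, fit_base, x = tr$x, y = tr$y)
  ids <- names(specs) %||% purrr::map_chr(specs, "kind")
  if (is.null(names(specs))) ids <- make.unique(ids)

  if (!is.null(newdata)) {
    target_labels <- NULL
    if (is.data.frame(newdata) && label %in% names(newdata)) {
      sp <- split_features(newdata, label)
      xt <- sp$x
      if (!all(levels(sp$y) %in% class_set)) {
        abort("newdata contains class(es) absent from the training data")
      }
      target_labels <- factor(as.character(sp$y), levels = class_set)
    } else {
      xt <- as.matrix(newdata)
    }
    slices <- purrr::map(models, predict_soft, x = xt)
  } else {
    target_labels <- tr$y
    if (stacking == "resubstitution") {
      slices <- purrr::map(models, predict_soft, x = tr$x)
    } else {
      folds <- kfold_split(tr$y, k = inner_k, stratified = TRUE,
                           seed = derive_seed(seed, 101L))
      n <- nrow(tr$x); p <- length(class_set)
      slices <- purrr::map(specs, function(sp) {
        out <- matrix(NA_real_, n, p)
        for (f in sort(unique(folds))) {
          hold <- folds == f
          mod <- fit_base(sp, tr$x[!hold, , drop = FALSE], tr$y[!hold])
          pr <- predict_soft(mod, tr$x[hold, , drop = FALSE])
          # a fold's training part may miss a rare class; re-align columns
          full <- matrix(0, sum(hold), p, dimnames = list(NULL, class_set))
          full[, colnames(pr)] <- pr
          out[hold, ] <- full
        }
        out
      })
    }
  }
  n <- nrow(slices[[1]]); p <- length(class_set); l <- length(slices)
  vals <- array(0, c(n, p, l))
  for (j in seq_len(l)) vals[, , j] <- slices[[j]]
  xi <- support_tensor(vals, class_set, ids, mode = "soft")
  if (mode == "hard") xi <- xi_harden(xi)
  list(xi = xi, labels = target_labels, models = models)
}
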
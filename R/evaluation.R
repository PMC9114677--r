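#' Assign instances to k cross-validation folds
#'
#' Folds are disjoint, cover all instances and differ in size by at most
#' one. Stratified assignment (the default when labels are given) deals each
#' class's shuffled instances to the currently smallest folds, so per-fold
#' class proportions match the data within one instance. A class with fewer
#' instances than `k` triggers a warning and unstratified assignment.
#'
#' @param y Class labels (stratified case) or a single integer n.
#' @param k Number of folds, `2 <= k <= n`. Default 10.
#' @param stratified Preserve class proportions per fold? Default `TRUE`
#'   when `y` is a label vector.
#' @param seed Integer seed; the same seed reproduces the assignment.
#' @return Integer vector of fold ids (1..k), one per instance.
#' @export
kfold_split <- function(y, k = 10L, stratified = TRUE, seed = 1L) {
  n <- if (length(y) == 1L && is.numeric(y)) as.integer(y) else length(y)
  if (k < 2L || k > n) abort("need 2 <= k <= n folds")
  if (length(y) == 1L) stratified <- FALSE
  if (stratified) {
    tab <- table(y)
    if (min(tab) < k) {
      warn(sprintf("class '%s' has fewer than %d instances; using unstratified folds",
                   names(tab)[which.min(tab)], k))
      stratified <- FALSE
    }
  }
  withr::with_seed(as.integer(seed), {
    folds <- integer(n)
    if (!stratified) {
      folds <- sample(rep(seq_len(k), length.out = n))
    } else {
      counts <- integer(k)
      for (cl in unique(as.character(y))) {
        idx <- sample(which(as.character(y) == cl))
        # deal this class to the least-filled folds first
        ord <- order(counts, sample(k))
        target <- rep(ord, length.out = length(idx))
        folds[idx] <- target
        counts <- counts + tabulate(target, nbins = k)
      }
    }
    folds
  })
}

#' Misclassification percentage
#'
#' `100 * mismatches / n`; together with accuracy it sums to exactly 100.
#'
#' @param predicted,actual Equal-length label vectors.
#' @return Error rate in percent.
#' @export
error_rate <- function(predicted, actual) {
  if (length(predicted) != length(actual)) abort("length mismatch")
  if (length(predicted) < 1L) abort("need at least one prediction")
  100 * mean(as.character(predicted) != as.character(actual))
}

#' Per-fold accuracy gain over the best single classifier
#'
#' `Acc_j = (P_j - S_j) / m` where `P_j` and `S_j` are the counts of fold-j
#' instances correctly predicted by the fused model and by the comparator
#' (best single classifier), and `m` is the fold size. Always in \[-1, 1\].
#'
#' @param correct_proposed Integer `P_j` (0..m), possibly a vector over folds.
#' @param correct_best Integer `S_j` (0..m), same length.
#' @param fold_size Fold size(s) `m >= 1`.
#' @return Numeric vector of per-fold gains.
#' @export
accuracy_gain <- function(correct_proposed, correct_best, fold_size) {
  if (any(fold_size < 1)) abort("fold size must be >= 1")
  if (any(correct_proposed < 0 | correct_proposed > fold_size) ||
      any(correct_best < 0 | correct_best > fold_size)) {
    abort("correct counts must lie in [0, fold size]")
  }
  (correct_proposed - correct_best) / fold_size
}

#' Aggregate per-fold gains into a mean gain
#'
#' @param gains Per-fold gains from [accuracy_gain()].
#' @param comparator Name of the comparator method. Default `"best_single"`.
#' @return A `"gain_result"`: tibble of per-fold gains with the mean gain
#'   `ACC` and comparator recorded as attributes (also in [glance()] form
#'   via `attr(x, "acc")`).
#' @export
gain_summary <- function(gains, comparator = "best_single") {
  out <- tibble::tibble(fold = seq_along(gains), gain = gains)
  structure(out, acc = mean(gains), comparator = comparator,
            class = c("gain_result", class(out)))
}

#' Cross-validated comparison of fusion methods
#'
#' Runs stratified k-fold cross-validation of the full pipeline. Per fold:
#' preprocessing (min-max scaling, optional PCA) is fit on the training part
#' only; the base ensemble is fit on the training part; the combiner is
#' trained on out-of-fold training supports; every requested method then
#' scores the held-out fold. Base classifiers themselves are scored too, so
#' the accuracy-weighting baseline and the best-single-classifier comparator
#' are available.
#'
#' @param data Tibble of features plus one label column.
#' @param label Label column name. Default `"class"`.
#' @param specs Base-classifier specs. Default [default_base_specs()].
#' @param methods Character vector of methods to compare: `"bitfusion"`
#'   and/or any of [fuse_predict()]'s methods. Default
#'   `c("bitfusion", "majority")`.
#' @param k Folds. Default 10.
#' @param config `"fusion_config"` for the combiner.
#' @param normalize Min-max scale features (fit on training folds)? Default
#'   `TRUE`.
#' @param pca_retain `NULL` for no PCA, else an integer k or variance
#'   fraction passed to [pca_fit()].
#' @param stacking Supports used to train the combiner: `"out_of_fold"`
#'   (default) or `"resubstitution"`.
#' @param stratified Stratify the outer folds? Default `TRUE`.
#' @param seed Master seed; every internal seed derives from it.
#' @return A `"fusion_cv"` object: `results` (tibble: method, fold,
#'   error_rate), `fold_assignments`, `predictions` (tibble: instance, fold,
#'   method, predicted, actual), `fallback_stages` (bit-fusion diagnostics),
#'   `base_errors`, and the resolved configuration. Methods: [tidy()],
#'   [glance()], [autoplot()], [accuracy_gain_cv()].
#' @export
cross_validate <- function(data, label = "class", specs = default_base_specs(),
                           methods = c("bitfusion", "majority"), k = 10L,
                           config = fusion_config(), normalize = TRUE,
                           pca_retain = NULL,
                           stacking = c("out_of_fold", "resubstitution"),
                           stratified = TRUE, seed = 1L) {
  stacking <- match.arg(stacking)
  known <- c("bitfusion", fusion_method_names())
  bad <- setdiff(methods, known)
  if (length(bad) > 0L) {
    abort(sprintf("unknown method(s): %s (known: %s)",
                  paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  }
  sp <- split_features(data, label)
  y <- sp$y
  folds <- kfold_split(y, k = k, stratified = stratified,
                       seed = derive_seed(seed, 1L))
  base_ids <- names(specs) %||% purrr::map_chr(specs, "kind")
  rows <- list()
  pred_rows <- list()
  stage_rows <- list()
  for (f in seq_len(k)) {
    test <- folds == f
    if (nlevels(droplevels(y[!test])) < 2L) {
      abort(sprintf("training part of fold %d contains a single class", f))
    }
    x_tr <- sp$x[!test, , drop = FALSE]
    x_te <- sp$x[test, , drop = FALSE]
    if (normalize) {
      nm <- withCallingHandlers(minmax_normalize(x_tr),
                                warning = function(w) invokeRestart("muffleWarning"))
      x_tr <- nm$values
      x_te <- minmax_apply(nm$ranges, x_te)
    }
    if (!is.null(pca_retain)) {
      pm <- pca_fit(x_tr, retain = pca_retain)
      x_tr <- pca_transform(pm, x_tr)
      x_te <- pca_transform(pm, x_te)
    }
    tr_df <- tibble::as_tibble(as.data.frame(x_tr))
    tr_df[[label]] <- droplevels(y[!test])
    fold_seed <- derive_seed(seed, 1000L + f)
    built <- build_xi(tr_df, label = label, specs = specs, mode = "soft",
                      stacking = stacking, seed = fold_seed)
    xi_test <- {
      slices <- purrr::map(built$models, predict_soft, x = x_te)
      p <- nlevels(built$labels)
      vals <- array(0, c(nrow(x_te), p, length(slices)))
      for (j in seq_along(slices)) vals[, , j] <- slices[[j]]
      support_tensor(vals, levels(built$labels), base_ids, mode = "soft")
    }
    actual <- as.character(y[test])
    train_labels <- built$labels

    # per-base-classifier held-out error (also feeds accuracy weighting)
    base_acc_oof <- vapply(seq_along(specs), function(j) {
      am <- apply(unclass(built$xi)[, , j, drop = FALSE], 1, which.max)
      mean(levels(train_labels)[am] == as.character(train_labels))
    }, numeric(1))
    for (j in seq_along(base_ids)) {
      am <- apply(unclass(xi_test)[, , j, drop = FALSE], 1, which.max)
      pred <- levels(train_labels)[am]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = paste0("base:", base_ids[j]), fold = f,
        error_rate = error_rate(pred, actual))
      pred_rows[[length(pred_rows) + 1L]] <- tibble::tibble(
        instance = which(test), fold = f, method = paste0("base:", base_ids[j]),
        predicted = pred, actual = actual)
    }

    for (m in methods) {
      if (m == "bitfusion") {
        cfg <- config
        cfg$seed <- derive_seed(fold_seed, 7L)
        model <- train_bitfusion(built$xi, train_labels, cfg)
        pr <- predict(model, xi_test)
        pred <- as.character(pr$class)
        stage_rows[[length(stage_rows) + 1L]] <-
          dplyr::count(pr, .data$stage, name = "n_instances") |>
          dplyr::mutate(fold = f)
      } else {
        pred <- as.character(fuse_predict(xi_test, m, weights = base_acc_oof))
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = m, fold = f, error_rate = error_rate(pred, actual))
      pred_rows[[length(pred_rows) + 1L]] <- tibble::tibble(
        instance = which(test), fold = f, method = m,
        predicted = pred, actual = actual)
    }
  }
  results <- dplyr::bind_rows(rows)
  structure(list(
    results = results,
    fold_assignments = folds,
    predictions = dplyr::bind_rows(pred_rows),
    fallback_stages = if (length(stage_rows)) dplyr::bind_rows(stage_rows) else NULL,
    base_errors = results |>
      dplyr::filter(startsWith(.data$method, "base:")) |>
      dplyr::group_by(.data$method) |>
      dplyr::summarise(error_rate = mean(.data$error_rate), .groups = "drop"),
    methods = methods, k = as.integer(k), seed = as.integer(seed),
    config = config, stacking = stacking, class_set = levels(y)
  ), class = "fusion_cv")
}

#' @export
print.fusion_cv <- function(x, ...) {
  cat(sprintf("<fusion_cv> %d-fold cross-validation, seed %d\n", x$k, x$seed))
  print(glance(x))
  invisible(x)
}

#' Per-fold error rates of a cross-validation run
#'
#' @param x A `"fusion_cv"` object.
#' @param ... Unused.
#' @return Tibble with columns `method`, `fold`, `error_rate` (percent).
#' @export
tidy.fusion_cv <- function(x, ...) x$results

#' Average error rate per method
#'
#' @param x A `"fusion_cv"` object.
#' @param ... Unused.
#' @return Tibble with columns `method` and `average_error_rate` (percent,
#'   the mean of the per-fold error rates).
#' @export
glance.fusion_cv <- function(x, ...) {
  x$results |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(average_error_rate = mean(.data$error_rate),
                     .groups = "drop")
}

#' Plot per-fold error rates by method
#'
#' @param object A `"fusion_cv"` object.
#' @param ... Unused.
#' @return A ggplot: per-fold error rates with the per-method mean marked.
#' @export
autoplot.fusion_cv <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$method, y = .data$error_rate)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "#b2182b",
                          shape = 18, size = 3) +
    ggplot2::labs(x = NULL, y = "fold error rate (%)",
                  title = "Cross-validated error by fusion method") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Accuracy gain of a fused method over the best single classifier
#'
#' Per fold, counts the instances correctly predicted by `method` (`P_j`)
#' and by the comparator (`S_j`) and reports `Acc_j = (P_j - S_j) / m` and
#' its mean `ACC` over folds. The comparator defaults to the base classifier
#' with the lowest cross-validated average error in this run.
#'
#' @param cv A `"fusion_cv"` object.
#' @param method Fused method to assess. Default `"bitfusion"`.
#' @param comparator Comparator method name; default the best base
#'   classifier.
#' @return A `"gain_result"` (see [gain_summary()]); the mean gain is
#'   `attr(x, "acc")`.
#' @export
accuracy_gain_cv <- function(cv, method = "bitfusion", comparator = NULL) {
  stopifnot(inherits(cv, "fusion_cv"))
  if (is.null(comparator)) {
    comparator <- cv$base_errors$method[which.min(cv$base_errors$error_rate)]
  }
  gains <- vapply(seq_len(cv$k), function(f) {
    pf <- cv$predictions[cv$predictions$fold == f & cv$predictions$method == method, ]
    sf <- cv$predictions[cv$predictions$fold == f & cv$predictions$method == comparator, ]
    if (nrow(pf) == 0L || nrow(sf) == 0L) abort("method not present in this run")
    accuracy_gain(sum(pf$predicted == pf$actual),
                  sum(sf$predicted == sf$actual), nrow(pf))
  }, numeric(1))
  gain_summary(gains, comparator = comparator)
}

#' Write cross-validation results to disk
#'
#' Writes the per-fold tidy results as CSV and the per-method summary (plus
#' run configuration) as JSON.
#'
#' @param cv A `"fusion_cv"`.
#' @param dir Output directory (created if needed).
#' @return Paths of the files written, invisibly.
#' @export
write_cv_results <- function(cv, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "results.csv")
  readr::write_csv(cv$results, csv)
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(list(
    summary = glance(cv), k = cv$k, seed = cv$seed,
    methods = cv$methods, stacking = cv$stacking,
    config = unclass(cv$config), class_set = cv$class_set
  ), js, digits = NA, auto_unbox = TRUE)
  invisible(c(csv, js))
}
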
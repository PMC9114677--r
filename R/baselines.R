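#' Classical fusion baselines
#'
#' Fixed (untrained) combiner rules applied per instance to the p x l
#' support slice. Each rule accepts either a single p x l matrix or a whole
#' `"support_tensor"`; tensors return a label vector over all instances.
#' These are the standard literature definitions — reconstructions, not
#' replications of any particular published implementation — so comparisons
#' against published benchmark tables are qualitative.
#'
#' @name baselines
NULL

apply_rule <- function(xi, rule) {
  if (inherits(xi, "support_tensor")) {
    class_set <- attr(xi, "class_set")
    d <- dim(xi)
    vals <- unclass(xi)
    idx <- vapply(seq_len(d[1]),
                  function(i) rule(matrix(vals[i, , ], d[2], d[3])),
                  integer(1))
    factor(class_set[idx], levels = class_set)
  } else {
    xi <- as.matrix(xi)
    rule(xi)
  }
}

#' Majority vote
#'
#' Each classifier casts one vote for its maximum-membership class; the most
#' voted class wins, ties to the lowest class index.
#'
#' @param xi p x l support slice, or a `"support_tensor"`.
#' @return Class index (slice input) or factor of labels (tensor input).
#' @rdname baselines
#' @export
fuse_majority <- function(xi) {
  apply_rule(xi, function(s) {
    votes <- apply(s, 2, which.max)
    which.max(tabulate(votes, nbins = nrow(s)))
  })
}

#' Distribution summation
#'
#' Sums soft supports across classifiers and takes the per-class argmax.
#' On one-hot (hard) supports this coincides with majority voting.
#'
#' @rdname baselines
#' @export
fuse_distribution_sum <- function(xi) {
  apply_rule(xi, function(s) which.max(rowSums(s)))
}

#' Dempster-Shafer combination
#'
#' Each classifier's support vector becomes a belief mass function over the
#' class frame: mass `(1 - uncertainty) * support` on each singleton class
#' and mass `uncertainty` on the full frame. The l mass functions are
#' combined by Dempster's rule (normalized conjunctive combination) and the
#' singleton with maximal combined mass wins. Total conflict (normalization
#' constant zero) is an error.
#'
#' @param uncertainty Mass reserved for the full frame, in \[0, 1).
#'   Default 0.1.
#' @rdname baselines
#' @export
fuse_dempster <- function(xi, uncertainty = 0.1) {
  if (uncertainty < 0 || uncertainty >= 1) abort("uncertainty must lie in [0, 1)")
  apply_rule(xi, function(s) {
    m <- dempster_combine_slice(s, uncertainty)
    which.max(m$singletons)
  })
}

# Combine the l columns of a support slice as mass functions; returns the
# combined masses. Mass functions have singleton focal elements plus the
# full frame Theta.
dempster_combine_slice <- function(s, uncertainty) {
  p <- nrow(s)
  acc <- list(singletons = rep(0, p), theta = 1)  # vacuous identity
  for (j in seq_len(ncol(s))) {
    supp <- s[, j]
    total <- sum(supp)
    singl <- if (total > 0) (1 - uncertainty) * supp / total else rep(0, p)
    m2 <- list(singletons = singl, theta = 1 - sum(singl))
    acc <- dempster_pair(acc, m2)
  }
  acc
}

dempster_pair <- function(m1, m2) {
  comb <- m1$singletons * m2$singletons +
    m1$singletons * m2$theta + m1$theta * m2$singletons
  theta <- m1$theta * m2$theta
  k <- sum(comb) + theta
  if (k <= 0) abort("total conflict in Dempster combination (normalization constant 0)")
  list(singletons = comb / k, theta = theta / k)
}

#' Rank-based fusion
#'
#' Each classifier ranks the classes by support (rank 0 = best, ties take
#' the best tied rank). `"borda"` picks the class with the smallest summed
#' rank; `"highest_rank"` picks the class with the best minimum rank across
#' classifiers, ties broken by the second-best rank, then lowest index.
#'
#' @param scheme `"borda"` or `"highest_rank"`.
#' @rdname baselines
#' @export
fuse_rank <- function(xi, scheme = c("borda", "highest_rank")) {
  scheme <- match.arg(scheme)
  apply_rule(xi, function(s) {
    ranks <- apply(s, 2, function(col) rank(-col, ties.method = "min") - 1)
    ranks <- matrix(ranks, nrow = nrow(s))
    if (scheme == "borda") {
      which.min(rowSums(ranks))
    } else {
      sorted <- t(apply(ranks, 1, sort))
      sorted <- matrix(sorted, nrow = nrow(s))
      best <- do.call(order, as.data.frame(sorted))
      best[1]
    }
  })
}

#' Weighted support fusion
#'
#' Takes the argmax of a weighted sum of supports across classifiers.
#' `scheme = "entropy"` derives per-instance weights
#' `w_j = 1 - H(column j) / log p`, so confident (low-entropy) classifiers
#' count more; `scheme = "fixed"` uses supplied nonnegative weights — the
#' accuracy-weighting baseline passes each classifier's held-out accuracy
#' here (see [cross_validate()]).
#'
#' @param weights Length-l nonnegative weights (scheme `"fixed"`); at least
#'   one must be positive.
#' @rdname baselines
#' @export
fuse_weighted <- function(xi, weights = NULL, scheme = c("entropy", "fixed")) {
  scheme <- match.arg(scheme)
  if (scheme == "fixed") {
    if (is.null(weights) || any(weights < 0) || all(weights == 0)) {
      abort("fixed weighting needs nonnegative weights, not all zero")
    }
  }
  apply_rule(xi, function(s) {
    w <- if (scheme == "entropy") column_entropy_weights(s) else weights
    if (length(w) != ncol(s)) abort("weights length must equal classifier count")
    which.max(as.vector(s %*% w))
  })
}

column_entropy_weights <- function(s) {
  p <- nrow(s)
  apply(s, 2, function(col) {
    tot <- sum(col)
    if (tot <= 0) return(0)
    q <- col / tot
    q <- q[q > 0]
    h <- -sum(q * log(q))
    1 - h / log(p)
  })
}

#' Dispatch a fusion rule by name
#'
#' @param xi A `"support_tensor"`.
#' @param method One of `"majority"`, `"dist_sum"`, `"dempster"`, `"borda"`,
#'   `"highest_rank"`, `"entropy_w"`, `"accuracy_w"`.
#' @param weights Per-classifier weights, required for `"accuracy_w"`.
#' @param uncertainty Frame mass for `"dempster"`. Default 0.1.
#' @return Factor of predicted labels.
#' @export
fuse_predict <- function(xi, method, weights = NULL, uncertainty = 0.1) {
  switch(match.arg(method, fusion_method_names()),
         majority = fuse_majority(xi),
         dist_sum = fuse_distribution_sum(xi),
         dempster = fuse_dempster(xi, uncertainty),
         borda = fuse_rank(xi, "borda"),
         highest_rank = fuse_rank(xi, "highest_rank"),
         entropy_w = fuse_weighted(xi, scheme = "entropy"),
         accuracy_w = fuse_weighted(xi, weights = weights, scheme = "fixed"))
}

fusion_method_names <- function() {
  c("majority", "dist_sum", "dempster", "borda", "highest_rank",
    "entropy_w", "accuracy_w")
}
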
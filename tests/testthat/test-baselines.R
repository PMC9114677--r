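slice_from_votes <- function(votes, p) {
  s <- matrix(0, p, length(votes))
  s[cbind(votes, seq_along(votes))] <- 1
  s
}

test_that("majority vote counts crisp votes with a lowest-index tie rule", {
  # votes (a, a, b, a, b) -> a
  expect_equal(fuse_majority(slice_from_votes(c(1, 1, 2, 1, 2), 2)), 1L)
  # unanimity
  expect_equal(fuse_majority(slice_from_votes(rep(3, 4), 3)), 3L)
  # 2-2-1 split: lowest index of the tied pair
  expect_equal(fuse_majority(slice_from_votes(c(2, 2, 3, 3, 1), 3)), 2L)
})

test_that("distribution summation takes the argmax of summed supports", {
  # row sums (1.2, 2.4, 1.4) -> class 2
  expect_equal(fuse_distribution_sum(rbind(c(0.3, 0.5, 0.4),
                                           c(0.6, 0.9, 0.9),
                                           c(0.1, 0.6, 0.7))), 2L)
  # single classifier: its own argmax
  expect_equal(fuse_distribution_sum(cbind(c(0.2, 0.7, 0.1))), 2L)
})

test_that("distribution summation equals majority vote on every one-hot slice", {
  # all 27 vote patterns for 3 classes x 3 classifiers
  for (v1 in 1:3) for (v2 in 1:3) for (v3 in 1:3) {
    s <- slice_from_votes(c(v1, v2, v3), 3)
    expect_equal(fuse_distribution_sum(s), fuse_majority(s),
                 label = paste(v1, v2, v3))
  }
})

test_that("Dempster combination matches a hand computation and its algebraic laws", {
  # two classifiers, supports (0.8, 0.2) and (0.6, 0.4), no frame mass:
  # combined singleton masses proportional to (0.48, 0.08) -> class 1
  s <- cbind(c(0.8, 0.2), c(0.6, 0.4))
  expect_equal(fuse_dempster(s, uncertainty = 0), 1L)
  m <- bitfusion:::dempster_combine_slice(s, 0)
  expect_equal(m$singletons, c(0.48, 0.08) / 0.56, tolerance = 1e-12)

  # vacuous identity: combining with all-frame mass changes nothing
  m1 <- list(singletons = c(0.3, 0.2, 0.1), theta = 0.4)
  vac <- list(singletons = c(0, 0, 0), theta = 1)
  expect_equal(bitfusion:::dempster_pair(m1, vac), m1, tolerance = 1e-12)

  # order invariance and normalization
  set.seed(12)
  s5 <- matrix(runif(15), 3, 5)
  s5 <- sweep(s5, 2, colSums(s5), "/")
  ref <- bitfusion:::dempster_combine_slice(s5, 0.1)
  for (rep in 1:5) {
    perm <- sample(5)
    got <- bitfusion:::dempster_combine_slice(s5[, perm], 0.1)
    expect_equal(got$singletons, ref$singletons, tolerance = 1e-10)
    expect_equal(sum(got$singletons) + got$theta, 1, tolerance = 1e-10)
  }
})

test_that("rank fusion follows the documented Borda and highest-rank rules", {
  # ranks per classifier (0,1,2), (1,0,2), (1,0,2): borda sums (2,1,6) -> class 2
  s <- cbind(c(0.5, 0.3, 0.2), c(0.3, 0.5, 0.2), c(0.3, 0.5, 0.2))
  expect_equal(fuse_rank(s, "borda"), 2L)
  # single classifier: argmax under both schemes
  one <- cbind(c(0.1, 0.2, 0.7))
  expect_equal(fuse_rank(one, "borda"), 3L)
  expect_equal(fuse_rank(one, "highest_rank"), 3L)
  # a class ranked first by everyone wins under both schemes
  dom <- cbind(c(0.6, 0.3, 0.1), c(0.5, 0.4, 0.1), c(0.9, 0.05, 0.05))
  expect_equal(fuse_rank(dom, "borda"), 1L)
  expect_equal(fuse_rank(dom, "highest_rank"), 1L)
  # highest rank: best minimum rank wins, second-best breaks ties
  hr <- cbind(c(0.6, 0.3, 0.1), c(0.1, 0.6, 0.3), c(0.2, 0.5, 0.3))
  # class 1 ranks: 0,2,2 ; class 2 ranks: 1,0,0 ; both have a 0? no: min(c1)=0, min(c2)=0
  expect_equal(fuse_rank(hr, "highest_rank"), 2L)  # second-best 0 beats 2
})

test_that("weighted fusion honours entropy endpoints and fixed weights", {
  # one-hot column has entropy 0 (weight 1); uniform column entropy log p (weight 0)
  s <- cbind(c(0, 1, 0), rep(1 / 3, 3))
  expect_equal(fuse_weighted(s, scheme = "entropy"), 2L)
  # uniform weights reduce to distribution summation
  set.seed(3)
  for (rep in 1:10) {
    sl <- matrix(runif(12), 3, 4)
    sl <- sweep(sl, 2, colSums(sl), "/")
    expect_equal(fuse_weighted(sl, weights = rep(1, 4), scheme = "fixed"),
                 fuse_distribution_sum(sl))
  }
  # degenerate weighting follows the selected classifier
  s5 <- matrix(runif(15), 3, 5)
  expect_equal(fuse_weighted(s5, weights = c(1, 0, 0, 0, 0), scheme = "fixed"),
               which.max(s5[, 1]))
  expect_error(fuse_weighted(s5, weights = rep(0, 5), scheme = "fixed"), "weights")
})

test_that("all baselines are equivariant under class relabelling", {
  set.seed(23)
  perm <- c(3, 1, 2)  # new index of each old class
  rules <- list(
    majority = function(s) fuse_majority(s),
    dist_sum = function(s) fuse_distribution_sum(s),
    dempster = function(s) fuse_dempster(s, 0.1),
    borda = function(s) fuse_rank(s, "borda"),
    highest_rank = function(s) fuse_rank(s, "highest_rank"),
    entropy = function(s) fuse_weighted(s, scheme = "entropy")
  )
  # lowest-index tie-breaking is deliberately not label-equivariant, so only
  # decisive (tie-free) slices are asserted for the integer-scored rules
  decisive <- function(s, name) {
    votes <- apply(s, 2, which.max)
    cnt <- tabulate(votes, 3)
    ranks <- matrix(apply(s, 2, function(col) rank(-col, ties.method = "min") - 1), 3)
    bsum <- rowSums(ranks)
    sorted <- t(apply(ranks, 1, sort))
    o <- do.call(order, as.data.frame(sorted))
    switch(name,
           majority = sum(cnt == max(cnt)) == 1L,
           borda = sum(bsum == min(bsum)) == 1L,
           highest_rank = !identical(sorted[o[1], ], sorted[o[2], ]),
           TRUE)
  }
  checked <- 0L
  for (rep in 1:15) {
    s <- matrix(runif(15, 0.01, 1), 3, 5)
    s <- sweep(s, 2, colSums(s), "/")
    s_perm <- s
    s_perm[perm, ] <- s  # row r moves to position perm[r]
    for (name in names(rules)) {
      if (decisive(s, name)) {
        expect_equal(rules[[name]](s_perm), perm[rules[[name]](s)], label = name)
        checked <- checked + 1L
      }
    }
  }
  expect_gte(checked, 30L)
})

test_that("fuse_predict dispatches every named method on tensors", {
  xi <- rand_soft_tensor(20, 3, 5, seed = 14)
  for (m in c("majority", "dist_sum", "dempster", "borda", "highest_rank",
              "entropy_w")) {
    out <- fuse_predict(xi, m)
    expect_s3_class(out, "factor")
    expect_length(out, 20L)
  }
  out <- fuse_predict(xi, "accuracy_w", weights = c(0.9, 0.7, 0.8, 0.6, 0.75))
  expect_length(out, 20L)
})
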
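test_that("weight initialization is seeded, bounded, and uniform in the mean", {
  w1 <- init_weights(3, 5, seed = 7)
  w2 <- init_weights(3, 5, seed = 7)
  expect_identical(w1, w2)
  expect_equal(dim(w1), c(3L, 5L))
  big <- init_weights(200, 500, seed = 1)  # 1e5 entries
  expect_lte(max(abs(big)), 0.5)
  expect_equal(mean(big), 0, tolerance = 0.01)
})

test_that("the forward pass is the elementwise product of slice and weights", {
  w <- matrix(rnorm(15), 3, 5)
  expect_equal(fuse_forward(matrix(1, 3, 5), w), w)
  # one-hot columns leave activation only at the predicted-class rows
  s <- matrix(0, 3, 5); s[cbind(c(1, 2, 2, 3, 1), 1:5)] <- 1
  f <- fuse_forward(s, w)
  expect_true(all(f[s == 0] == 0))
  # brute-force scalar oracle
  set.seed(8)
  s2 <- matrix(runif(15), 3, 5); w2 <- matrix(rnorm(15), 3, 5)
  f2 <- fuse_forward(s2, w2)
  for (r in 1:3) for (j in 1:5) {
    expect_equal(f2[r, j], s2[r, j] * w2[r, j], tolerance = 1e-12)
  }
  expect_error(fuse_forward(matrix(1, 2, 2), w), "shape")
})

test_that("binarization is strict and monotone in the threshold", {
  expect_equal(fuse_binarize(matrix(c(0.91, 0.9), 1), 0.9), matrix(c(1, 0), 1))
  # fresh weights cannot cross 0.9 with supports in [0,1]
  s <- matrix(runif(15), 3, 5)
  expect_true(all(fuse_binarize(fuse_forward(s, init_weights(3, 5, 1)), 0.9) == 0))
  # delta' > delta never sets more bits
  set.seed(9)
  for (rep in 1:20) {
    f <- matrix(rnorm(12, 0.5, 0.5), 3, 4)
    ds <- sort(runif(2, 0.01, 0.99))
    expect_true(all(fuse_binarize(f, ds[2]) <= fuse_binarize(f, ds[1])))
  }
})

test_that("the instance error compares bits against the broadcast one-hot target", {
  cs <- c("a", "b", "c")
  B0 <- matrix(0, 3, 4)
  E <- fuse_error(B0, "b", cs, sign = "output_minus_target")
  omega <- rbind(rep(0, 4), rep(1, 4), rep(0, 4))
  expect_equal(E, -omega)
  expect_equal(fuse_error(omega, "b", cs, sign = "output_minus_target"), matrix(0, 3, 4))
  expect_equal(fuse_error(B0, "b", cs, sign = "target_minus_output"), omega)
  set.seed(4)
  Br <- matrix(rbinom(12, 1, 0.5), 3, 4)
  expect_true(all(fuse_error(Br, "c", cs) %in% c(-1, 0, 1)))
  expect_error(fuse_error(B0, "z", cs), "unknown class")
})

test_that("the multiplicative update matches its closed form and fixes zeros", {
  expect_equal(fuse_update(0.4, matrix(1), eta = 0.5, mu = 0.2, n = 10),
               matrix(0.404))
  w <- matrix(rnorm(15), 3, 5)
  expect_equal(fuse_update(w, matrix(0, 3, 5), 0.5, 0.2, 7), w)
  w0 <- w; w0[2, 3] <- 0
  expect_equal(fuse_update(w0, matrix(1, 3, 5), 0.9, 0.9, 1)[2, 3], 0)
})

test_that("training is deterministic and matches a hand-rolled single pass", {
  xi <- rand_soft_tensor(30, 3, 4, seed = 5)
  labs <- factor(paste0("c", rep(1:3, 10)), levels = paste0("c", 1:3))
  cfg <- fusion_config(epochs = 5, seed = 2)
  m1 <- train_bitfusion(xi, labs, cfg)
  m2 <- train_bitfusion(xi, labs, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$mse_trace, m2$mse_trace)

  # epochs = 1, n = 1, one-hot slice: hand computation of the whole pass
  s <- matrix(0, 2, 3); s[1, ] <- 1
  xi1 <- support_tensor(array(as.vector(s), c(1, 2, 3)), c("c1", "c2"),
                        mode = "hard")
  cfg1 <- fusion_config(delta = 0.9, eta = 0.5, mu = 0.2, epochs = 1, seed = 3,
                        error_sign = "target_minus_output")
  m <- train_bitfusion(xi1, factor("c1", levels = c("c1", "c2")), cfg1)
  w0 <- init_weights(2, 3, 3)
  f <- s * w0
  B <- (f > 0.9) * 1
  E <- rbind(rep(1, 3), rep(0, 3)) - B
  w_expect <- w0 + (0.5 * 0.2 / 1) * (w0 * E)
  expect_equal(m$weights, w_expect, tolerance = 1e-12)
  expect_equal(m$mse_trace, mean(E^2))
})

test_that("no weight changes sign during training under the default config", {
  sim <- make_synthetic_xi(200, classes = 3, classifiers = 5,
                           base_accuracies = 0.8, seed = 6)
  cfg <- fusion_config(seed = 9)  # eta * mu / n = 0.1 / 200 << 1
  m <- train_bitfusion(sim$xi, sim$labels, cfg)
  w0 <- init_weights(3, 5, 9)
  expect_identical(sign(m$weights), sign(w0))
})

test_that("prediction counts bits and falls back deterministically", {
  # three classes, bit row sums (0, 3, 1) -> class 2
  wt <- matrix(1, 3, 4)
  vals <- array(0, c(1, 3, 4))
  vals[1, 2, 1:3] <- 0.95; vals[1, 3, 4] <- 0.95
  vals[1, 1, ] <- 1 - apply(vals[1, , ], 2, sum)  # normalize columns
  xi <- support_tensor(vals, paste0("c", 1:3))
  pr <- predict(make_model(wt, 0.9), xi)
  expect_equal(as.character(pr$class), "c2")
  expect_equal(as.character(pr$stage), "bit_count")
  expect_equal(pr$bits, 3L)

  # all bits zero: magnitude-weighted support sums decide (stage 2)
  wt2 <- matrix(0.5, 3, 2)
  vals2 <- array(c(0.1, 0.6, 0.3, 0.1, 0.6, 0.3), c(1, 3, 2))
  pr2 <- predict(make_model(wt2, 0.9), support_tensor(vals2, paste0("c", 1:3)))
  expect_equal(as.character(pr2$class), "c2")
  expect_equal(as.character(pr2$stage), "support_sum")

  # zero weights silence both bit and support stages: majority vote decides
  wt3 <- matrix(0, 2, 3)
  vals3 <- array(0, c(1, 2, 3))
  vals3[1, , 1] <- c(1, 0); vals3[1, , 2] <- c(1, 0); vals3[1, , 3] <- c(0, 1)
  pr3 <- predict(make_model(wt3, 0.9), support_tensor(vals3, c("c1", "c2"), mode = "hard"))
  expect_equal(as.character(pr3$class), "c1")
  expect_equal(as.character(pr3$stage), "majority_vote")
})

test_that("fused prediction matches the scalar brute-force oracle exactly", {
  for (case in list(c(2, 3), c(3, 5), c(4, 1), c(5, 7))) {
    p <- case[1]; l <- case[2]
    vals <- rand_xi_values(50, p, l, seed = p * 10 + l)
    wt <- withr::with_seed(p + l, matrix(runif(p * l, -3, 3), p, l))
    delta <- withr::with_seed(p * l, runif(1, 0.05, 0.95))
    xi <- support_tensor(vals, paste0("c", seq_len(p)))
    got <- as.integer(predict(make_model(wt, delta), xi)$class)
    expect_identical(got, oracle_predict(vals, wt, delta),
                     label = sprintf("p=%d l=%d", p, l))
  }
})

test_that("a unanimous hard ensemble is always returned verbatim", {
  withr::with_seed(31, {
    for (rep in 1:50) {
      p <- sample(2:5, 1); l <- sample(1:7, 1)
      cl <- sample(p, 1)
      votes <- matrix(cl, 1, l)
      xi <- hard_tensor_from_votes(votes, p)
      wt <- matrix(runif(p * l, -0.5, 0.5), p, l)
      pr <- predict(make_model(wt, 0.9), xi)
      expect_equal(as.integer(pr$class), cl)
    }
  })
})

test_that("hard-mode fused predictions stay inside the voted classes (closure)", {
  withr::with_seed(17, {
    for (rep in 1:40) {
      p <- sample(2:4, 1); l <- sample(2:6, 1)
      votes <- matrix(sample(p, 10 * l, replace = TRUE), 10, l)
      xi <- hard_tensor_from_votes(votes, p)
      wt <- matrix(runif(p * l, -0.5, 0.5), p, l)
      pr <- predict(make_model(wt, 0.9), xi)
      for (i in 1:10) {
        voted <- unique(votes[i, ])
        expect_true(as.integer(pr$class[i]) %in% voted ||
                      pr$stage[i] == "lowest_index")
      }
    }
  })
})

test_that("the training trace is finite, nonnegative, and model I/O round-trips", {
  sim <- make_synthetic_xi(60, classes = 3, classifiers = 4,
                           base_accuracies = 0.75, seed = 3)
  m <- train_bitfusion(sim$xi, sim$labels, fusion_config(epochs = 20, seed = 5))
  expect_length(m$mse_trace, 20L)
  expect_true(all(is.finite(m$mse_trace)) && all(m$mse_trace >= 0))
  tf <- withr::local_tempfile(fileext = ".json")
  write_fusion_model(m, tf)
  back <- read_fusion_model(tf)
  expect_equal(back$weights, m$weights, tolerance = 1e-12)
  expect_equal(back$config$delta, m$config$delta)
  p1 <- predict(m, sim$xi); p2 <- predict(back, sim$xi)
  expect_identical(p1$class, p2$class)
})

test_that("tidy, glance and autoplot expose the fitted combiner", {
  sim <- make_synthetic_xi(40, classes = 3, classifiers = 4,
                           base_accuracies = 0.8, seed = 2)
  m <- train_bitfusion(sim$xi, sim$labels, fusion_config(epochs = 3, seed = 1))
  td <- tidy(m)
  expect_equal(nrow(td), 12L)
  expect_named(td, c("class", "classifier", "weight"))
  gl <- glance(m)
  expect_equal(gl$n_classifiers, 4L)
  expect_s3_class(autoplot(m), "ggplot")
})
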
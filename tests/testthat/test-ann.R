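test_that("training is deterministic and epochs = 0 returns the initial network", {
  sp <- small_problem()
  cfg <- ann_config(n_input = 8, n_hidden = 3, n_output = 3, seed = 9)
  m1 <- train_ann(sp$X, sp$Y, cfg)
  m2 <- train_ann(sp$X, sp$Y, cfg)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  expect_identical(predict_ann(m1, sp$X), predict_ann(m2, sp$X))
  cfg0 <- ann_config(n_input = 8, n_hidden = 3, n_output = 3, seed = 9, epochs = 0)
  m0 <- train_ann(sp$X, sp$Y, cfg0)
  init <- chemocal:::with_local_seed(9L, list(
    W1 = matrix(stats::runif(8 * 3, -0.5, 0.5) / sqrt(8), 8, 3),
    b1 = stats::runif(3, -0.5, 0.5) / sqrt(8)
  ))
  expect_identical(m0$W1, init$W1)
  expect_identical(m0$b1, init$b1)
  expect_length(m0$rmsec_trace, 0L)
})

test_that("a linear network recovers a linear law and approaches least squares", {
  # y = 2 x, one neuron per layer
  set.seed(3)
  x <- matrix(seq(-1, 1, length.out = 20), 20, 1)
  y <- 2 * x
  cfg <- ann_config(
    n_input = 1, n_hidden = 1, n_output = 1, seed = 4, epochs = 50
  )
  m <- train_ann(x, y, cfg)
  pred <- predict_ann(m, x)
  slope <- cov(pred[, 1], x[, 1]) / var(x[, 1])
  expect_lt(abs(slope - 2) / 2, 0.01)
  # small well-conditioned multivariate problem: trained loss within 5% of
  # the ordinary least-squares loss
  sp <- small_problem(n = 30, p = 5, m = 2, noise = 0.2, seed = 10)
  cfg2 <- ann_config(n_input = 5, n_hidden = 4, n_output = 2, seed = 5)
  m2 <- train_ann(sp$X, sp$Y, cfg2)
  ann_sse <- sum((predict_ann(m2, sp$X) - sp$Y)^2)
  ols_sse <- sum(lm.fit(cbind(1, sp$X), sp$Y)$residuals^2)
  expect_lt(ann_sse, ols_sse * 1.05)
})

test_that("training reduces the error and divergence is reported", {
  sp <- small_problem()
  cfg <- ann_config(n_input = 8, n_hidden = 3, n_output = 3, seed = 1)
  m <- train_ann(sp$X, sp$Y, cfg)
  expect_lt(tail(m$rmsec_trace, 1), m$rmsec_trace[1])
  # gradient descent at an absurd step size diverges with a clear error
  cfg_gd <- ann_config(
    n_input = 8, n_hidden = 3, n_output = 3, seed = 1,
    learning_rate = 1e6, algorithm = "gradient-descent"
  )
  expect_error(train_ann(sp$X, sp$Y, cfg_gd), "epoch")
  expect_error(train_ann(sp$X, sp$Y[1:5, ], cfg), "row counts")
  expect_error(
    train_ann(sp$X, sp$Y, ann_config(n_input = 7, n_output = 3)),
    "dimensions"
  )
})

test_that("prediction is a pure forward pass", {
  sp <- small_problem()
  cfg <- ann_config(n_input = 8, n_hidden = 3, n_output = 3, seed = 2)
  m <- train_ann(sp$X, sp$Y, cfg)
  P <- predict_ann(m, sp$X)
  # permuting samples permutes predictions identically
  perm <- c(4, 1, 12, 3, 2, 11, 5, 10, 6, 9, 7, 8)
  expect_equal(predict_ann(m, sp$X[perm, ]), P[perm, ])
  # a zeroed network maps everything to the inverse-scaled zero
  m$W1[] <- 0; m$b1[] <- 0; m$W2[] <- 0; m$b2[] <- 0
  out <- predict_ann(m, sp$X)
  expect_equal(out, matrix(m$output_scaling$lo, 12, 3, byrow = TRUE),
    ignore_attr = TRUE
  )
  expect_error(predict_ann(m, matrix(0, 1, 7)), "wavelength")
})

test_that("hidden-size scanning reproduces the sharp-drop-then-plateau shape", {
  dat <- study_data(noise_sd = 0.002, seed = 1)
  cal <- dat$split$calibration_rows
  Xc <- fit_center(dat$X[cal, ])$centered
  cfg <- ann_config(n_input = 326, n_output = 4, seed = 3)
  tab <- scan_hidden(Xc, dat$conc[cal, ], sizes = c(2, 3, 4, 5, 8), cfg)
  expect_equal(tab$n_hidden, c(2L, 3L, 4L, 5L, 8L))
  r <- setNames(tab$rmsec, tab$n_hidden)
  expect_lte(r[["5"]], r[["2"]])
  # plateau: the 5 -> 8 change is small against the 2 -> 5 drop
  expect_lt(abs(r[["8"]] - r[["5"]]), r[["2"]] - r[["5"]])
  one <- scan_hidden(Xc, dat$conc[cal, ], sizes = 4, cfg)
  expect_equal(nrow(one), 1L)
})
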
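test_that("NIPALS recovers exact-rank data and matches the pseudoinverse oracle", {
  sp <- small_problem()
  # full-rank fit equals minimum-norm least squares
  m <- fit_pls(sp$X, sp$Y, n_lv = 8)
  oracle <- pinv_fit(sp$X, sp$Y)
  expect_lt(
    max(abs(predict_pls(m, sp$X) - oracle$predict(sp$X))) / max(abs(sp$Y)),
    1e-6
  )
  # rank-2 noiseless data are reproduced exactly with 2 latent variables
  set.seed(5)
  X2 <- matrix(rnorm(24), 12, 2) %*% matrix(rnorm(16), 2, 8)
  Y2 <- X2 %*% matrix(rnorm(24), 8, 3)
  m2 <- fit_pls(X2, Y2, 2)
  expect_lt(max(abs(predict_pls(m2, X2) - Y2)), 1e-8)
  # zero response gives zero coefficients
  m0 <- fit_pls(sp$X, matrix(0, 12, 2), 3)
  expect_equal(max(abs(m0$B)), 0)
  expect_equal(max(abs(predict_pls(m0, sp$X))), 0)
  expect_error(fit_pls(sp$X, sp$Y, 20), "between 1 and")
  expect_error(fit_pls(sp$X * NA, sp$Y, 2), "finite")
})

test_that("scores are orthogonal and RMSEC is non-increasing in model size", {
  sp <- small_problem()
  m <- fit_pls(sp$X, sp$Y, 8)
  G <- crossprod(m$T)
  norms <- sqrt(diag(G))
  off <- abs(G - diag(diag(G))) / outer(norms, norms)
  expect_lt(max(off), 1e-8)
  r <- vapply(1:8, function(h) mean(rmsec(m, sp$X, sp$Y, n_lv = h)), numeric(1))
  expect_true(all(diff(r) <= 1e-10))
})

test_that("rmsec reproduces hand-computable cases", {
  sp <- small_problem(noise = 0)
  m <- fit_pls(sp$X, sp$Y, 8)
  expect_lt(max(rmsec(m, sp$X, sp$Y)), 1e-8)
  # a constant shift of delta in Y gives RMSEC |delta| at unchanged model
  delta <- 0.3
  expect_equal(
    unname(rmsec(m, sp$X, sp$Y + delta)),
    rep(delta, 3),
    tolerance = 1e-7
  )
})

test_that("leave-one-out cross-validation separates model sizes on synthetic mixtures", {
  dat <- study_data(noise_sd = 0)
  cal <- dat$split$calibration_rows
  Xc <- fit_center(dat$X[cal, ])$centered
  cv <- loo_cv(Xc, dat$conc[cal, ], max_lv = 6)
  expect_length(cv$per_lv_rmsecv, 6L)
  # noiseless four-component data: four latent variables beat one by >= 10x
  expect_lt(cv$per_lv_rmsecv[4] * 10, cv$per_lv_rmsecv[1])
  # constant response cross-validates to zero error at every size
  Yconst <- matrix(5, length(cal), 2)
  cv0 <- loo_cv(Xc, Yconst, max_lv = 3)
  expect_equal(cv0$per_lv_rmsecv, rep(0, 3))
  expect_error(loo_cv(Xc[1:2, ], dat$conc[cal, ][1:2, ], 1), "at least 3")
})

test_that("the F-test rule picks the most parsimonious adequate model", {
  # flat tail from 3 latent variables onwards
  cv <- list(per_lv_press = c(50, 10, 1.00, 0.99, 0.985), n = 14)
  expect_equal(select_n_lv(cv), 3L)
  expect_equal(select_n_lv(list(per_lv_press = c(1, 2, 3), n = 14)), 1L)
  expect_equal(select_n_lv(list(per_lv_press = rep(2, 5), n = 14)), 1L)
  expect_equal(select_n_lv(list(per_lv_press = rep(0, 4), n = 14)), 1L)
  expect_error(select_n_lv(list(per_lv_press = numeric(0), n = 14)), "empty")
})

test_that("predictions are linear and centre-consistent", {
  sp <- small_problem()
  m <- fit_pls(sp$X, sp$Y, 4)
  expect_equal(
    drop(predict_pls(m, m$x_means)),
    unname(m$y_means)
  )
  # linearity of the coefficient matrix around the centre
  v <- rnorm(8)
  p1 <- drop(predict_pls(m, m$x_means + v)) - m$y_means
  p2 <- drop(predict_pls(m, m$x_means + 2 * v)) - m$y_means
  expect_equal(2 * p1, p2, tolerance = 1e-10)
  expect_error(predict_pls(m, matrix(0, 1, 5)), "wavelength")
})
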
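test_that("purest-sample initial estimates find orthogonal sources", {
  # two orthogonal non-negative spectra in a noiseless two-source data set
  s1 <- c(1, 1, 0, 0, 0, 0)
  s2 <- c(0, 0, 0, 1, 1, 1)
  C <- cbind(c(2, 0.2, 1), c(0.1, 2, 1))
  D <- C %*% rbind(s1, s2)
  S0 <- initial_spectra(D, 2)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  best <- sapply(list(s1, s2), function(s) {
    max(apply(S0, 2, cosine, b = s))
  })
  expect_true(all(best >= 0.99))
  # a single component is the maximum-norm sample direction
  one <- initial_spectra(D, 1)
  expect_equal(drop(one), D[which.max(sqrt(rowSums(D^2))), ])
  # duplicated samples do not change the selection
  S0dup <- initial_spectra(D[c(1, 1, 2, 2, 3, 3), ], 2)
  expect_equal(unname(S0dup), unname(S0))
  expect_error(initial_spectra(D, 7), "between")
})

test_that("an exact one-component factorisation converges immediately", {
  c1 <- c(1, 2, 3, 4)
  s1 <- c(0.5, 1, 0.25)
  D <- c1 %*% t(s1)
  fit <- fit_mcr(D, matrix(s1, 3, 1), mcr_config())
  expect_lt(fit$lof, 1e-10)
  expect_true(fit$converged)
  expect_gte(fit$r2, 100 - 1e-10)
  # max_iter = 1 performs exactly one iteration
  fit1 <- fit_mcr(D, matrix(s1, 3, 1), mcr_config(max_iter = 1))
  expect_equal(fit1$n_iter, 1L)
})

test_that("constrained ALS recovers the four mixture components without noise", {
  dat <- study_data(noise_sd = 0)
  S_true <- pure_matrix()
  fit <- fit_mcr(dat$X, S_true, mcr_config(tol = 1e-8, max_iter = 100))
  expect_lt(fit$lof, 0.1)
  expect_true(all(fit$C >= 0))
  expect_true(all(fit$S >= 0))
  expect_true(all(diff(fit$lof_trace) <= 1e-9))
  sim <- spectral_similarity(fit$S, S_true)
  expect_true(all(sim >= 0.999))
  # contributions proportional to the true concentrations
  for (j in 1:4) {
    expect_gte(cor(fit$C[, j], dat$conc[, j]), 0.999)
  }
})

test_that("lack of fit and explained variance follow their definitions", {
  expect_error(lack_of_fit(matrix(0, 2, 2), matrix(1, 2, 1), matrix(1, 2, 1)), "zero")
  D <- diag(2)
  C <- matrix(c(1, 0), 2, 1)
  S <- matrix(c(1, 0), 2, 1)
  out <- lack_of_fit(D, C, S) # model reproduces only D[1,1]
  expect_equal(out$lof, 100 * sqrt(1 / 2))
  # exact reconstruction and null reconstruction
  set.seed(8)
  C2 <- matrix(runif(6), 3, 2)
  S2 <- matrix(runif(8), 4, 2)
  D2 <- C2 %*% t(S2)
  exact <- lack_of_fit(D2, C2, S2)
  expect_equal(exact$lof, 0)
  expect_equal(exact$r2, 100)
  null <- lack_of_fit(D2, 0 * C2, S2)
  expect_equal(null$lof, 100)
  expect_equal(null$r2, 0)
  # identity r2 = 100 - lof^2 / 100 on random mismatched factors
  rnd <- lack_of_fit(D2, C2 + 0.3, S2)
  expect_equal(rnd$r2, 100 - rnd$lof^2 / 100, tolerance = 1e-12)
})

test_that("quantification inverts the calibration line exactly for affine contributions", {
  conc <- matrix(c(1, 2, 3, 4, 5, 2, 4, 6, 8, 10), 5, 2)
  fake <- structure(
    list(C = cbind(3 * conc[, 1] + 1, 0.5 * conc[, 2] - 0.2)),
    class = "mcr_fit"
  )
  pred <- quantify_mcr(fake, calibration_rows = c(1, 2, 4), conc[c(1, 2, 4), ])
  expect_equal(unname(pred), unname(conc[c(3, 5), ]), tolerance = 1e-12)
  # proportional contributions are the special case with zero intercept
  fake2 <- structure(list(C = 2 * conc), class = "mcr_fit")
  pred2 <- quantify_mcr(fake2, c(1, 3, 5), conc[c(1, 3, 5), ])
  expect_equal(unname(pred2), unname(conc[c(2, 4), ]), tolerance = 1e-12)
  degen <- structure(list(C = matrix(1, 5, 2)), class = "mcr_fit")
  expect_error(quantify_mcr(degen, c(1, 2, 3), conc[1:3, ]), "degenerate")
})

test_that("noiseless quantification of the simulated design recovers 100 +/- 1 percent", {
  dat <- study_data(noise_sd = 0)
  fit <- fit_mcr(dat$X, pure_matrix(), mcr_config(tol = 1e-8, max_iter = 100))
  pred <- quantify_mcr(fit, dat$split$calibration_rows,
    dat$conc[dat$split$calibration_rows, ])
  rec <- 100 * pred / dat$conc[dat$split$validation_rows, ]
  expect_true(all(abs(rec - 100) <= 1))
})

test_that("spectral similarity is a matched scale-invariant cosine", {
  S <- pure_matrix()
  expect_equal(as.numeric(spectral_similarity(S, S)), rep(1, 4), tolerance = 1e-12)
  expect_equal(as.numeric(spectral_similarity(3 * S, S)), rep(1, 4), tolerance = 1e-12)
  A <- cbind(c(1, 0, 0), c(0, 1, 0))
  B <- cbind(c(0, 0, 1), c(0, 1, 0))
  sim <- spectral_similarity(A, B)
  expect_equal(as.numeric(sim), c(0, 1))
  # permuted columns are re-matched
  sim_perm <- spectral_similarity(S[, c(3, 1, 4, 2)], S)
  expect_equal(as.numeric(sim_perm), rep(1, 4), tolerance = 1e-12)
  expect_error(spectral_similarity(S[, 1:2] * 0, S[, 1:2]), "zero")
})

test_that("rank collapse is reported, not silently dropped", {
  s1 <- c(1, 1, 0)
  D <- matrix(rep(s1, 4), 4, 3, byrow = TRUE)
  S0 <- cbind(s1, c(0, 0, 1)) # second component absent from the data
  expect_error(
    fit_mcr(D, S0, mcr_config()),
    "rank collapse"
  )
})
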
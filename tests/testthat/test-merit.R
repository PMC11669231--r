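test_that("recovery and its summary match hand arithmetic and the printed example", {
  expect_equal(recovery_percent(7.0, 7.0), 100)
  expect_equal(recovery_percent(1.0, 2.0), 50)
  expect_equal(round(recovery_percent(6.8782, 7.0), 2), 98.26)
  expect_error(recovery_percent(1, 0), "positive")
  s <- summarize_recoveries(c(99, 101))
  expect_equal(s$mean, 100)
  expect_equal(s$sd, sqrt(2))
  const <- summarize_recoveries(rep(101.3, 5))
  expect_equal(const$sd, 0)
  expect_equal(const$rsd, 0)
  expect_error(summarize_recoveries(100), "at least two")
})

test_that("bias, SEP and RMSEP follow the error decomposition", {
  y <- c(5, 6, 7, 8)
  expect_equal(
    bias_sep_rmsep(y, y)[c("bias", "sep", "rmsep")],
    list(bias = 0, sep = 0, rmsep = 0)
  )
  # a pure shift: all error is bias
  shifted <- bias_sep_rmsep(y, y - 0.25)
  expect_equal(shifted$bias, 0.25)
  expect_equal(shifted$sep, 0)
  expect_equal(shifted$rmsep, 0.25)
  # brute-force recomputation on random data
  set.seed(31)
  for (i in 1:5) {
    a <- runif(9, 1, 10)
    p <- a + rnorm(9, sd = 0.3)
    out <- bias_sep_rmsep(a, p)
    e <- numeric(9)
    for (j in 1:9) e[j] <- a[j] - p[j]
    b <- sum(e) / 9
    expect_equal(out$bias, b)
    expect_equal(out$sep, sqrt(sum((e - b)^2) / 8))
    expect_equal(out$rmsep, sqrt(sum(e^2) / 9))
    # algebraic identity linking the three
    expect_equal(out$rmsep^2, out$bias^2 + out$sep^2 * 8 / 9,
      tolerance = 1e-10
    )
  }
  expect_error(bias_sep_rmsep(1, 1), "at least two")
})

test_that("the found-versus-actual line reproduces exact relationships", {
  a <- c(1, 2, 3, 4, 5)
  ident <- regression_found_vs_actual(a, a)
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0)
  expect_equal(ident$r, 1)
  lin <- regression_found_vs_actual(a, 2 * a + 1)
  expect_equal(lin$slope, 2)
  expect_equal(lin$intercept, 1)
  expect_equal(lin$r, 1)
  expect_equal(lin$sigma_resid, 0)
  expect_error(regression_found_vs_actual(rep(2, 4), a[1:4]), "variance")
  expect_error(regression_found_vs_actual(a[1:2], a[1:2]), "three")
})

test_that("detection limits scale as 3.3 and 10 sigma over slope", {
  out <- lod_loq(1, 1)
  expect_equal(out$lod, 3.3)
  expect_equal(out$loq, 10)
  expect_equal(lod_loq(0, 2), list(lod = 0, loq = 0))
  expect_equal(lod_loq(0.06, 1.2)$lod, 0.165)
  expect_equal(lod_loq(0.37, 0.9)$loq, (10 / 3.3) * lod_loq(0.37, 0.9)$lod)
  expect_error(lod_loq(1, 0), "positive")
  expect_error(lod_loq(-1, 1), "non-negative")
})

test_that("merit_report bundles consistent statistics", {
  set.seed(12)
  a <- runif(11, 1, 9)
  p <- a * (1 + rnorm(11, sd = 0.01))
  r <- merit_report(a, p, "ANT")
  expect_equal(r$rsd, 100 * r$sd / r$mean)
  expect_equal(r$loq, (10 / 3.3) * r$lod)
  expect_equal(r$n, 11L)
  tab <- merit_table(list(r))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$rmsep, r$rmsep)
})

test_that("standard addition reports total-found over total-nominal", {
  expect_equal(standard_addition(3, 3, 6)$recoveries, 100)
  expect_equal(standard_addition(3, 1.5, 4.5)$recoveries, 100)
  exact <- standard_addition(3, c(1.5, 3, 6), c(4.5, 6, 9))
  expect_equal(exact$sd, 0)
  expect_equal(exact$mean, 100)
  expect_error(standard_addition(3, c(0, 1), c(3, 4)), "positive")
})
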
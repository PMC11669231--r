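test_that("wavelength grids have the right point counts and fail on bad input", {
  expect_equal(wavelength_grid(250, 315, 0.2)$points, 326L)
  expect_equal(wavelength_grid(250, 250.2, 0.2)$points, 2L)
  expect_equal(wavelength_grid(200, 400, 0.2)$points, 1001L)
  g <- wavelength_grid(250, 315, 0.2)
  expect_true(all(diff(g$wavelengths) > 0))
  expect_equal(length(g$wavelengths), g$points)
  expect_error(wavelength_grid(250, 315, -0.2), "positive")
  expect_error(wavelength_grid(315, 250, 0.2), "exceed")
  expect_error(wavelength_grid(250, 315, 0.3), "evenly")
})

test_that("default pure spectra are non-negative, overlapping and collinear where intended", {
  g <- default_grid()
  pure <- default_pure_spectra(g)
  expect_named(pure, c("ANT", "BEN", "ANT_impA", "PABA"))
  S <- pure_matrix(g)
  expect_true(all(S >= 0))
  expect_equal(nrow(S), 326L)
  # antipyrine and its impurity are nearly collinear
  expect_gte(cor(S[, "ANT"], S[, "ANT_impA"]), 0.90)
  # every component keeps at least half its integrated absorbance inside
  # the union of the others' supports (support = above 1% of peak)
  for (k in seq_len(ncol(S))) {
    others <- S[, -k, drop = FALSE]
    support <- rowSums(sweep(others, 2, 0.01 * apply(others, 2, max), `>`)) > 0
    expect_gte(sum(S[support, k]) / sum(S[, k]), 0.5)
  }
  # each spectrum equals the sum of its band contributions at its maximum
  for (p in pure) {
    i <- which.max(p$absorptivity)
    wl <- g$wavelengths[i]
    manual <- sum(vapply(
      p$bands,
      function(b) b$amplitude * exp(-0.5 * ((wl - b$center_nm) / b$width_nm)^2),
      numeric(1)
    ))
    expect_equal(p$absorptivity[i], manual)
  }
  expect_error(default_pure_spectra(wavelength_grid(150, 315, 0.5)), "200-400")
})

test_that("simulation obeys Beer-Lambert additivity and homogeneity", {
  g <- default_grid()
  pure <- default_pure_spectra(g)
  quiet <- noise_model(0)
  zero <- concentration_matrix(matrix(0, 2, 4))
  expect_equal(simulate_spectra(zero, pure, quiet)$absorbance,
    matrix(0, 2, g$points),
    ignore_attr = TRUE
  )
  # unit concentration of one component reproduces its absorptivity
  unit <- concentration_matrix(matrix(c(0, 1, 0, 0), 1, 4))
  expect_equal(
    drop(simulate_spectra(unit, pure, quiet)$absorbance),
    pure$BEN$absorptivity
  )
  set.seed(7)
  c1 <- concentration_matrix(matrix(runif(12, 0, 2), 3, 4))
  c2 <- concentration_matrix(matrix(runif(12, 0, 2), 3, 4))
  a1 <- simulate_spectra(c1, pure, quiet)$absorbance
  a2 <- simulate_spectra(c2, pure, quiet)$absorbance
  a12 <- simulate_spectra(concentration_matrix(unclass(c1) + unclass(c2)), pure, quiet)$absorbance
  expect_equal(a1 + a2, a12, tolerance = 1e-12)
  # homogeneity: simulate(k C) = k simulate(C)
  k <- 1.7
  ak <- simulate_spectra(concentration_matrix(k * unclass(c1)), pure, quiet)$absorbance
  expect_equal(ak, k * a1, tolerance = 1e-12)
  expect_error(
    simulate_spectra(matrix(1, 1, 3), pure, quiet),
    "match"
  )
})

test_that("noise is reproducible, has the stated sd, and large absorbances warn", {
  g <- default_grid()
  pure <- default_pure_spectra(g)
  conc <- concentration_matrix(matrix(rep(c(7, 3, 1.5, 0.75), each = 40), 40, 4))
  n1 <- simulate_spectra(conc, pure, noise_model(0.002, seed = 11))
  n2 <- simulate_spectra(conc, pure, noise_model(0.002, seed = 11))
  expect_identical(n1$absorbance, n2$absorbance)
  clean <- simulate_spectra(conc, pure, noise_model(0))
  resid <- n1$absorbance - clean$absorbance
  expect_gt(length(resid), 1e4)
  expect_lt(abs(sd(resid) - 0.002) / 0.002, 0.05)
  big <- concentration_matrix(matrix(c(30, 10, 3, 2), 1, 4))
  expect_warning(simulate_spectra(big, pure, noise_model(0)), "1.5")
})

test_that("spectra and concentration CSV round-trips preserve the data", {
  g <- wavelength_grid(250, 260, 0.5)
  pure <- default_pure_spectra(g)
  conc <- concentration_matrix(matrix(c(5, 1, 0.5, 0.25, 9, 5, 2.5, 1.25), 2, 4, byrow = TRUE))
  sp <- simulate_spectra(conc, pure, noise_model(0.001, seed = 3))
  f <- tempfile(fileext = ".csv")
  write_spectra_csv(sp, f)
  back <- read_spectra_csv(f)
  expect_equal(back$absorbance, sp$absorbance, tolerance = 1e-12)
  expect_equal(back$grid$wavelengths, g$wavelengths)
  f2 <- tempfile(fileext = ".csv")
  write_concentrations_csv(conc, f2)
  expect_equal(unclass(read_concentrations_csv(f2)), unclass(conc),
    ignore_attr = TRUE
  )
})
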
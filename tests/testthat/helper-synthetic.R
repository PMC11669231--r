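# Shared synthetic fixtures, built in code at test time.

default_grid <- function() wavelength_grid(250, 315, 0.2)

# pure absorptivity matrix (wavelengths x 4) on the default grid
pure_matrix <- function(grid = default_grid()) {
  vapply(
    default_pure_spectra(grid), `[[`, numeric(grid$points), "absorptivity"
  )
}

# the standard simulated study data set: design concentrations, spectra at
# a given noise level, and the 14/11 split
study_data <- function(noise_sd = 0.002, seed = 1) {
  design <- brereton_design(5, 4)
  conc <- map_design(design)
  split <- split_design(design)
  spectra <- simulate_spectra(
    conc, default_pure_spectra(default_grid()),
    noise_model(noise_sd, seed = seed)
  )
  list(
    design = design, conc = unclass(conc), split = split,
    X = spectra$absorbance
  )
}

# small random regression problem for PLS/ANN oracles
small_problem <- function(n = 12, p = 8, m = 3, noise = 0.01, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  B <- matrix(rnorm(p * m), p, m)
  Y <- X %*% B + noise * matrix(rnorm(n * m), n, m)
  list(X = X, Y = Y)
}

# independent pseudoinverse least-squares oracle (SVD-based, no reuse of
# package code)
pinv_fit <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  s <- svd(Xc)
  pos <- s$d > max(dim(Xc)) * .Machine$double.eps * s$d[1]
  B <- s$v[, pos, drop = FALSE] %*%
    ((1 / s$d[pos]) * (t(s$u[, pos, drop = FALSE]) %*% Yc))
  list(
    predict = function(Xn) {
      sweep(sweep(Xn, 2, colMeans(X)) %*% B, 2, colMeans(Y), `+`)
    },
    B = B
  )
}

table2_recoveries <- function(component, model) {
  rec <- validation_set_recoveries()
  rec[rec$component == component & rec$model == model, , drop = FALSE]
}
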
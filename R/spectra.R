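#' Evenly spaced wavelength grid
#'
#' Builds the inclusive wavelength axis on which all spectra in the package
#' live. The default working window for the quaternary mixture problem is
#' 250.0--315.0 nm sampled every 0.2 nm (326 points): below 250 nm the
#' instrument response is noise-dominated and above 315 nm the four analytes
#' are essentially transparent.
#'
#' @param start_nm first wavelength (nm).
#' @param end_nm last wavelength (nm); must exceed `start_nm`.
#' @param step_nm increment (nm); must divide the span evenly.
#'
#' @return An object of class `wavelength_grid`: a list with `start_nm`,
#'   `end_nm`, `step_nm`, `points` and the numeric `wavelengths` vector.
#' @examples
#' g <- wavelength_grid(250, 315, 0.2)
#' g$points # 326
#' @export
wavelength_grid <- function(start_nm = 250, end_nm = 315, step_nm = 0.2) {
  if (!is.finite(step_nm) || step_nm <= 0) {
    stop("`step_nm` must be positive", call. = FALSE)
  }
  if (!is.finite(start_nm) || !is.finite(end_nm) || end_nm <= start_nm) {
    stop("`end_nm` must exceed `start_nm`", call. = FALSE)
  }
  span <- (end_nm - start_nm) / step_nm
  if (abs(span - round(span)) > 1e-6) {
    stop("`step_nm` does not divide the wavelength span evenly", call. = FALSE)
  }
  points <- as.integer(round(span)) + 1L
  structure(
    list(
      start_nm = start_nm, end_nm = end_nm, step_nm = step_nm,
      points = points,
      wavelengths = start_nm + step_nm * (seq_len(points) - 1)
    ),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %.1f-%.1f nm, step %.3g nm, %d points\n",
    x$start_nm, x$end_nm, x$step_nm, x$points
  ))
  invisible(x)
}

#' Gaussian absorption band
#'
#' One Gaussian component of a pure-analyte UV absorptivity curve:
#' `amplitude * exp(-((wl - center)^2) / (2 * width^2))`, with amplitude in
#' absorbance units per microgram per mL.
#'
#' @param center_nm band centre (nm).
#' @param width_nm Gaussian standard deviation (nm), > 0.
#' @param amplitude peak absorptivity, >= 0.
#' @return A `gaussian_band` list.
#' @export
gaussian_band <- function(center_nm, width_nm, amplitude) {
  if (!is.finite(width_nm) || width_nm <= 0) {
    stop("band `width_nm` must be positive", call. = FALSE)
  }
  if (!is.finite(amplitude) || amplitude < 0) {
    stop("band `amplitude` must be non-negative", call. = FALSE)
  }
  structure(
    list(center_nm = center_nm, width_nm = width_nm, amplitude = amplitude),
    class = "gaussian_band"
  )
}

#' Pure-component spectrum from Gaussian bands
#'
#' Evaluates the sum of Gaussian bands on a wavelength grid, giving the
#' absorptivity (absorbance per microgram per mL at 1 cm path) of a single
#' analyte.
#'
#' @param name analyte label.
#' @param bands list of [gaussian_band()] objects.
#' @param grid a [wavelength_grid()].
#' @return A `pure_spectrum`: list with `name`, `bands`, `grid` and the
#'   non-negative `absorptivity` vector (one value per grid point).
#' @export
pure_spectrum <- function(name, bands, grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (length(bands) == 0) stop("at least one band is required", call. = FALSE)
  wl <- grid$wavelengths
  a <- numeric(length(wl))
  for (b in bands) {
    a <- a + b$amplitude * exp(-0.5 * ((wl - b$center_nm) / b$width_nm)^2)
  }
  structure(
    list(name = name, bands = bands, grid = grid, absorptivity = a),
    class = "pure_spectrum"
  )
}

# Band parameterisation of the four emulated analyte spectra. These are
# documented constants of the simulator, chosen so that (i) all four curves
# overlap heavily across 250-315 nm, (ii) antipyrine and its impurity A are
# nearly collinear (Pearson r > 0.9), and (iii) a 9 ug/mL antipyrine +
# 5 ug/mL benzocaine mixture stays near but below 1.5 AU. They are not
# fitted molar absorptivities.
.default_band_table <- function() {
  list(
    ANT = list(
      gaussian_band(263, 10.5, 0.098),
      gaussian_band(287, 13.0, 0.020)
    ),
    BEN = list(
      gaussian_band(286, 9.0, 0.150),
      gaussian_band(261, 10.0, 0.035)
    ),
    ANT_impA = list(
      gaussian_band(269, 13.0, 0.105),
      gaussian_band(253, 5.0, 0.040)
    ),
    PABA = list(
      gaussian_band(275, 8.5, 0.115),
      gaussian_band(296, 11.0, 0.014)
    )
  )
}

#' Default pure spectra of the four analytes
#'
#' Synthetic stand-ins for the (unpublished) measured pure spectra of
#' antipyrine (ANT), benzocaine (BEN), antipyrine impurity A (ANT_impA) and
#' p-aminobenzoic acid (PABA). The four curves overlap strongly over the
#' working window and ANT / ANT_impA are nearly collinear, which is the
#' feature that makes the quaternary mixture hard for univariate methods.
#'
#' @param grid a [wavelength_grid()] lying inside 200--400 nm.
#' @return Named list of four [pure_spectrum()] objects, in the fixed
#'   component order ANT, BEN, ANT_impA, PABA.
#' @export
default_pure_spectra <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (grid$start_nm < 200 || grid$end_nm > 400) {
    stop("default spectra are parameterised for grids inside 200-400 nm",
      call. = FALSE
    )
  }
  bands <- .default_band_table()
  out <- lapply(names(bands), function(nm) pure_spectrum(nm, bands[[nm]], grid))
  names(out) <- names(bands)
  out
}

#' Component order used throughout the package
#' @return Character vector `c("ANT", "BEN", "ANT_impA", "PABA")`.
#' @export
component_names <- function() c("ANT", "BEN", "ANT_impA", "PABA")

#' Concentration matrix constructor
#'
#' @param values numeric matrix, samples x components, in ug/mL; all
#'   values must be non-negative.
#' @param components component labels (defaults to [component_names()]).
#' @return A `concentration_matrix` (a plain matrix with column names and a
#'   class attribute).
#' @export
concentration_matrix <- function(values, components = component_names()) {
  values <- as.matrix(values)
  if (ncol(values) != length(components)) {
    stop("column count does not match component labels", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("concentrations must be finite and non-negative", call. = FALSE)
  }
  colnames(values) <- components
  structure(values, class = c("concentration_matrix", "matrix", "array"))
}

#' Additive instrumental noise model
#'
#' Homoscedastic Gaussian absorbance noise. The default standard deviation,
#' 0.002 AU, is a typical photometric repeatability figure for a bench-top
#' double-beam UV spectrophotometer.
#'
#' @param additive_sd noise standard deviation in absorbance units, >= 0.
#' @param seed integer RNG seed; fixing it makes simulations bit-reproducible.
#' @return A `noise_model` list.
#' @export
noise_model <- function(additive_sd = 0.002, seed = 1L) {
  if (!is.finite(additive_sd) || additive_sd < 0) {
    stop("`additive_sd` must be non-negative", call. = FALSE)
  }
  structure(
    list(additive_sd = additive_sd, seed = as.integer(seed)),
    class = "noise_model"
  )
}

# evaluate an expression with a locally seeded RNG, restoring global state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate mixture spectra by Beer-Lambert additivity
#'
#' Builds `A = C %*% t(S) + E`, where `C` holds concentrations (ug/mL), `S`
#' the pure-component absorptivities and `E` additive Gaussian noise. A
#' warning is raised if any simulated absorbance exceeds 1.5 AU, the level
#' at which the real instrument response becomes unreliable and which
#' motivated the restricted concentration ranges of the calibration design.
#'
#' @param conc a [concentration_matrix()] (or coercible matrix), samples x
#'   components.
#' @param pure list of [pure_spectrum()] objects sharing one grid, one per
#'   concentration column.
#' @param noise a [noise_model()]; `additive_sd = 0` gives noiseless spectra.
#' @return A `spectra_matrix`: list with `grid`, `absorbance` (samples x
#'   wavelengths) and `sample_ids`.
#' @export
simulate_spectra <- function(conc, pure, noise = noise_model()) {
  conc <- as.matrix(conc)
  if (ncol(conc) != length(pure)) {
    stop("number of components in `conc` must match number of pure spectra",
      call. = FALSE
    )
  }
  grid <- pure[[1]]$grid
  S <- vapply(pure, function(p) {
    if (!identical(p$grid$wavelengths, grid$wavelengths)) {
      stop("all pure spectra must share one wavelength grid", call. = FALSE)
    }
    p$absorptivity
  }, numeric(grid$points))
  A <- conc %*% t(S)
  if (noise$additive_sd > 0) {
    E <- with_local_seed(
      noise$seed,
      matrix(stats::rnorm(length(A), sd = noise$additive_sd), nrow(A), ncol(A))
    )
    A <- A + E
  }
  if (any(A > 1.5)) {
    warning("simulated absorbance exceeds 1.5 AU; outside the reliable ",
      "photometric range of the emulated instrument",
      call. = FALSE
    )
  }
  ids <- rownames(conc)
  if (is.null(ids)) ids <- paste0("sample_", seq_len(nrow(A)))
  structure(
    list(grid = grid, absorbance = A, sample_ids = ids),
    class = "spectra_matrix"
  )
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf(
    "<spectra_matrix> %d samples x %d wavelengths (%.1f-%.1f nm)\n",
    nrow(x$absorbance), ncol(x$absorbance), x$grid$start_nm, x$grid$end_nm
  ))
  invisible(x)
}

#' Write / read spectra as delimited text
#'
#' The on-disk dialect is a plain CSV with the wavelength axis in the first
#' column and one column per sample, headed by the sample ids.
#'
#' @param spectra a `spectra_matrix`.
#' @param path file path.
#' @return `write_spectra_csv` returns `path` invisibly; `read_spectra_csv`
#'   returns a `spectra_matrix`.
#' @export
write_spectra_csv <- function(spectra, path) {
  df <- data.frame(
    wavelength_nm = spectra$grid$wavelengths,
    t(spectra$absorbance),
    check.names = FALSE
  )
  colnames(df) <- c("wavelength_nm", spectra$sample_ids)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wl <- df[[1]]
  step <- stats::median(diff(wl))
  grid <- wavelength_grid(wl[1], wl[length(wl)], step)
  A <- t(as.matrix(df[, -1, drop = FALSE]))
  structure(
    list(grid = grid, absorbance = unname(A), sample_ids = colnames(df)[-1]),
    class = "spectra_matrix"
  )
}

#' Write / read concentration tables as CSV
#'
#' One row per sample, one column per component (ug/mL), in the fixed
#' ANT, BEN, ANT_impA, PABA order.
#'
#' @param conc a [concentration_matrix()].
#' @param path file path.
#' @export
write_concentrations_csv <- function(conc, path) {
  utils::write.csv(as.data.frame(unclass(conc)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_concentrations_csv
#' @export
read_concentrations_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  concentration_matrix(as.matrix(df), components = colnames(df))
}
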
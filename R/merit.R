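#' Prediction recovery
#'
#' `100 * predicted / actual`, the standard accuracy measure for an
#' external validation mixture.
#'
#' @param predicted predicted concentration(s), ug/mL.
#' @param actual true concentration(s), ug/mL; must be strictly positive.
#' @return Recovery in percent (vectorised).
#' @export
recovery_percent <- function(predicted, actual) {
  if (any(actual <= 0)) {
    stop("`actual` concentrations must be strictly positive", call. = FALSE)
  }
  100 * predicted / actual
}

#' Mean, SD and RSD of a recovery vector
#'
#' Sample standard deviation (n - 1 denominator); `rsd = 100 * sd / mean`.
#'
#' @param recoveries numeric vector of recoveries (%), length >= 2.
#' @return List with `mean`, `sd`, `rsd` and `n`.
#' @export
summarize_recoveries <- function(recoveries) {
  n <- length(recoveries)
  if (n < 2) stop("at least two recoveries are needed for an SD", call. = FALSE)
  m <- mean(recoveries)
  s <- stats::sd(recoveries)
  list(mean = m, sd = s, rsd = 100 * s / m, n = n)
}

#' Bias, SEP and RMSEP of a prediction set
#'
#' With errors `e = actual - predicted`:
#' `bias = mean(e)`, `SEP = sqrt(sum((e - bias)^2) / (n - 1))` and
#' `RMSEP = sqrt(sum(e^2) / n)`, which are linked by the identity
#' `RMSEP^2 = bias^2 + SEP^2 * (n - 1) / n`.
#'
#' @param actual,predicted concentration vectors of equal length >= 2.
#' @return List with `bias`, `sep`, `rmsep` and `n`.
#' @export
bias_sep_rmsep <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("`actual` and `predicted` lengths differ", call. = FALSE)
  }
  n <- length(actual)
  if (n < 2) stop("at least two samples are required", call. = FALSE)
  e <- actual - predicted
  bias <- mean(e)
  list(
    bias = bias,
    sep = sqrt(sum((e - bias)^2) / (n - 1)),
    rmsep = sqrt(sum(e^2) / n),
    n = n
  )
}

#' Found-versus-actual straight line
#'
#' Ordinary least squares of predicted on actual concentration, plus the
#' Pearson correlation -- the linearity diagnostics reported per component
#' for an external validation set.
#'
#' @param actual,predicted concentration vectors, length >= 3, with
#'   non-degenerate `actual`.
#' @return List with `slope`, `intercept`, `r` and `sigma_resid` (the
#'   residual standard deviation of the line, n - 2 denominator).
#' @export
regression_found_vs_actual <- function(actual, predicted) {
  if (length(actual) < 3) stop("at least three samples required", call. = FALSE)
  if (stats::var(actual) <= 0) {
    stop("`actual` has zero variance", call. = FALSE)
  }
  slope <- stats::cov(actual, predicted) / stats::var(actual)
  intercept <- mean(predicted) - slope * mean(actual)
  resid <- predicted - (intercept + slope * actual)
  list(
    slope = slope,
    intercept = intercept,
    r = stats::cor(actual, predicted),
    sigma_resid = sqrt(sum(resid^2) / (length(actual) - 2))
  )
}

#' Detection and quantification limits
#'
#' `LOD = 3.3 * sigma / slope`, `LOQ = 10 * sigma / slope`, with `sigma` a
#' response standard deviation and `slope` the found-versus-actual
#' calibration slope. The package convention takes `sigma` as the residual
#' standard deviation of the found-versus-actual line (see
#' [merit_report()]); other conventions can be fed in directly.
#'
#' @param sigma response standard deviation (>= 0).
#' @param slope calibration slope (> 0).
#' @return List with `lod` and `loq` (ug/mL); `loq = (10 / 3.3) * lod`.
#' @export
lod_loq <- function(sigma, slope) {
  if (slope <= 0) stop("`slope` must be positive", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be non-negative", call. = FALSE)
  list(lod = 3.3 * sigma / slope, loq = 10 * sigma / slope)
}

#' Full figures-of-merit report for one component
#'
#' Bundles every validation statistic reported per analyte: the individual
#' recoveries with their mean/SD/RSD, the found-versus-actual line, bias,
#' SEP, RMSEP and the LOD/LOQ derived from the regression residual
#' standard deviation.
#'
#' @param actual,predicted validation concentrations, ug/mL.
#' @param component analyte label.
#' @return A `merit_report` list.
#' @export
merit_report <- function(actual, predicted, component = "component") {
  rec <- recovery_percent(predicted, actual)
  summ <- summarize_recoveries(rec)
  err <- bias_sep_rmsep(actual, predicted)
  reg <- regression_found_vs_actual(actual, predicted)
  lim <- lod_loq(reg$sigma_resid, reg$slope)
  structure(
    list(
      component = component, n = summ$n,
      recoveries = rec, mean = summ$mean, sd = summ$sd, rsd = summ$rsd,
      slope = reg$slope, intercept = reg$intercept, r = reg$r,
      bias = err$bias, sep = err$sep, rmsep = err$rmsep,
      lod = lim$lod, loq = lim$loq
    ),
    class = "merit_report"
  )
}

#' @export
print.merit_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<merit_report> %s (n = %d)\n",
      "  recovery %% : %.2f +/- %.3f (RSD %.3f)\n",
      "  line       : slope %.4f, intercept %.4f, r %.4f\n",
      "  errors     : bias %.5f, SEP %.6f, RMSEP %.6f\n",
      "  limits     : LOD %.3f, LOQ %.3f ug/mL\n"
    ),
    x$component, x$n, x$mean, x$sd, x$rsd,
    x$slope, x$intercept, x$r, x$bias, x$sep, x$rmsep, x$lod, x$loq
  ))
  invisible(x)
}

#' Merit reports as a flat table
#'
#' @param reports list of `merit_report` objects (possibly nested by model).
#' @return `data.frame` with one row per report, mirroring the usual
#'   validation-table column order.
#' @export
merit_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    data.frame(
      component = r$component, slope = r$slope, intercept = r$intercept,
      r = r$r, lod = r$lod, loq = r$loq, sep = r$sep, rmsep = r$rmsep,
      mean_recovery = r$mean, sd_recovery = r$sd, rsd = r$rsd
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Standard-addition recoveries
#'
#' For each spike level, `recovery = 100 * found / (taken + added)`: the
#' total found amount against the total nominal amount in the spiked
#' sample.
#'
#' @param taken analyte already present (ug/mL), one value.
#' @param added spike levels (ug/mL), all > 0.
#' @param found total concentrations recovered by the model at each level.
#' @return List with the per-level `recoveries`, their `mean` and `sd`.
#' @export
standard_addition <- function(taken, added, found) {
  if (any(added <= 0)) stop("`added` spikes must be positive", call. = FALSE)
  if (length(added) != length(found)) {
    stop("`added` and `found` lengths differ", call. = FALSE)
  }
  rec <- 100 * found / (taken + added)
  list(
    recoveries = rec,
    mean = mean(rec),
    sd = if (length(rec) >= 2) stats::sd(rec) else NA_real_
  )
}
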
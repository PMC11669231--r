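#' Summary statistics for a method-comparison group
#'
#' @param mean group mean (e.g. mean recovery, %).
#' @param sd sample standard deviation (>= 0).
#' @param n group size (>= 2).
#' @return A `summary_stats` list (`mean`, `sd`, `var`, `n`).
#' @export
summary_stats <- function(mean, sd, n) {
  if (n < 2) stop("`n` must be at least 2", call. = FALSE)
  if (sd < 0) stop("`sd` must be non-negative", call. = FALSE)
  structure(
    list(mean = mean, sd = sd, var = sd^2, n = as.integer(n)),
    class = "summary_stats"
  )
}

#' Summary statistics from raw recoveries
#'
#' @param recoveries numeric vector, length >= 2.
#' @return A [summary_stats()] object.
#' @export
from_recoveries <- function(recoveries) {
  if (length(recoveries) < 2) {
    stop("at least two recoveries are required", call. = FALSE)
  }
  summary_stats(mean(recoveries), stats::sd(recoveries), length(recoveries))
}

#' Pooled-variance two-sample Student's t test
#'
#' The classical equal-variance comparison of two method means:
#' `t = |m1 - m2| / sqrt(sp2 * (1/n1 + 1/n2))` with the pooled variance
#' `sp2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`, reported together
#' with the two-tailed 5% critical value at `n1 + n2 - 2` degrees of
#' freedom. Pooling (rather than Welch's correction) matches the tabulated
#' critical values conventionally quoted alongside such comparisons.
#'
#' @param a,b [summary_stats()] for the two groups.
#' @return List with `t` (absolute value), `df` and `t_crit` (two-tailed,
#'   p = 0.05).
#' @export
pooled_t_test <- function(a, b) {
  df <- a$n + b$n - 2L
  sp2 <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / df
  if (sp2 <= 0) {
    if (a$mean == b$mean) {
      return(list(t = 0, df = df, t_crit = stats::qt(0.975, df)))
    }
    stop("zero pooled variance with unequal means", call. = FALSE)
  }
  tval <- abs(a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  list(t = tval, df = df, t_crit = stats::qt(0.975, df))
}

#' Variance-ratio F test
#'
#' `F = larger variance / smaller variance`, with numerator and
#' denominator degrees of freedom `n - 1` of the corresponding groups and
#' the upper 5% critical value.
#'
#' @param a,b [summary_stats()] for the two groups; both SDs must be
#'   positive.
#' @return List with `F`, `df` (length-2 vector, numerator first) and
#'   `F_crit` (upper tail, p = 0.05).
#' @export
variance_f_test <- function(a, b) {
  if (a$sd <= 0 || b$sd <= 0) {
    stop("both groups need a positive variance", call. = FALSE)
  }
  if (a$var >= b$var) {
    num <- a
    den <- b
  } else {
    num <- b
    den <- a
  }
  df <- c(num$n - 1L, den$n - 1L)
  list(
    F = num$var / den$var,
    df = df,
    F_crit = stats::qf(0.95, df[1], df[2])
  )
}
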
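#' Mean-centre a matrix and keep the centring parameters
#'
#' Column mean-centring is the sole spectral preprocessing used throughout
#' the calibration workflow. The fitted column means are retained so that
#' prediction-time data can be centred with the *training* means rather
#' than re-estimated ones.
#'
#' @param X numeric matrix with at least one row.
#' @return A list with `centered` (the centred matrix) and `model`
#'   (a `centering_model` holding `column_means`).
#' @examples
#' fc <- fit_center(matrix(1:6, 3, 2))
#' colMeans(fc$centered) # ~0
#' @export
fit_center <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 1) stop("`X` must have at least one row", call. = FALSE)
  mu <- colMeans(X)
  structure(
    list(
      centered = sweep(X, 2, mu),
      model = structure(list(column_means = mu), class = "centering_model")
    ),
    class = "centering_fit"
  )
}

#' Apply stored centring to new data
#'
#' Subtracts the training column means; never re-estimates them.
#'
#' @param model a `centering_model` from [fit_center()].
#' @param X_new matrix (or vector treated as one row) with matching columns.
#' @return The centred matrix.
#' @export
apply_center <- function(model, X_new) {
  if (is.null(dim(X_new))) X_new <- matrix(X_new, nrow = 1)
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$column_means)) {
    stop("column count does not match the centring model", call. = FALSE)
  }
  sweep(X_new, 2, model$column_means)
}
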
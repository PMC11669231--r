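#' Fit a PLS2 regression by NIPALS
#'
#' Classical NIPALS partial least squares relating a spectral block `X`
#' (samples x wavelengths) to a concentration block `Y` (samples x
#' components), all components modelled jointly. Scores `T` and loadings
#' `P`, `Q` satisfy `X = T P' + E` and `Y = T Q' + F` on the centred data,
#' with `X` and `Y` deflated by each extracted latent variable; the
#' regression matrix `B = W (P'W)^-1 Q'` reproduces [predict_pls()].
#'
#' @param X numeric matrix of predictors (spectra), samples x wavelengths.
#' @param Y numeric matrix (or vector) of responses, samples x components.
#' @param n_lv number of latent variables, at most `min(nrow(X) - 1, ncol(X))`.
#' @param center centre both blocks (the standard preprocessing here);
#'   disable only for already-centred data.
#' @param tol,max_iter inner NIPALS convergence control for the score
#'   direction (relevant when `Y` has several columns).
#' @return A `pls_model` with elements `n_lv`, `x_means`, `y_means`, `W`,
#'   `P`, `Q`, `T` and `B`.
#' @export
fit_pls <- function(X, Y, n_lv, center = TRUE, tol = 1e-10, max_iter = 500) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y row counts differ", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(Y))) {
    stop("X and Y must be finite", call. = FALSE)
  }
  n <- nrow(X)
  p <- ncol(X)
  m <- ncol(Y)
  n_lv <- as.integer(n_lv)
  max_rank <- min(n - 1L, p)
  if (n_lv < 1L || n_lv > max_rank) {
    stop("`n_lv` must be between 1 and min(nrow - 1, ncol) = ", max_rank,
      call. = FALSE
    )
  }
  x_means <- if (center) colMeans(X) else numeric(p)
  y_means <- if (center) colMeans(Y) else numeric(m)
  Xc <- sweep(X, 2, x_means)
  Yc <- sweep(Y, 2, y_means)

  W <- matrix(0, p, n_lv)
  P <- matrix(0, p, n_lv)
  Q <- matrix(0, m, n_lv)
  Tm <- matrix(0, n, n_lv)
  eps <- 1e-300
  for (h in seq_len(n_lv)) {
    if (sum(Yc^2) <= 1e-28 * max(1, sum(Y^2)) || sum(Xc^2) <= eps) break
    u <- Yc[, which.max(colSums(Yc^2)), drop = TRUE]
    w <- numeric(p)
    t_sc <- numeric(n)
    q <- numeric(m)
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xc, u) / sum(u^2)
      wn <- sqrt(sum(w^2))
      if (wn <= eps) break
      w <- w / wn
      t_sc <- drop(Xc %*% w)
      q <- drop(crossprod(Yc, t_sc)) / sum(t_sc^2)
      u <- drop(Yc %*% q) / sum(q^2)
      if (sqrt(sum((t_sc - t_old)^2)) <= tol * sqrt(sum(t_sc^2))) break
      t_old <- t_sc
    }
    if (sqrt(sum(w^2)) <= eps || sum(t_sc^2) <= eps) break
    p_load <- drop(crossprod(Xc, t_sc)) / sum(t_sc^2)
    W[, h] <- w
    P[, h] <- p_load
    Q[, h] <- q
    Tm[, h] <- t_sc
    Xc <- Xc - tcrossprod(t_sc, p_load)
    Yc <- Yc - tcrossprod(t_sc, q)
  }
  model <- structure(
    list(
      n_lv = n_lv, x_means = x_means, y_means = y_means,
      W = W, P = P, Q = Q, T = Tm,
      component_names = colnames(Y)
    ),
    class = "pls_model"
  )
  model$B <- .pls_coefficients(model, n_lv)
  model
}

# regression coefficients from the first h latent variables
.pls_coefficients <- function(model, h) {
  keep <- which(colSums(model$T^2) > 0)
  keep <- keep[keep <= h]
  if (length(keep) == 0) {
    return(matrix(0, length(model$x_means), length(model$y_means)))
  }
  W <- model$W[, keep, drop = FALSE]
  P <- model$P[, keep, drop = FALSE]
  Q <- model$Q[, keep, drop = FALSE]
  W %*% solve(crossprod(P, W), t(Q))
}

#' Predict concentrations from spectra with a fitted PLS model
#'
#' @param model a `pls_model` from [fit_pls()].
#' @param X_new matrix of new spectra (or a single spectrum vector).
#' @param n_lv number of latent variables to use (default: all fitted).
#' @return Matrix of predicted responses, samples x components.
#' @export
predict_pls <- function(model, X_new, n_lv = model$n_lv) {
  if (is.null(dim(X_new))) X_new <- matrix(X_new, nrow = 1)
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$x_means)) {
    stop("wavelength count does not match the fitted model", call. = FALSE)
  }
  if (n_lv < 1 || n_lv > model$n_lv) {
    stop("`n_lv` must be between 1 and the fitted number of latent variables",
      call. = FALSE
    )
  }
  B <- if (n_lv == model$n_lv) model$B else .pls_coefficients(model, n_lv)
  Yhat <- sweep(X_new, 2, model$x_means) %*% B
  Yhat <- sweep(Yhat, 2, model$y_means, `+`)
  colnames(Yhat) <- model$component_names
  Yhat
}

#' Root mean square error of calibration
#'
#' `sqrt(sum(residual^2) / n)` per component, on the data used to fit the
#' model (or any labelled data set).
#'
#' @param model a `pls_model`.
#' @param X,Y the spectra and reference concentrations to evaluate on.
#' @param n_lv number of latent variables to use.
#' @return Named numeric vector, one RMSEC per component.
#' @export
rmsec <- function(model, X, Y, n_lv = model$n_lv) {
  Y <- as.matrix(Y)
  R <- Y - predict_pls(model, X, n_lv = n_lv)
  out <- sqrt(colMeans(R^2))
  names(out) <- colnames(Y)
  out
}

#' Leave-one-out cross-validation over latent variables
#'
#' Refits the model with each single sample held out and predicts it, for
#' every latent-variable count up to `max_lv`. PRESS is pooled over all
#' response components; `rmsecv = sqrt(PRESS / n)`.
#'
#' @param X,Y calibration spectra and concentrations (>= 3 samples).
#' @param max_lv largest number of latent variables to assess; capped at
#'   `min(n - 2, ncol(X))` so every leave-one-out fit is feasible.
#' @return A `pls_cv` list: `per_lv_press`, `per_lv_rmsecv`, `selected_lv`
#'   (by [select_n_lv()] with its default threshold), and `n`.
#' @export
loo_cv <- function(X, Y, max_lv) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 3) stop("leave-one-out needs at least 3 samples", call. = FALSE)
  max_lv <- as.integer(max_lv)
  feasible <- min(n - 2L, ncol(X))
  if (max_lv < 1L || max_lv > feasible) {
    stop("`max_lv` must be between 1 and ", feasible, call. = FALSE)
  }
  press <- numeric(max_lv)
  for (i in seq_len(n)) {
    fit <- fit_pls(X[-i, , drop = FALSE], Y[-i, , drop = FALSE], max_lv)
    for (h in seq_len(max_lv)) {
      e <- Y[i, ] - drop(predict_pls(fit, X[i, , drop = FALSE], n_lv = h))
      press[h] <- press[h] + sum(e^2)
    }
  }
  cv <- structure(
    list(
      per_lv_press = press,
      per_lv_rmsecv = sqrt(press / n),
      n = n
    ),
    class = "pls_cv"
  )
  cv$selected_lv <- select_n_lv(cv)
  cv
}

#' F-test selection of the number of latent variables
#'
#' Haaland--Thomas rule: among all model sizes, pick the smallest `h` whose
#' `PRESS(h) / min(PRESS)` ratio stays below the F quantile at probability
#' `alpha` (degrees of freedom `n`, `n`), i.e. the most parsimonious model
#' not significantly worse than the PRESS minimiser. Ties resolve to the
#' smaller `h`.
#'
#' @param cv a `pls_cv` from [loo_cv()], or any list with `per_lv_press`
#'   and `n`.
#' @param alpha F probability threshold; 0.75 is the conventional choice in
#'   multivariate calibration.
#' @return Selected number of latent variables (integer).
#' @export
select_n_lv <- function(cv, alpha = 0.75) {
  press <- cv$per_lv_press
  if (length(press) == 0) stop("empty PRESS vector", call. = FALSE)
  thr <- stats::qf(alpha, cv$n, cv$n)
  ok <- press <= thr * min(press) + 1e-300
  as.integer(which(ok)[1])
}
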
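#' MCR-ALS configuration
#'
#' Controls for the constrained alternating-least-squares factorisation
#' `D = C S' + E`. Defaults mirror routine usage on UV mixture data:
#' non-negativity on both factors, unit-length normalisation of the
#' resolved spectra (which fixes the intensity ambiguity of the bilinear
#' model), convergence when the lack of fit changes by less than 0.1%
#' (relative) between iterations, and at most 50 iterations.
#'
#' @param max_iter maximum ALS iterations (>= 1).
#' @param tol convergence threshold: relative change of the lack-of-fit
#'   percentage between successive iterations, in percent.
#' @param nonneg_C,nonneg_S enforce non-negative contributions / spectra.
#' @param upper_bound_C optional per-component upper bound on the
#'   contributions (applied by projection after each C update). Bounds are
#'   expressed in the units `C` actually carries, so they are only
#'   meaningful with `s_normalization = FALSE` and an initial `S` on the
#'   true absorptivity scale.
#' @param s_normalization rescale each resolved spectrum to unit length
#'   after every iteration (contributions rescaled inversely).
#' @param nonneg_method `"nnls"` for exact non-negative least squares
#'   (the default), `"clip"` for the fast clipped-least-squares fallback.
#' @return An `mcr_config` list.
#' @export
mcr_config <- function(max_iter = 50, tol = 0.1, nonneg_C = TRUE,
                       nonneg_S = TRUE, upper_bound_C = NULL,
                       s_normalization = TRUE,
                       nonneg_method = c("nnls", "clip")) {
  nonneg_method <- match.arg(nonneg_method)
  stopifnot(max_iter >= 1, tol > 0)
  if (!is.null(upper_bound_C) && any(upper_bound_C <= 0)) {
    stop("`upper_bound_C` entries must be positive", call. = FALSE)
  }
  structure(
    list(
      max_iter = as.integer(max_iter), tol = tol,
      nonneg_C = nonneg_C, nonneg_S = nonneg_S,
      upper_bound_C = upper_bound_C, s_normalization = s_normalization,
      nonneg_method = nonneg_method
    ),
    class = "mcr_config"
  )
}

#' Purest-sample initial spectral estimates
#'
#' Greedy determinant criterion in the spirit of SIMPLISMA, applied to the
#' sample direction: the first estimate is the largest-norm spectrum in
#' `D`; each further estimate is the row whose direction maximises the Gram
#' determinant (i.e. is most dissimilar) with the rows already chosen.
#' Selection depends only on row directions, so duplicated samples do not
#' change the result.
#'
#' @param D data matrix, samples x wavelengths.
#' @param n_components number of components to initialise.
#' @return Matrix of initial spectra, wavelengths x `n_components` (the
#'   selected rows of `D`, transposed).
#' @export
initial_spectra <- function(D, n_components) {
  D <- as.matrix(D)
  n_components <- as.integer(n_components)
  if (n_components < 1 || n_components > min(dim(D))) {
    stop("`n_components` must be between 1 and min(dim(D))", call. = FALSE)
  }
  norms <- sqrt(rowSums(D^2))
  if (all(norms == 0)) stop("`D` is all zero", call. = FALSE)
  U <- D / pmax(norms, .Machine$double.eps) # unit row directions
  chosen <- which.max(norms)
  while (length(chosen) < n_components) {
    best <- -Inf
    best_i <- NA_integer_
    for (i in seq_len(nrow(D))[-chosen]) {
      G <- tcrossprod(U[c(chosen, i), , drop = FALSE])
      d <- det(G)
      if (d > best + 1e-15) {
        best <- d
        best_i <- i
      }
    }
    chosen <- c(chosen, best_i)
  }
  S0 <- t(D[chosen, , drop = FALSE])
  colnames(S0) <- paste0("component_", seq_len(n_components))
  S0
}

# least-squares solve of min ||A x - b|| per column of B, optionally
# non-negative
.solve_block <- function(A, B, nonneg, method) {
  if (!nonneg) {
    return(qr.solve(A, B))
  }
  if (method == "nnls") {
    out <- apply(B, 2, function(b) pracma::lsqnonneg(A, b)$x)
    matrix(out, ncol(A), ncol(B))
  } else {
    pmax(qr.solve(A, B), 0)
  }
}

#' Lack of fit and explained variance of a bilinear model
#'
#' `lof = 100 * sqrt(sum((D - C S')^2) / sum(D^2))` and
#' `r2 = 100 * (1 - sum((D - C S')^2) / sum(D^2))`, so `r2 = 100 - lof^2 / 100`.
#'
#' @param D data matrix, samples x wavelengths.
#' @param C contributions, samples x components.
#' @param S spectra, wavelengths x components.
#' @return List with `lof` and `r2`, both in percent.
#' @export
lack_of_fit <- function(D, C, S) {
  D <- as.matrix(D)
  ss_tot <- sum(D^2)
  if (ss_tot == 0) stop("`D` is all zero", call. = FALSE)
  ss_res <- sum((D - tcrossprod(as.matrix(C), as.matrix(S)))^2)
  list(lof = 100 * sqrt(ss_res / ss_tot), r2 = 100 * (1 - ss_res / ss_tot))
}

#' Constrained alternating least squares
#'
#' Alternates the two conditional least-squares problems of the bilinear
#' model: contributions `C` given spectra `S` (with non-negativity and, if
#' configured, per-component upper bounds) and `S` given `C` (with
#' non-negativity), until the lack of fit stabilises or `max_iter` is
#' reached. With the exact NNLS solver and no upper bounds the lack-of-fit
#' trace is monotone non-increasing.
#'
#' @param D data matrix, samples x wavelengths (raw absorbances; the
#'   non-negativity constraints presuppose uncentred data).
#' @param initial_S starting spectra, wavelengths x components.
#' @param config an [mcr_config()].
#' @return An `mcr_fit`: `C`, `S`, `lof_trace`, `lof`, `r2`, `n_iter`,
#'   `converged`.
#' @export
fit_mcr <- function(D, initial_S, config = mcr_config()) {
  D <- as.matrix(D)
  S <- as.matrix(initial_S)
  if (nrow(S) != ncol(D)) {
    stop("`initial_S` must have one row per wavelength of `D`", call. = FALSE)
  }
  if (config$nonneg_S && any(S < 0)) {
    stop("`initial_S` must be non-negative under the spectral ",
      "non-negativity constraint",
      call. = FALSE
    )
  }
  k <- ncol(S)
  bounds <- config$upper_bound_C
  if (!is.null(bounds) && length(bounds) != k) {
    stop("`upper_bound_C` must have one entry per component", call. = FALSE)
  }
  lof_trace <- numeric(0)
  lof_prev <- Inf
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(config$max_iter)) {
    n_iter <- it
    # C given S (rows of D are independent problems)
    C <- t(.solve_block(S, t(D), config$nonneg_C, config$nonneg_method))
    if (!is.null(bounds)) {
      C <- pmin(C, matrix(bounds, nrow(C), k, byrow = TRUE))
    }
    dead <- colSums(abs(C)) == 0
    if (any(dead)) {
      stop(
        "rank collapse: component(s) ",
        paste(which(dead), collapse = ", "),
        " have an all-zero contribution profile", call. = FALSE
      )
    }
    # S given C (columns of D are independent problems)
    S <- t(.solve_block(C, D, config$nonneg_S, config$nonneg_method))
    fitq <- lack_of_fit(D, C, S)
    lof_trace <- c(lof_trace, fitq$lof)
    if (config$s_normalization) {
      len <- sqrt(colSums(S^2))
      len[len == 0] <- 1
      S <- sweep(S, 2, len, `/`)
      C <- sweep(C, 2, len, `*`)
    }
    if (is.finite(lof_prev)) {
      rel <- if (lof_prev > 0) 100 * abs(lof_prev - fitq$lof) / lof_prev else 0
      if (rel < config$tol || fitq$lof == 0) {
        converged <- TRUE
        break
      }
    } else if (fitq$lof == 0) {
      converged <- TRUE
      break
    }
    lof_prev <- fitq$lof
  }
  structure(
    list(
      C = C, S = S, lof_trace = lof_trace,
      lof = lof_trace[length(lof_trace)],
      r2 = 100 - lof_trace[length(lof_trace)]^2 / 100,
      n_iter = n_iter, converged = converged
    ),
    class = "mcr_fit"
  )
}

#' Quantify unknown samples from resolved contributions
#'
#' The bilinear factorisation recovers contributions only up to an affine
#' calibration per component, so quantification goes through a straight
#' line fitted on samples of known concentration: per component,
#' `contribution = a * concentration + b` is estimated on the calibration
#' rows and inverted on the remaining rows.
#'
#' @param result an `mcr_fit`.
#' @param calibration_rows indices (into the rows of `result$C`) of the
#'   samples with known concentrations.
#' @param known_conc matrix of known concentrations for those rows,
#'   in the same component order as `result$C`.
#' @return Matrix of predicted concentrations for the rows *not* in
#'   `calibration_rows`.
#' @export
quantify_mcr <- function(result, calibration_rows, known_conc) {
  C <- result$C
  calibration_rows <- as.integer(calibration_rows)
  if (min(calibration_rows) < 1 || max(calibration_rows) > nrow(C)) {
    stop("`calibration_rows` out of range", call. = FALSE)
  }
  known_conc <- as.matrix(known_conc)
  if (nrow(known_conc) != length(calibration_rows) ||
    ncol(known_conc) != ncol(C)) {
    stop("`known_conc` must be calibration rows x components", call. = FALSE)
  }
  other <- setdiff(seq_len(nrow(C)), calibration_rows)
  pred <- matrix(NA_real_, length(other), ncol(C))
  for (j in seq_len(ncol(C))) {
    x <- known_conc[, j]
    y <- C[calibration_rows, j]
    if (stats::var(y) <= 0 || stats::var(x) <= 0) {
      stop("degenerate calibration regression for component ", j,
        call. = FALSE
      )
    }
    a <- stats::cov(x, y) / stats::var(x)
    b <- mean(y) - a * mean(x)
    if (abs(a) <= .Machine$double.eps) {
      stop("zero-slope calibration regression for component ", j,
        call. = FALSE
      )
    }
    pred[, j] <- (C[other, j] - b) / a
  }
  colnames(pred) <- colnames(known_conc)
  rownames(pred) <- rownames(C)[other]
  pred
}

#' Cosine similarity between resolved and reference spectra
#'
#' Components are matched by the assignment (over column permutations)
#' that maximises the total cosine similarity, then the per-component
#' cosines are reported in the reference column order. Cosine similarity
#' is scale-invariant, which is the right yardstick for spectra recovered
#' only up to intensity.
#'
#' @param resolved_S,reference_S matrices, wavelengths x components, on a
#'   shared grid.
#' @return Named numeric vector of cosines in `[-1, 1]`, one per reference
#'   component, with the matched resolved column as an attribute
#'   `"assignment"`.
#' @export
spectral_similarity <- function(resolved_S, reference_S) {
  A <- as.matrix(resolved_S)
  B <- as.matrix(reference_S)
  if (nrow(A) != nrow(B) || ncol(A) != ncol(B)) {
    stop("spectra matrices must share dimensions", call. = FALSE)
  }
  na <- sqrt(colSums(A^2))
  nb <- sqrt(colSums(B^2))
  if (any(na == 0) || any(nb == 0)) {
    stop("zero spectrum encountered", call. = FALSE)
  }
  cosmat <- crossprod(A, B) / outer(na, nb) # resolved x reference
  perms <- .permutations(ncol(B))
  scores <- vapply(
    perms,
    function(p) sum(cosmat[cbind(p, seq_along(p))]),
    numeric(1)
  )
  best <- perms[[which.max(scores)]]
  out <- cosmat[cbind(best, seq_along(best))]
  names(out) <- colnames(B)
  attr(out, "assignment") <- best
  out
}

.permutations <- function(n) {
  if (n == 1) {
    return(list(1L))
  }
  sub <- .permutations(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  lapply(out, as.integer)
}
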
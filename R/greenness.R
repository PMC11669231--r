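#' Analytical Eco-scale penalty item
#'
#' One itemised deduction in the Eco-scale greenness assessment: a
#' reagent, the instrument's energy draw, an occupational hazard, or
#' generated waste, with its penalty points.
#'
#' @param label free-text description (e.g. `"distilled water"`).
#' @param category one of `"reagent"`, `"instrument_energy"`,
#'   `"occupational_hazard"`, `"waste"`.
#' @param points non-negative integer penalty.
#' @return A `penalty_item` list.
#' @export
penalty_item <- function(label,
                         category = c(
                           "reagent", "instrument_energy",
                           "occupational_hazard", "waste"
                         ),
                         points) {
  category <- match.arg(category)
  if (!is.finite(points) || points < 0 || points != round(points)) {
    stop("`points` must be a non-negative integer", call. = FALSE)
  }
  structure(
    list(label = label, category = category, points = as.integer(points)),
    class = "penalty_item"
  )
}

#' Analytical Eco-scale score
#'
#' `score = 100 - sum(penalty points)`. A score above 75 marks an
#' excellent green method, 50--75 an acceptable green method, and below 50
#' an inadequate one (the conventional Eco-scale tiers).
#'
#' @param items list of [penalty_item()] objects (possibly empty).
#' @return An `eco_scale_result`: `total_penalty`, `score`,
#'   `classification`.
#' @export
eco_scale <- function(items) {
  pts <- vapply(items, function(it) {
    if (!inherits(it, "penalty_item")) {
      stop("all items must be `penalty_item` objects", call. = FALSE)
    }
    it$points
  }, integer(1))
  total <- sum(pts)
  score <- 100L - total
  classification <- if (score > 75) {
    "excellent green"
  } else if (score >= 50) {
    "acceptable green"
  } else {
    "inadequate green"
  }
  structure(
    list(
      total_penalty = total, score = score,
      classification = classification
    ),
    class = "eco_scale_result"
  )
}

#' @export
print.eco_scale_result <- function(x, ...) {
  cat(sprintf(
    "<eco_scale> total penalty %d, score %d (%s)\n",
    x$total_penalty, x$score, x$classification
  ))
  invisible(x)
}

#' Read penalty items from a CSV file
#'
#' Expected columns: `method`, `label`, `category`, `points`. The shipped
#' fixture `eco_scale_items.csv` itemises the water-based chemometric
#' method alongside the two earlier single-analyte methods it is compared
#' against (an ethanolic PLS assay and a dilute-HCl PLS/PCR assay).
#'
#' @param path CSV path; defaults to the shipped item table.
#' @param method optional method name to filter on.
#' @return List of [penalty_item()] objects (named by label), or, when
#'   `method` is `NULL`, a list of such lists keyed by method.
#' @export
read_penalty_items <- function(path = system.file("extdata", "eco_scale_items.csv",
                                 package = "chemocal"
                               ),
                               method = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  make <- function(sub) {
    items <- Map(penalty_item, sub$label, sub$category, points = sub$points)
    names(items) <- sub$label
    items
  }
  if (!is.null(method)) {
    sub <- df[df$method == method, , drop = FALSE]
    if (nrow(sub) == 0) stop("unknown method: ", method, call. = FALSE)
    return(make(sub))
  }
  lapply(split(df, df$method), make)
}
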
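# Cyclic generator for the five-level design. The design is the centre run
# (all factors at level 0) followed by the 24 cyclic width-4 windows of this
# sequence, so successive factor columns are one-step rotations of each
# other. The sequence is balanced (each non-zero level five times, zero four
# times -- the centre run supplies the fifth zero per column) and all lag
# 1..3 circular autocorrelations are exactly zero, which makes every pair of
# coded factor columns exactly orthogonal.
.generator_five <- c(
  -2, -2, 0, 1, -2, 1, -1, -1, 0, -2, -1, -2,
  2, 2, 0, -1, 2, -1, 1, 1, 0, 2, 1, 2
)

# Deterministic Eulerian-circuit generator for other odd level counts:
# walk the complete level digraph (loops included, except the 0 -> 0 loop,
# which the centre run provides), always taking the smallest unused
# successor. Yields a cyclic sequence of length n_levels^2 - 1 in which
# every ordered level pair occurs exactly once, so adjacent factor columns
# are exactly orthogonal and each column is balanced.
.generator_eulerian <- function(n_levels) {
  half <- (n_levels - 1L) %/% 2L
  levels <- seq.int(-half, half)
  unused <- matrix(TRUE, n_levels, n_levels) # unused[from, to], 1-based
  idx <- function(l) l + half + 1L
  unused[idx(0L), idx(0L)] <- FALSE
  # Hierholzer with a stack, smallest-successor-first
  stack <- integer(0)
  circuit <- integer(0)
  v <- idx(0L)
  repeat {
    nxt <- which(unused[v, ])
    if (length(nxt) > 0) {
      unused[v, nxt[1]] <- FALSE
      stack <- c(stack, v)
      v <- nxt[1]
    } else {
      circuit <- c(circuit, v)
      if (length(stack) == 0) break
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
    }
  }
  # circuit is the closed walk in reverse; drop the repeated endpoint
  seqv <- rev(circuit)[-1]
  levels[seqv]
}

#' Brereton-style multilevel calibration design
#'
#' Generates the coded `n_levels^2`-run design used to lay out calibration
#' mixtures: one centre run with every factor at level 0, plus the cyclic
#' windows of a balanced generator sequence, so that each factor column
#' contains every coded level exactly `n_levels` times, all runs are
#' distinct, and coded columns are mutually orthogonal (exactly so for the
#' shipped five-level generator).
#'
#' @param n_levels odd number of concentration levels per factor, >= 3.
#' @param n_factors number of factors (components), at most `n_levels - 1`.
#' @return A `coded_design`: integer matrix of coded levels in
#'   `-(n_levels-1)/2 ... +(n_levels-1)/2`, runs x factors.
#' @examples
#' d <- brereton_design(5, 4)
#' dim(d) # 25 x 4
#' colSums(d == 2) # each level appears 5 times per column
#' @export
brereton_design <- function(n_levels = 5, n_factors = 4) {
  n_levels <- as.integer(n_levels)
  n_factors <- as.integer(n_factors)
  if (n_levels < 3 || n_levels %% 2L == 0L) {
    stop("`n_levels` must be an odd integer >= 3", call. = FALSE)
  }
  if (n_factors < 1 || n_factors > n_levels - 1L) {
    stop("`n_factors` must be between 1 and n_levels - 1", call. = FALSE)
  }
  g <- as.integer(
    if (n_levels == 5L) .generator_five else .generator_eulerian(n_levels)
  )
  n <- length(g) # n_levels^2 - 1
  rows <- t(vapply(
    seq_len(n),
    function(p) g[((p - 1L + seq_len(n_factors) - 1L) %% n) + 1L],
    integer(n_factors)
  ))
  design <- rbind(matrix(0L, 1L, n_factors), rows)
  colnames(design) <- paste0("factor_", seq_len(n_factors))
  rownames(design) <- paste0("run_", seq_len(nrow(design)))
  structure(design, class = c("coded_design", "matrix", "array"))
}

#' Factor specification: coded level to concentration mapping
#'
#' @param name component label.
#' @param center concentration at coded level 0 (ug/mL).
#' @param step concentration increment per coded level (ug/mL).
#' @param max_level largest absolute coded level that will be mapped
#'   (2 for a five-level design); `center - max_level * step` must stay
#'   positive so that all mapped concentrations are physical.
#' @return A `factor_spec` list.
#' @export
factor_spec <- function(name, center, step, max_level = 2) {
  if (center - max_level * step <= 0) {
    stop("`center - max_level * step` must be positive for ", name,
      call. = FALSE
    )
  }
  structure(
    list(name = name, center = center, step = step),
    class = "factor_spec"
  )
}

#' Default factor specifications for the quaternary mixture
#'
#' Centres and steps reproducing the calibrated ranges 5.0--9.0 (ANT),
#' 1.0--5.0 (BEN), 0.5--2.5 (ANT_impA) and 0.25--1.25 (PABA) ug/mL over
#' coded levels -2..+2.
#'
#' @return Named list of four [factor_spec()] objects.
#' @export
default_factor_specs <- function() {
  list(
    ANT = factor_spec("ANT", 7.0, 1.0),
    BEN = factor_spec("BEN", 3.0, 1.0),
    ANT_impA = factor_spec("ANT_impA", 1.5, 0.5),
    PABA = factor_spec("PABA", 0.75, 0.25)
  )
}

#' Map a coded design to concentrations
#'
#' `concentration = center + level * step`, per factor.
#'
#' @param coded a [brereton_design()] matrix.
#' @param specs list of [factor_spec()], one per design column.
#' @return A [concentration_matrix()] in ug/mL.
#' @export
map_design <- function(coded, specs = default_factor_specs()) {
  if (ncol(coded) != length(specs)) {
    stop("one factor spec is required per design column", call. = FALSE)
  }
  centers <- vapply(specs, `[[`, numeric(1), "center")
  steps <- vapply(specs, `[[`, numeric(1), "step")
  values <- sweep(
    sweep(unclass(coded) + 0, 2, steps, `*`),
    2, centers, `+`
  )
  rownames(values) <- rownames(coded)
  concentration_matrix(values, components = vapply(specs, `[[`, character(1), "name"))
}

#' Default validation-set run indices
#'
#' The eleven runs of the 25-run five-level design whose mapped default
#' concentrations reproduce, as a set, the printed validation mixtures
#' (see [validation_set_concentrations()]). Shipped as a documented
#' constant of the default study layout.
#'
#' @return Integer vector of 11 run indices.
#' @export
default_validation_rows <- function() {
  c(1L, 4L, 6L, 7L, 9L, 10L, 15L, 16L, 20L, 23L, 25L)
}

#' Split a design into calibration and validation runs
#'
#' @param design a [brereton_design()] (or any run matrix).
#' @param validation_rows indices of the external validation runs; the
#'   default yields the standard 14 calibration / 11 validation layout.
#' @return A `design_split`: list with integer vectors `calibration_rows`
#'   and `validation_rows`.
#' @export
split_design <- function(design, validation_rows = default_validation_rows()) {
  n <- nrow(design)
  validation_rows <- as.integer(validation_rows)
  if (anyDuplicated(validation_rows)) {
    stop("`validation_rows` contains duplicates", call. = FALSE)
  }
  if (length(validation_rows) > 0 &&
    (min(validation_rows) < 1L || max(validation_rows) > n)) {
    stop("`validation_rows` out of range", call. = FALSE)
  }
  structure(
    list(
      calibration_rows = setdiff(seq_len(n), validation_rows),
      validation_rows = sort(validation_rows)
    ),
    class = "design_split"
  )
}

#' Coded or mapped design export
#'
#' @param design a `coded_design` or [concentration_matrix()].
#' @param path CSV file path.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(as.data.frame(unclass(design)), path, row.names = TRUE)
  invisible(path)
}
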
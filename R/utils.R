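#' Derive a reproducible sub-stream seed
#'
#' Mixes a master seed with an arbitrary sequence of integer or character
#' components through a Lehmer-style modular recurrence, so that any single
#' simulated unit (a sample, ROI, panel or timepoint) can be regenerated in
#' isolation from the master seed alone. The result is always a non-negative
#' integer below 2^31 - 1.
#'
#' @param master master seed (single number).
#' @param ... components identifying the sub-stream (numbers or strings).
#' @return a single integer seed.
#' @keywords internal
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647  # 2^31 - 1; 48271 * m < 2^53 so the recurrence is exact
  h <- abs(as.double(master)) %% m
  for (k in list(...)) {
    kk <- if (is.character(k)) {
      v <- utf8ToInt(k)
      sum(v * seq_along(v)) %% m
    } else {
      abs(as.double(k)) %% m
    }
    h <- (h * 48271 + kk + 1) %% m
  }
  as.integer(h)
}

#' Trapezoid-rule integral of tabulated values
#' @param x abscissae (non-decreasing).
#' @param y ordinates, same length as `x`.
#' @return the integral as a single number.
#' @keywords internal
trapz <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched. NULL seed runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# ROI area in mm^2 from field dimensions in microns.
roi_area_mm2 <- function(width_um, height_um) {
  stopifnot(width_um > 0, height_um > 0)
  width_um * height_um / 1e6
}

`%||%` <- function(a, b) if (is.null(a)) b else a
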
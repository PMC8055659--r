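#' Empirical nearest-neighbour distance G function
#'
#' The empirical cumulative distribution of nearest-neighbour distances
#' evaluated on a radius grid: `G(r) = #\{d_i <= r\} / n` (right-continuous).
#'
#' @param distances nearest-neighbour distances in microns (non-empty).
#' @param radii non-decreasing radius grid in microns.
#' @return numeric vector of G values in `[0, 1]`, one per radius.
#' @export
empirical_G <- function(distances, radii) {
  distances <- distances[!is.na(distances)]
  if (length(distances) == 0L) stop("no distances supplied")
  if (is.unsorted(radii)) stop("radii must be non-decreasing")
  stats::ecdf(distances)(radii)
}

#' Theoretical Poisson G function
#'
#' Under complete spatial randomness of the target pattern with intensity
#' `lambda` (points per square micron), the nearest-neighbour distance CDF
#' is `G(r) = 1 - exp(-lambda * pi * r^2)`. The intensity is taken from the
#' observed pattern (`n_target / area`), so the reference curve assumes the
#' same abundance as the data.
#'
#' @param lambda target intensity, cells per square micron (>= 0).
#' @param radii non-decreasing radius grid in microns.
#' @return numeric vector of G values.
#' @export
theoretical_G <- function(lambda, radii) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (is.unsorted(radii)) stop("radii must be non-decreasing")
  1 - exp(-lambda * pi * radii^2)
}

#' Mixing deviation score between empirical and Poisson G curves
#'
#' The signed area, by the trapezoid rule, between the theoretical and the
#' empirical curve over the radius grid:
#' `score = integral of (G_theo(r) - G_emp(r)) dr`, in microns. The score
#' is positive when the observed target cells sit farther from the
#' reference cells than complete spatial randomness predicts (empirical
#' curve below the Poisson curve) — i.e. when T cells are excluded from
#' the malignant nests.
#'
#' @param g_emp empirical G values on `radii`.
#' @param g_theo theoretical G values on the same grid.
#' @param radii common radius grid in microns (default 0..200, matching the
#'   200-micron working radius of the proximity maps).
#' @return the score in microns.
#' @export
mix_score <- function(g_emp, g_theo, radii = 0:200) {
  if (length(g_emp) != length(radii) || length(g_theo) != length(radii)) {
    stop("curve/grid length mismatch")
  }
  trapz(radii, g_theo - g_emp)
}

#' Label a mixing score as mixed, unmixed or aggregated
#'
#' Scores within the `[-10, +10]` band (boundary inclusive) track the
#' Poisson curve closely: the mixed pattern, T cells infiltrating among
#' malignant cells. Scores above +10 mark the unmixed pattern: cohesive
#' malignant nests with excluded T cells. Scores below -10 indicate target
#' cells markedly closer than random — an extension label (`"aggregated"`)
#' for patterns outside the published band.
#'
#' @param score finite mixing score(s) in microns.
#' @param band half-width of the mixed band (default 10).
#' @return character vector of labels.
#' @export
classify_pattern <- function(score, band = 10) {
  stopifnot(all(is.finite(score)))
  ifelse(score > band, "unmixed",
         ifelse(score < -band, "aggregated", "mixed"))
}

#' Cross-type G-function pattern classification for a cohort
#'
#' For each sample, pools the nearest-neighbour distances from reference
#' cells (malignant, `CK+`) to the nearest key-marker cell (`CD3+`) across
#' the sample's ROIs, estimates the key-marker intensity from the pooled
#' count over the pooled area, compares the empirical G curve to the
#' theoretical Poisson curve, and labels the sample mixed or unmixed by the
#' [mix_score()].
#'
#' @param ct a [cell_table()] (use a single timepoint).
#' @param panel a [panel_spec()] defining both phenotypes.
#' @param reference reference phenotype name (default `"CK+"`).
#' @param key key-marker phenotype name (default `"CD3+"`).
#' @param radii radius grid in microns (default 0..200, step 1).
#' @param by `"sample"` (default) pools ROIs per sample; `"roi"` scores
#'   each ROI separately.
#' @param border_correction drop reference cells nearer than `max(radii)`
#'   to the ROI boundary (reduces censoring bias of the raw empirical CDF
#'   in a finite field, at the cost of discarding most cells when the grid
#'   is wide; off by default, matching the descriptive use of the curves).
#' @return an object of class `mif_gpattern`: list with `table`
#'   (data.frame: unit, n_ref, n_target, lambda, score, label) and `curves`
#'   (per-unit list with `radii`, `g_emp`, `g_theo`). Units without both
#'   phenotypes yield an `NA` row and a message.
#' @export
classify_cohort <- function(ct, panel, reference = "CK+", key = "CD3+",
                            radii = 0:200, by = c("sample", "roi"),
                            border_correction = FALSE) {
  by <- match.arg(by)
  mem <- assign_phenotypes(ct, panel)
  stopifnot(all(c(reference, key) %in% colnames(mem)))
  W <- attr(ct, "width_um"); H <- attr(ct, "height_um")
  area <- W * H  # um^2
  unit_key <- if (by == "sample") ct$sample_id else
    paste(ct$sample_id, ct$roi_id, sep = "/")
  units <- unique(unit_key)
  frames <- split(seq_len(nrow(ct)), frame_key(ct))
  rows <- list(); curves <- list()
  rmax <- max(radii)
  for (u in units) {
    dl <- list(); n_t <- 0L; n_frames <- 0L
    for (ii in frames) {
      if (unit_key[ii[1]] != u) next
      n_frames <- n_frames + 1L
      ri <- ii[mem[ii, reference]]
      ti <- ii[mem[ii, key]]
      n_t <- n_t + length(ti)
      if (border_correction && length(ri) > 0L) {
        interior <- ct$x_um[ri] >= rmax & ct$x_um[ri] <= W - rmax &
          ct$y_um[ri] >= rmax & ct$y_um[ri] <= H - rmax
        ri <- ri[interior]
      }
      if (length(ri) == 0L || length(ti) == 0L) next
      dl[[length(dl) + 1L]] <- suppressWarnings(
        nn_distances(cbind(ct$x_um[ri], ct$y_um[ri]),
                     cbind(ct$x_um[ti], ct$y_um[ti]),
                     ref_ids = ct$cell_id[ri], target_ids = ct$cell_id[ti]))
    }
    d <- unlist(dl) %||% numeric(0)
    if (length(d) == 0L || n_t == 0L) {
      message("unit ", u, ": missing ", reference, " or ", key,
              " cells; no pattern call")
      rows[[u]] <- data.frame(unit = u, n_ref = length(d), n_target = n_t,
                              lambda = NA_real_, score = NA_real_,
                              label = NA_character_, stringsAsFactors = FALSE)
      next
    }
    lambda <- n_t / (n_frames * area)
    g_emp <- empirical_G(d, radii)
    g_theo <- theoretical_G(lambda, radii)
    score <- mix_score(g_emp, g_theo, radii)
    rows[[u]] <- data.frame(unit = u, n_ref = length(d), n_target = n_t,
                            lambda = lambda, score = score,
                            label = classify_pattern(score),
                            stringsAsFactors = FALSE)
    curves[[u]] <- list(radii = radii, g_emp = g_emp, g_theo = g_theo,
                        lambda = lambda, score = score,
                        label = classify_pattern(score))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, curves = curves, reference = reference,
                 key = key, by = by),
            class = "mif_gpattern")
}

#' @export
print.mif_gpattern <- function(x, ...) {
  cat("spatial pattern classification: ", x$reference, " -> ", x$key,
      " nearest-neighbour G vs Poisson (per ", x$by, ")\n", sep = "")
  tab <- x$table
  tab$score <- round(tab$score, 2)
  tab$lambda <- signif(tab$lambda, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Plot empirical and Poisson G curves for one unit
#'
#' @param x a `mif_gpattern` object.
#' @param unit which sample (or ROI) to plot; default the first with a call.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.mif_gpattern <- function(x, unit = names(x$curves)[1], ...) {
  cv <- x$curves[[unit]]
  if (is.null(cv)) stop("no curves for unit ", unit)
  graphics::plot(cv$radii, cv$g_theo, type = "l", lty = 2, col = "grey40",
                 xlab = "radius r (um)", ylab = "G(r)", ylim = c(0, 1),
                 main = sprintf("%s: score %.1f um (%s)", unit, cv$score,
                                cv$label))
  graphics::lines(cv$radii, cv$g_emp, col = "firebrick", lwd = 2)
  graphics::legend("bottomright",
                   legend = c("empirical G", "Poisson G (same intensity)"),
                   col = c("firebrick", "grey40"), lty = c(1, 2), bty = "n")
  invisible(x)
}
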
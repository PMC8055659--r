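#' Nearest-neighbour distances between two point sets
#'
#' Euclidean distance, in microns, from each reference cell to its nearest
#' target cell within the same ROI. When the same segmented cell qualifies
#' for both phenotypes (overlapping co-expression rules), its self-distance
#' is excluded — the nearest *other* cell counts. The computation is a
#' block-wise vectorised exhaustive search; tests hold it exactly equal to
#' a plain O(n^2) double loop.
#'
#' @param ref matrix or data.frame of reference positions (columns
#'   `x_um`, `y_um`, or the first two columns).
#' @param target positions of target cells (same layout).
#' @param ref_ids,target_ids optional cell ids used to exclude
#'   self-matches between overlapping phenotype sets.
#' @return numeric vector, one distance per reference cell (length 0 if
#'   `ref` is empty). `NA` (with a warning) for a reference cell whose only
#'   target is itself.
#' @export
nn_distances <- function(ref, target, ref_ids = NULL, target_ids = NULL) {
  ref <- as_xy(ref)
  target <- as_xy(target)
  if (nrow(target) == 0L) stop("no target cells")
  if (nrow(ref) == 0L) return(numeric(0))
  exclude <- !is.null(ref_ids) && !is.null(target_ids)
  if (exclude) {
    stopifnot(length(ref_ids) == nrow(ref),
              length(target_ids) == nrow(target))
  }
  out <- numeric(nrow(ref))
  block <- 512L
  for (start in seq(1L, nrow(ref), by = block)) {
    idx <- start:min(start + block - 1L, nrow(ref))
    d2 <- outer(ref[idx, 1], target[, 1], "-")^2 +
      outer(ref[idx, 2], target[, 2], "-")^2
    if (exclude) {
      hit <- outer(ref_ids[idx], target_ids, "==")
      d2[hit] <- Inf
    }
    nearest <- max.col(-d2, ties.method = "first")
    out[idx] <- d2[cbind(seq_along(idx), nearest)]
  }
  if (any(!is.finite(out))) {
    warning("reference cell(s) with no other target cell: NA distance")
    out[!is.finite(out)] <- NA_real_
  }
  sqrt(out)
}

as_xy <- function(p) {
  if (is.data.frame(p)) {
    cols <- if (all(c("x_um", "y_um") %in% names(p))) c("x_um", "y_um") else 1:2
    p <- as.matrix(p[, cols, drop = FALSE])
  }
  storage.mode(p) <- "double"
  p
}

#' Global median radius from phenotype-pair median distances
#'
#' The close/far radius of the cohort: the median over all phenotype pairs
#' (across panels) of the per-pair median nearest-neighbour distance.
#'
#' @param medians numeric vector of per-pair median distances, or the
#'   `pairs` data.frame from [proximity_summary()] (its `median_distance`
#'   column is used).
#' @return a single radius in microns.
#' @export
median_radius <- function(medians) {
  if (is.data.frame(medians)) medians <- medians$median_distance
  medians <- medians[!is.na(medians)]
  if (length(medians) == 0L) stop("no defined median distances")
  stats::median(medians)
}

#' Classify a phenotype as close to or far from the reference cells
#'
#' Close iff the median nearest-neighbour distance is less than or equal to
#' the radius (boundary inclusive); far otherwise.
#'
#' @param median_distance median NN distance in microns.
#' @param radius close/far radius in microns.
#' @return `"close"` or `"far"` (vectorised).
#' @export
classify_proximity <- function(median_distance, radius) {
  stopifnot(all(median_distance >= 0, na.rm = TRUE), radius >= 0)
  ifelse(median_distance <= radius, "close", "far")
}

#' Nearest-neighbour proximity summary between phenotype pairs
#'
#' For every (reference, target) phenotype pair, computes per-reference-cell
#' nearest-neighbour distances within each ROI, pools them across the
#' cohort (default) or summarises per sample first, and reports the median.
#' Distances are never computed across ROI boundaries: each scanned field
#' is a separate capture.
#'
#' @param ct a [cell_table()] (typically one timepoint of a cohort).
#' @param panel a [panel_spec()].
#' @param ref_phenotypes character vector of reference phenotype names
#'   (default: `CK+` and every rule requiring CK, i.e. malignant cells and
#'   malignant cells expressing each checkpoint).
#' @param target_phenotypes target phenotype names (default: all other
#'   rules of the panel).
#' @param pooling `"pooled"` (default) pools per-cell distances across all
#'   ROIs and samples before taking the median; `"per_sample"` takes the
#'   median within each sample and then the median of those.
#' @param keep_distances retain the raw pooled distance vectors.
#' @return an object of class `mif_proximity`: list with `pairs`
#'   (data.frame: reference, target, n_ref, n_target, median_distance),
#'   `matrix` (reference x target median distances), `pooling` and
#'   optionally `distances`.
#' @export
proximity_summary <- function(ct, panel,
                              ref_phenotypes = NULL,
                              target_phenotypes = NULL,
                              pooling = c("pooled", "per_sample"),
                              keep_distances = FALSE) {
  pooling <- match.arg(pooling)
  mem <- assign_phenotypes(ct, panel)
  rule_names <- colnames(mem)
  if (is.null(ref_phenotypes)) {
    ref_phenotypes <- rule_names[vapply(panel$rules, function(r)
      "CK" %in% r$positive, logical(1))]
    if (length(ref_phenotypes) == 0L) ref_phenotypes <- rule_names[1]
  }
  if (is.null(target_phenotypes)) {
    target_phenotypes <- setdiff(rule_names, ref_phenotypes)
  }
  stopifnot(all(c(ref_phenotypes, target_phenotypes) %in% rule_names))
  frames <- split(seq_len(nrow(ct)), frame_key(ct))
  pairs <- expand.grid(reference = ref_phenotypes,
                       target = target_phenotypes,
                       stringsAsFactors = FALSE)
  dist_list <- vector("list", nrow(pairs))
  med <- n_ref <- n_tgt <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    rph <- pairs$reference[k]; tph <- pairs$target[k]
    dl <- list()
    samp <- list()
    for (ii in frames) {
      ri <- ii[mem[ii, rph]]
      ti <- ii[mem[ii, tph]]
      if (length(ri) == 0L || length(ti) == 0L) next
      d <- suppressWarnings(
        nn_distances(cbind(ct$x_um[ri], ct$y_um[ri]),
                     cbind(ct$x_um[ti], ct$y_um[ti]),
                     ref_ids = ct$cell_id[ri], target_ids = ct$cell_id[ti]))
      dl[[length(dl) + 1L]] <- d
      samp[[length(samp) + 1L]] <- rep(ct$sample_id[ri[1]], length(d))
    }
    d_all <- unlist(dl) %||% numeric(0)
    n_ref[k] <- length(d_all)
    n_tgt[k] <- sum(mem[, tph])
    if (length(d_all) == 0L) {
      med[k] <- NA_real_
      message("proximity pair ", rph, " -> ", tph,
              ": no co-occurring cells in any ROI; entry NULL")
    } else if (pooling == "pooled") {
      med[k] <- stats::median(d_all, na.rm = TRUE)
    } else {
      per <- tapply(d_all, unlist(samp), stats::median, na.rm = TRUE)
      med[k] <- stats::median(per, na.rm = TRUE)
    }
    if (keep_distances) dist_list[[k]] <- d_all
  }
  pairs$n_ref <- n_ref
  pairs$n_target <- n_tgt
  pairs$median_distance <- med
  mat <- matrix(NA_real_, length(ref_phenotypes), length(target_phenotypes),
                dimnames = list(ref_phenotypes, target_phenotypes))
  mat[cbind(pairs$reference, pairs$target)] <- pairs$median_distance
  out <- list(pairs = pairs, matrix = mat, pooling = pooling)
  if (keep_distances) out$distances <- dist_list
  structure(out, class = "mif_proximity")
}

#' @export
print.mif_proximity <- function(x, ...) {
  cat("median nearest-neighbour distances (um), ", x$pooling,
      " pooling:\n", sep = "")
  print(round(x$matrix, 2))
  invisible(x)
}

#' Heatmap of a proximity matrix
#' @param x a `mif_proximity` object.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.mif_proximity <- function(x, ...) {
  m <- x$matrix
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                  axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(m)), rev(rownames(m)), las = 2, cex.axis = 0.7)
  graphics::box()
  invisible(x)
}
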
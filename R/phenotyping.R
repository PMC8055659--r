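#' Assign co-expression phenotypes to cells
#'
#' A cell belongs to a phenotype rule iff all of the rule's positive markers
#' are positive and all of its negative markers are negative. Membership is
#' non-exclusive: a CD3+CD8+ cell is also CD3+, mirroring the overlapping
#' phenotype rows of the published panels.
#'
#' @param ct a [cell_table()] carrying all markers declared by `panel`.
#' @param panel a [panel_spec()].
#' @return logical matrix, one row per cell (named by `cell_id` order of
#'   `ct`), one column per phenotype rule.
#' @export
assign_phenotypes <- function(ct, panel) {
  validate_cell_table(ct, panel = panel)
  n <- nrow(ct)
  out <- matrix(FALSE, nrow = n, ncol = length(panel$rules),
                dimnames = list(NULL, vapply(panel$rules, `[[`,
                                             character(1), "name")))
  for (j in seq_along(panel$rules)) {
    r <- panel$rules[[j]]
    member <- rep(TRUE, n)
    for (mk in r$positive) member <- member & ct[[mk]] == 1L
    for (mk in r$negative) member <- member & ct[[mk]] == 0L
    out[, j] <- member
  }
  out
}

#' Compute phenotype densities per ROI
#'
#' Counts each phenotype per (sample, roi, timepoint) frame and normalises
#' to cells/mm^2 using the ROI field area. One additional record per frame,
#' phenotype `"DAPI+"`, carries the total nucleated-cell count — the
#' denominator for [percent_of_total()].
#'
#' @param ct a [cell_table()].
#' @param panel a [panel_spec()].
#' @return data.frame with columns `sample_id`, `roi_id`, `timepoint`,
#'   `panel`, `phenotype`, `count`, `density_cells_mm2`.
#' @export
compute_densities <- function(ct, panel) {
  mem <- assign_phenotypes(ct, panel)
  area <- roi_area_mm2(attr(ct, "width_um"), attr(ct, "height_um"))
  key <- frame_key(ct)
  ukey <- unique(key)
  grp <- factor(key, levels = ukey)
  counts <- rowsum(cbind(mem * 1L, `DAPI+` = 1L), grp)
  meta <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  phen <- colnames(counts)
  out <- data.frame(
    sample_id = rep(meta[, 1], times = length(phen)),
    roi_id = rep(meta[, 2], times = length(phen)),
    timepoint = rep(meta[, 3], times = length(phen)),
    panel = panel$panel_id,
    phenotype = rep(phen, each = length(ukey)),
    count = as.vector(counts),
    stringsAsFactors = FALSE)
  out$density_cells_mm2 <- out$count / area
  ord <- order(match(out$sample_id, meta[, 1]), out$roi_id, out$timepoint,
               match(out$phenotype, phen))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fill percent-of-DAPI for a density table
#'
#' Percent is the phenotype count divided by the frame's total nucleated
#' (DAPI+) count, times 100 — equivalently the density ratio, since the ROI
#' area cancels. Frames whose total count is zero are flagged with a
#' warning and get `NA` percents.
#'
#' @param dens a density table from [compute_densities()] (the `"DAPI+"`
#'   rows must be present).
#' @return `dens` with an added `percent_dapi` column.
#' @export
percent_of_total <- function(dens) {
  stopifnot(all(c("sample_id", "roi_id", "timepoint", "count") %in% names(dens)))
  key <- paste(dens$sample_id, dens$roi_id, dens$timepoint, dens$panel,
               sep = "\r")
  tot_rows <- dens$phenotype == "DAPI+"
  if (!any(tot_rows)) stop("density table lacks DAPI+ total records")
  totals <- dens$count[tot_rows]
  names(totals) <- key[tot_rows]
  tot <- totals[key]
  if (anyNA(tot)) stop("frame(s) lack a DAPI+ total record")
  zero <- tot == 0
  if (any(zero)) {
    warning("frame(s) with zero total cells flagged; percents set to NA: ",
            paste(unique(gsub("\r", "/", key[zero])), collapse = ", "))
  }
  dens$percent_dapi <- ifelse(zero, NA_real_, 100 * dens$count / tot)
  dens
}
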
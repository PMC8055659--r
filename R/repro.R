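#' Two-point coefficient of variation between timepoints
#'
#' CV of a pair of replicate measurements, using the sample standard
#' deviation (denominator n-1), so `CV(a, b) = |a - b| / (sqrt(2) * mean)`.
#' By convention a pair of zeros has CV 0 (a phenotype absent in both
#' replicates is perfectly reproduced); for non-negative inputs a zero mean
#' with `a != b` cannot occur.
#'
#' @param a,b non-negative replicate values (vectorised).
#' @return CV values, same length as the inputs.
#' @export
cv_two_timepoints <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE)) {
    stop("CV inputs must be non-negative")
  }
  m <- (a + b) / 2
  ifelse(a == 0 & b == 0, 0, abs(a - b) / (sqrt(2) * m))
}

#' Spearman rank correlation between two timepoints
#'
#' Standard Spearman coefficient with average ranks for ties and a
#' two-sided p-value from the t approximation (ties make the exact null
#' distribution unavailable). Pairs shorter than 3, or with zero variance
#' in either vector, are undefined and return `NA` with a warning.
#'
#' @param x,y paired vectors (e.g. week-1 and week-2 percentages over ROIs).
#' @return list with elements `rho` and `p`.
#' @export
spearman_pair <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    warning("Spearman undefined for fewer than 3 pairs")
    return(list(rho = NA_real_, p = NA_real_))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("Spearman undefined for a zero-variance vector")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` with `m` the family size (the number of
#' phenotypes tested within one panel).
#'
#' @param p vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "bonferroni")
}

#' Summarise between-timepoint reproducibility for one panel
#'
#' For every phenotype of a panel, computes the per-ROI two-point CV of its
#' percent-of-DAPI between the two timepoints, the within-sample Spearman
#' correlation (one coefficient per sample, over its ROIs), and the
#' across-sample Spearman correlation (sample-level mean percents, week 1
#' vs week 2, over all samples) with Bonferroni adjustment across the
#' panel's phenotypes. Phenotypes with zero counts in at least
#' `min_nonzero_frac` of the (ROI, timepoint) observations are too scarce
#' for a meaningful reproducibility call and are excluded (and listed).
#' Flags mark phenotypes whose median CV exceeds 0.5 or whose median
#' within-sample / across-sample correlations fall below the 0.5 / 0.7
#' benchmarks.
#'
#' @param dens density table for one panel with `percent_dapi` filled (see
#'   [percent_of_total()]), containing both timepoints.
#' @param timepoints the two timepoint labels, week 1 first.
#' @param min_nonzero_frac exclusion threshold: fraction of zero-count
#'   observations at or above which a phenotype is dropped (default 0.5).
#' @param across_mode `"sample_means"` (default) correlates sample-level
#'   mean percents across samples; `"pooled"` correlates all per-ROI
#'   percents pooled over samples.
#' @return an object of class `mif_repro`: list with `stats` (per-phenotype
#'   summary), `cv` (long per-ROI CV table), `rho_within` (per sample x
#'   phenotype), `excluded` (character), `family_size`.
#' @export
summarize_repro <- function(dens, timepoints = c("week1", "week2"),
                            min_nonzero_frac = 0.5,
                            across_mode = c("sample_means", "pooled")) {
  across_mode <- match.arg(across_mode)
  stopifnot("percent_dapi" %in% names(dens))
  if (length(unique(dens$panel)) > 1L) {
    stop("summarize_repro expects a single panel; split the table first")
  }
  d1 <- dens[dens$timepoint == timepoints[1], , drop = FALSE]
  d2 <- dens[dens$timepoint == timepoints[2], , drop = FALSE]
  k1 <- paste(d1$sample_id, d1$roi_id, d1$phenotype, sep = "\r")
  k2 <- paste(d2$sample_id, d2$roi_id, d2$phenotype, sep = "\r")
  orphans <- c(setdiff(k1, k2), setdiff(k2, k1))
  if (length(orphans) > 0L) {
    stop("unmatched (sample, ROI, phenotype) keys across timepoints: ",
         paste(utils::head(gsub("\r", "/", orphans), 5), collapse = ", "))
  }
  d2 <- d2[match(k1, k2), , drop = FALSE]
  phenos <- setdiff(unique(d1$phenotype), "DAPI+")
  scarce <- vapply(phenos, function(ph) {
    i <- d1$phenotype == ph
    mean(c(d1$count[i], d2$count[i]) == 0) >= min_nonzero_frac
  }, logical(1))
  excluded <- phenos[scarce]
  phenos <- phenos[!scarce]
  if (length(phenos) == 0L) stop("no phenotype passes the scarcity filter")

  cv_tab <- do.call(rbind, lapply(phenos, function(ph) {
    i <- d1$phenotype == ph
    data.frame(sample_id = d1$sample_id[i], roi_id = d1$roi_id[i],
               phenotype = ph,
               percent_w1 = d1$percent_dapi[i], percent_w2 = d2$percent_dapi[i],
               cv = cv_two_timepoints(d1$percent_dapi[i], d2$percent_dapi[i]),
               stringsAsFactors = FALSE)
  }))

  samples <- unique(d1$sample_id)
  rho_within <- do.call(rbind, lapply(phenos, function(ph) {
    do.call(rbind, lapply(samples, function(s) {
      i <- d1$phenotype == ph & d1$sample_id == s
      sp <- suppressWarnings(spearman_pair(d1$percent_dapi[i],
                                           d2$percent_dapi[i]))
      data.frame(sample_id = s, phenotype = ph, n_roi = sum(i),
                 rho = sp$rho, p = sp$p, stringsAsFactors = FALSE)
    }))
  }))

  across <- lapply(phenos, function(ph) {
    i <- d1$phenotype == ph
    if (across_mode == "sample_means") {
      m1 <- tapply(d1$percent_dapi[i], d1$sample_id[i], mean)
      m2 <- tapply(d2$percent_dapi[i], d2$sample_id[i], mean)
      m2 <- m2[names(m1)]
      suppressWarnings(spearman_pair(as.vector(m1), as.vector(m2)))
    } else {
      suppressWarnings(spearman_pair(d1$percent_dapi[i], d2$percent_dapi[i]))
    }
  })
  p_raw <- vapply(across, `[[`, numeric(1), "p")
  p_adj <- bonferroni(p_raw)

  stats_tab <- data.frame(
    panel = dens$panel[1],
    phenotype = phenos,
    n_cv = as.vector(table(factor(cv_tab$phenotype, levels = phenos))),
    median_cv = vapply(phenos, function(ph)
      stats::median(cv_tab$cv[cv_tab$phenotype == ph], na.rm = TRUE),
      numeric(1)),
    median_rho_within = vapply(phenos, function(ph)
      stats::median(rho_within$rho[rho_within$phenotype == ph], na.rm = TRUE),
      numeric(1)),
    rho_across = vapply(across, `[[`, numeric(1), "rho"),
    p_raw = p_raw, p_adj = p_adj,
    stringsAsFactors = FALSE)
  stats_tab$flag_cv <- stats_tab$median_cv > 0.5
  stats_tab$flag_within <- !is.na(stats_tab$median_rho_within) &
    stats_tab$median_rho_within < 0.5
  stats_tab$flag_across <- !is.na(stats_tab$rho_across) &
    stats_tab$rho_across < 0.7
  rownames(stats_tab) <- NULL
  structure(list(stats = stats_tab, cv = cv_tab, rho_within = rho_within,
                 excluded = excluded, family_size = length(phenos),
                 across_mode = across_mode),
            class = "mif_repro")
}

#' @export
print.mif_repro <- function(x, ...) {
  cat("between-timepoint reproducibility, panel ", x$stats$panel[1], " (",
      x$family_size, " phenotypes; ", length(x$excluded),
      " excluded as scarce)\n", sep = "")
  df <- x$stats
  df$median_cv <- round(df$median_cv, 3)
  df$median_rho_within <- round(df$median_rho_within, 3)
  df$rho_across <- round(df$rho_across, 3)
  df$p_adj <- signif(df$p_adj, 3)
  print(df[, c("phenotype", "n_cv", "median_cv", "median_rho_within",
               "rho_across", "p_adj")], row.names = FALSE)
  if (length(x$excluded) > 0L) {
    cat("excluded (scarce): ", paste(x$excluded, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Trellis-style reproducibility plot
#'
#' Per-sample panels of percent-of-DAPI by ROI, week-1 and week-2 points
#' overlaid, for a single phenotype — the standard visual check that the
#' two staining runs track each other.
#'
#' @param x a `mif_repro` object.
#' @param phenotype which phenotype to plot (default the first).
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.mif_repro <- function(x, phenotype = x$stats$phenotype[1], ...) {
  cv <- x$cv[x$cv$phenotype == phenotype, , drop = FALSE]
  if (nrow(cv) == 0L) stop("phenotype not present: ", phenotype)
  samples <- unique(cv$sample_id)
  nc <- ceiling(sqrt(length(samples)))
  nr <- ceiling(length(samples) / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(2.5, 2.5, 2, 0.5))
  on.exit(graphics::par(op))
  ylim <- range(c(cv$percent_w1, cv$percent_w2), na.rm = TRUE)
  for (s in samples) {
    i <- cv$sample_id == s
    rois <- seq_len(sum(i))
    graphics::plot(rois, cv$percent_w1[i], pch = 19, col = "blue",
                   ylim = ylim, xlab = "ROI", ylab = "% of DAPI+", main = s)
    graphics::points(rois, cv$percent_w2[i], pch = 19, col = "red")
  }
  invisible(x)
}
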
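#' Default phenotype-conditional marker positivity probabilities
#'
#' For each panel and each exclusive base cell class (`malignant`, `tcell`,
#' `macrophage`, `other`), the probability that a cell of that class scores
#' positive for each panel marker. Markers are drawn independently given the
#' class. The values are calibrated so that the rank order of the resulting
#' phenotype densities matches the published cohort medians (e.g. CK+ around
#' 3,000 cells/mm^2; CD45RO the most abundant T-cell subset marker;
#' CD3+TIM3+ rare): the exact medians of a 10-patient cohort are not
#' reproduction targets.
#'
#' @return nested list: panel id -> class -> named probability vector.
#' @export
default_marker_probs <- function() {
  bg <- function(markers, p = 0.002) stats::setNames(rep(p, length(markers)), markers)
  p1 <- c("CK", "CD3", "CD8", "PD-1", "PD-L1", "CD68")
  p2 <- c("CK", "CD3", "CD8", "CD45RO", "GZB", "FOXP3")
  p3 <- c("CK", "CD3", "PD-L1", "B7-H3", "B7-H4", "IDO-1", "CD68")
  p4 <- c("CK", "CD3", "ICOS", "LAG3", "OX40", "TIM3", "VISTA")
  p5 <- c("CK", "Arg-1", "CD11b", "CD14", "CD33", "CD66b", "CD68")
  set <- function(base, ...) {
    v <- list(...)
    base[names(v)] <- unlist(v)
    base
  }
  list(
    "1" = list(
      malignant  = set(bg(p1), CK = 0.97, `PD-L1` = 0.04),
      tcell      = set(bg(p1), CD3 = 0.95, CD8 = 0.70, `PD-1` = 0.05,
                       `PD-L1` = 0.03),
      macrophage = set(bg(p1), CD68 = 0.92, `PD-L1` = 0.65),
      other      = set(bg(p1), `PD-L1` = 0.02)
    ),
    "2" = list(
      malignant  = set(bg(p2), CK = 0.97),
      tcell      = set(bg(p2), CD3 = 0.95, CD8 = 0.60, CD45RO = 0.75,
                       GZB = 0.05, FOXP3 = 0.15),
      macrophage = bg(p2),
      other      = bg(p2)
    ),
    "3" = list(
      malignant  = set(bg(p3, 0.001), CK = 0.97, `PD-L1` = 0.055,
                       `B7-H3` = 0.0002, `B7-H4` = 0.002, `IDO-1` = 0.03),
      tcell      = set(bg(p3, 0.001), CD3 = 0.95, `PD-L1` = 0.11,
                       `B7-H3` = 0.80, `B7-H4` = 0.0005, `IDO-1` = 0.02),
      macrophage = set(bg(p3, 0.001), CD68 = 0.92, `PD-L1` = 0.55,
                       `B7-H3` = 0.0002, `B7-H4` = 0.0005, `IDO-1` = 0.13),
      other      = set(bg(p3, 0.001), `PD-L1` = 0.02)
    ),
    "4" = list(
      malignant  = set(bg(p4, 0.0005), CK = 0.97, OX40 = 0.0015),
      tcell      = set(bg(p4, 0.0005), CD3 = 0.95, VISTA = 0.024,
                       ICOS = 0.08, LAG3 = 0.015, OX40 = 0.026, TIM3 = 0.004),
      macrophage = bg(p4, 0.002),
      other      = bg(p4, 0.0005)
    ),
    "5" = list(
      malignant  = set(bg(p5, 0.001), CK = 0.97),
      tcell      = bg(p5, 0.001),
      macrophage = set(bg(p5, 0.001), CD68 = 0.92, `Arg-1` = 0.002,
                       CD11b = 0.88, CD14 = 0.45, CD33 = 0.35, CD66b = 0.03),
      other      = set(bg(p5, 0.001), CD11b = 0.02, CD14 = 0.01,
                       CD33 = 0.02, CD66b = 0.015)
    )
  )
}

#' Configuration for the synthetic tissue generator
#'
#' The generator emulates the study design: a cohort of `n_samples` tumours,
#' `n_rois` scanned fields of `width_um` x `height_um` per tumour, each
#' captured at two timepoints on consecutive sections. Malignant cells form
#' cohesive nests via a Matern cluster process (Poisson parents, uniform
#' offspring in discs of `nest_radius`); T cells and macrophages infiltrate
#' the nests with probability `mixing` and otherwise occupy the stroma;
#' `other` nucleated cells are uniform background. Between-sample abundance
#' heterogeneity is log-normal per class with log-sd `sample_sd`. The
#' week-2 replicate retains each week-1 cell with probability
#' `replicate_keep`, jitters retained positions by an isotropic Gaussian of
#' sd `jitter_sd`, and adds `Poisson(replicate_add * n)` new cells per
#' class from the same spatial model.
#'
#' @param width_um,height_um ROI field size in microns (931 x 698).
#' @param n_samples number of tumours (10).
#' @param n_rois ROIs per tumour (5).
#' @param nest_parent_rate mean number of malignant nests per ROI (8).
#' @param nest_radius nest disc radius, microns (120).
#' @param nest_offspring_mean mean malignant cells per nest (250).
#' @param immune_rate mean T cells per ROI (400).
#' @param macrophage_rate mean macrophages per ROI (75).
#' @param other_rate mean other nucleated (stromal) cells per ROI (600).
#' @param mixing fraction of immune cells placed inside nests, in `[0,1]`.
#' @param marker_probs phenotype-conditional positivity probabilities, as
#'   [default_marker_probs()].
#' @param sample_sd log-normal between-sample abundance sd (0.5).
#' @param replicate_keep per-cell retention probability q for week 2 (0.9).
#' @param replicate_add new-cell fraction epsilon for week 2 (0.1).
#' @param jitter_sd week-2 positional jitter sd, microns (2).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(width_um = 931, height_um = 698, n_samples = 10,
                       n_rois = 5, nest_parent_rate = 8, nest_radius = 120,
                       nest_offspring_mean = 250, immune_rate = 400,
                       macrophage_rate = 75, other_rate = 600, mixing = 0.5,
                       marker_probs = default_marker_probs(),
                       sample_sd = 0.5, replicate_keep = 0.9,
                       replicate_add = 0.1, jitter_sd = 2) {
  cfg <- list(width_um = width_um, height_um = height_um,
              n_samples = as.integer(n_samples), n_rois = as.integer(n_rois),
              nest_parent_rate = nest_parent_rate, nest_radius = nest_radius,
              nest_offspring_mean = nest_offspring_mean,
              immune_rate = immune_rate, macrophage_rate = macrophage_rate,
              other_rate = other_rate, mixing = mixing,
              marker_probs = marker_probs, sample_sd = sample_sd,
              replicate_keep = replicate_keep, replicate_add = replicate_add,
              jitter_sd = jitter_sd)
  with(cfg, {
    if (width_um <= 0 || height_um <= 0) stop("field dimensions must be positive")
    if (mixing < 0 || mixing > 1) stop("mixing must lie in [0, 1]")
    if (replicate_keep <= 0 || replicate_keep > 1) {
      stop("replicate_keep must lie in (0, 1]")
    }
    if (replicate_add < 0) stop("replicate_add must be >= 0")
    if (jitter_sd < 0) stop("jitter_sd must be >= 0")
    rates <- c(nest_parent_rate, nest_offspring_mean, immune_rate,
               macrophage_rate, other_rate)
    if (any(rates < 0)) stop("all rates must be >= 0")
    if (2 * nest_radius >= min(width_um, height_um)) {
      stop("nest_radius too large for the field")
    }
    for (pn in names(marker_probs)) {
      for (cl in names(marker_probs[[pn]])) {
        p <- marker_probs[[pn]][[cl]]
        if (any(p < 0 | p > 1)) {
          stop("marker probabilities must lie in [0, 1] (panel ", pn,
               ", class ", cl, ")")
        }
      }
    }
  })
  structure(cfg, class = "sim_config")
}

#' Simulate complete spatial randomness (a homogeneous Poisson pattern)
#'
#' The null model of the pattern classifier: point count drawn from
#' `Poisson(intensity * area)`, positions i.i.d. uniform over the field.
#'
#' @param intensity points per square micron.
#' @param width_um,height_um field dimensions, microns.
#' @param seed optional seed (the caller's RNG state is preserved).
#' @return data.frame with columns `x_um`, `y_um`.
#' @export
simulate_csr <- function(intensity, width_um = 931, height_um = 698,
                         seed = NULL) {
  if (intensity < 0) stop("intensity must be >= 0")
  with_seed(seed, {
    n <- stats::rpois(1, intensity * width_um * height_um)
    data.frame(x_um = stats::runif(n, 0, width_um),
               y_um = stats::runif(n, 0, height_um))
  })
}

# Uniform points in a disc of radius r about (cx, cy).
runif_disc <- function(n, cx, cy, r) {
  rad <- r * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = cx + rad * cos(th), y = cy + rad * sin(th))
}

# Place n immune-type cells: probability m inside a random nest disc,
# otherwise uniform in the stromal complement of all discs (rejection).
place_with_mixing <- function(n, m, nests, width_um, height_um) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  has_nests <- nrow(nests) > 0L
  inside <- if (has_nests) stats::runif(n) < m else rep(FALSE, n)
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
  if (any(inside)) {
    k <- sum(inside)
    pick <- sample.int(nrow(nests), k, replace = TRUE)
    out[inside, ] <- runif_disc(k, nests$x[pick], nests$y[pick], nests$r[1])
  }
  todo <- which(!inside)
  guard <- 0L
  while (length(todo) > 0L) {
    guard <- guard + 1L
    if (guard > 1000L) stop("stromal rejection sampling failed to converge")
    px <- stats::runif(length(todo), 0, width_um)
    py <- stats::runif(length(todo), 0, height_um)
    ok <- rep(TRUE, length(todo))
    if (has_nests) {
      for (j in seq_len(nrow(nests))) {
        ok <- ok & ((px - nests$x[j])^2 + (py - nests$y[j])^2 > nests$r[1]^2)
      }
    }
    out[todo[ok], ] <- cbind(px[ok], py[ok])
    todo <- todo[!ok]
  }
  out
}

# Bernoulli marker matrix for n cells of one class under panel `probs`.
draw_markers <- function(n, probs) {
  m <- matrix(stats::runif(n * length(probs)) < rep(probs, each = n),
              nrow = n, ncol = length(probs))
  storage.mode(m) <- "integer"
  colnames(m) <- names(probs)
  m
}

#' Simulate one week-1 ROI frame
#'
#' Malignant cells arise from a Matern cluster process whose parents are
#' uniform on the inner field (inset by `nest_radius`, so nests lie wholly
#' inside the ROI and offspring counts are not censored); T cells and
#' macrophages follow the mixing rule; `other` cells are uniform.
#'
#' @param config a [sim_config()].
#' @param panel a [panel_spec()] naming the markers to score; its id must
#'   key into `config$marker_probs`.
#' @param sample_id,roi_id,timepoint identifiers for the frame.
#' @param sample_factors named multipliers (`malignant`, `tcell`,
#'   `macrophage`, `other`) for between-sample abundance heterogeneity.
#' @param seed optional seed.
#' @return a [cell_table()] with attributes `truth` (data.frame of
#'   `cell_id`, `class`) and `nests` (data.frame of nest centres and radius).
#' @export
simulate_roi <- function(config, panel, sample_id = "S1", roi_id = "R1",
                         timepoint = "week1",
                         sample_factors = c(malignant = 1, tcell = 1,
                                            macrophage = 1, other = 1),
                         seed = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "panel_spec"))
  probs <- config$marker_probs[[panel$panel_id]]
  if (is.null(probs)) {
    stop("no marker probabilities configured for panel ", panel$panel_id)
  }
  with_seed(seed, {
    W <- config$width_um; H <- config$height_um; R <- config$nest_radius
    n_parents <- stats::rpois(1, config$nest_parent_rate)
    nests <- data.frame(x = stats::runif(n_parents, R, W - R),
                        y = stats::runif(n_parents, R, H - R),
                        r = rep(R, n_parents))
    mal <- if (n_parents > 0L) {
      n_off <- stats::rpois(n_parents,
                            config$nest_offspring_mean * sample_factors[["malignant"]])
      idx <- rep(seq_len(n_parents), n_off)
      runif_disc(length(idx), nests$x[idx], nests$y[idx], R)
    } else cbind(x = numeric(0), y = numeric(0))
    n_t <- stats::rpois(1, config$immune_rate * sample_factors[["tcell"]])
    n_m <- stats::rpois(1, config$macrophage_rate * sample_factors[["macrophage"]])
    n_o <- stats::rpois(1, config$other_rate * sample_factors[["other"]])
    tc <- place_with_mixing(n_t, config$mixing, nests, W, H)
    mc <- place_with_mixing(n_m, config$mixing, nests, W, H)
    ot <- cbind(x = stats::runif(n_o, 0, W), y = stats::runif(n_o, 0, H))
    xy <- rbind(mal, tc, mc, ot)
    class <- rep(c("malignant", "tcell", "macrophage", "other"),
                 c(nrow(mal), nrow(tc), nrow(mc), nrow(ot)))
    mk <- rbind(draw_markers(nrow(mal), probs$malignant[panel$markers]),
                draw_markers(nrow(tc), probs$tcell[panel$markers]),
                draw_markers(nrow(mc), probs$macrophage[panel$markers]),
                draw_markers(nrow(ot), probs$other[panel$markers]))
    n <- nrow(xy)
    df <- data.frame(sample_id = sample_id, roi_id = roi_id,
                     timepoint = timepoint,
                     cell_id = sprintf("c%06d", seq_len(n)),
                     x_um = pmin(pmax(xy[, 1], 0), W),
                     y_um = pmin(pmax(xy[, 2], 0), H),
                     stringsAsFactors = FALSE, check.names = FALSE)
    df <- cbind(df, as.data.frame(mk, check.names = FALSE))
    ct <- cell_table(df, panel = panel, width_um = W, height_um = H)
    attr(ct, "truth") <- data.frame(cell_id = df$cell_id, class = class,
                                    stringsAsFactors = FALSE)
    attr(ct, "nests") <- nests
    ct
  })
}

#' Replicate a frame at a second timepoint
#'
#' Emulates re-staining a consecutive tissue section one week later: each
#' week-1 cell is retained with probability `q` (a cell's soma spans several
#' sections, but some fall out of the new cut), retained cells keep their
#' marker calls and are jittered by an isotropic Gaussian of sd `jitter_sd`
#' (clamped to the field), and `Poisson(epsilon * n)` new cells per class
#' appear from the same class-specific spatial model with fresh marker
#' draws. All week-2 cells receive fresh cell ids.
#'
#' @param frame a week-1 [cell_table()] from [simulate_roi()] (its `truth`
#'   and `nests` attributes drive the class-specific placement of additions).
#' @param config a [sim_config()] (`replicate_keep`, `replicate_add`,
#'   `jitter_sd`, `mixing`, marker probabilities).
#' @param panel the [panel_spec()] used to simulate `frame`.
#' @param timepoint label for the new frame (default `"week2"`).
#' @param seed optional seed.
#' @return a [cell_table()] with a `truth` attribute.
#' @export
replicate_timepoint <- function(frame, config, panel, timepoint = "week2",
                                seed = NULL) {
  stopifnot(inherits(frame, "cell_table"), inherits(config, "sim_config"))
  q <- config$replicate_keep
  eps <- config$replicate_add
  truth <- attr(frame, "truth")
  nests <- attr(frame, "nests")
  if (is.null(truth) || is.null(nests)) {
    stop("frame lacks generator truth/nests attributes")
  }
  probs <- config$marker_probs[[panel$panel_id]]
  with_seed(seed, {
    W <- attr(frame, "width_um"); H <- attr(frame, "height_um")
    keep <- stats::runif(nrow(frame)) < q
    df <- as.data.frame(frame)[keep, , drop = FALSE]
    cls <- truth$class[keep]
    if (config$jitter_sd > 0 && nrow(df) > 0L) {
      df$x_um <- pmin(pmax(df$x_um + stats::rnorm(nrow(df), 0, config$jitter_sd), 0), W)
      df$y_um <- pmin(pmax(df$y_um + stats::rnorm(nrow(df), 0, config$jitter_sd), 0), H)
    }
    add <- list()
    for (cl in c("malignant", "tcell", "macrophage", "other")) {
      n1 <- sum(truth$class == cl)
      n_new <- if (eps > 0) stats::rpois(1, eps * n1) else 0L
      if (n_new == 0L) next
      xy <- switch(cl,
        malignant = if (nrow(nests) > 0L) {
          pick <- sample.int(nrow(nests), n_new, replace = TRUE)
          runif_disc(n_new, nests$x[pick], nests$y[pick], nests$r[1])
        } else cbind(x = stats::runif(n_new, 0, W),
                     y = stats::runif(n_new, 0, H)),
        tcell = ,
        macrophage = place_with_mixing(n_new, config$mixing, nests, W, H),
        other = cbind(x = stats::runif(n_new, 0, W),
                      y = stats::runif(n_new, 0, H)))
      mk <- draw_markers(n_new, probs[[cl]][panel$markers])
      a <- data.frame(sample_id = frame$sample_id[1],
                      roi_id = frame$roi_id[1], timepoint = timepoint,
                      cell_id = NA_character_,
                      x_um = pmin(pmax(xy[, 1], 0), W),
                      y_um = pmin(pmax(xy[, 2], 0), H),
                      stringsAsFactors = FALSE, check.names = FALSE)
      a <- cbind(a, as.data.frame(mk, check.names = FALSE))
      add[[cl]] <- a
      cls <- c(cls, rep(cl, n_new))
    }
    out <- rbind(df, do.call(rbind, add))
    out$timepoint <- timepoint
    out$cell_id <- sprintf("c%06d", seq_len(nrow(out)))
    ct <- cell_table(out, panel = panel, width_um = W, height_um = H)
    attr(ct, "truth") <- data.frame(cell_id = out$cell_id, class = cls,
                                    stringsAsFactors = FALSE)
    attr(ct, "nests") <- nests
    ct
  })
}

#' Simulate a full two-timepoint cohort
#'
#' Generates the default study design — `n_samples` tumours x `n_rois` ROIs
#' x 2 timepoints — for each requested panel (separate consecutive sections
#' per panel, so geometry is independent across panels but per-sample
#' abundance factors are shared). Sub-stream seeds are derived from the
#' master seed per (sample, panel, ROI, timepoint) with [derive_seed()], so
#' any ROI can be regenerated in isolation.
#'
#' @param config a [sim_config()].
#' @param panels named list of [panel_spec()] (default all five).
#' @param seed master seed.
#' @return an object of class `mif_cohort`: list with `tables` (per panel:
#'   `week1` and `week2` [cell_table()]s spanning the whole cohort),
#'   `truth` (data.frame: panel, sample_id, roi_id, timepoint, cell_id,
#'   class), `config` and `seed`.
#' @export
simulate_cohort <- function(config = sim_config(), panels = default_panels(),
                            seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  factors <- with_seed(derive_seed(seed, "sample_factors"), {
    f <- matrix(stats::rlnorm(config$n_samples * 4,
                              meanlog = -config$sample_sd^2 / 2,
                              sdlog = config$sample_sd),
                nrow = config$n_samples)
    colnames(f) <- c("malignant", "tcell", "macrophage", "other")
    f
  })
  tables <- list()
  truth <- list()
  for (pn in names(panels)) {
    panel <- panels[[pn]]
    w1 <- list(); w2 <- list()
    for (s in seq_len(config$n_samples)) {
      sid <- sprintf("S%02d", s)
      for (r in seq_len(config$n_rois)) {
        rid <- sprintf("R%d", r)
        f1 <- simulate_roi(config, panel, sample_id = sid, roi_id = rid,
                           sample_factors = factors[s, ],
                           seed = derive_seed(seed, pn, s, r, 1))
        f2 <- replicate_timepoint(f1, config, panel,
                                  seed = derive_seed(seed, pn, s, r, 2))
        w1[[length(w1) + 1L]] <- f1
        w2[[length(w2) + 1L]] <- f2
        truth[[length(truth) + 1L]] <- data.frame(
          panel = pn,
          sample_id = sid, roi_id = rid,
          timepoint = c(f1$timepoint, f2$timepoint),
          cell_id = c(f1$cell_id, f2$cell_id),
          class = c(attr(f1, "truth")$class, attr(f2, "truth")$class),
          stringsAsFactors = FALSE)
      }
    }
    bind <- function(frames) {
      cell_table(do.call(rbind, lapply(frames, as.data.frame)),
                 panel = panel, width_um = config$width_um,
                 height_um = config$height_um)
    }
    tables[[pn]] <- list(week1 = bind(w1), week2 = bind(w2))
  }
  structure(list(tables = tables, truth = do.call(rbind, truth),
                 config = config, seed = seed),
            class = "mif_cohort")
}

#' @export
print.mif_cohort <- function(x, ...) {
  cat("synthetic mIF cohort: ", x$config$n_samples, " samples x ",
      x$config$n_rois, " ROIs x 2 timepoints, ",
      length(x$tables), " panel(s), master seed ", x$seed, "\n", sep = "")
  for (pn in names(x$tables)) {
    cat("  panel ", pn, ": ", nrow(x$tables[[pn]]$week1), " week-1 cells, ",
        nrow(x$tables[[pn]]$week2), " week-2 cells\n", sep = "")
  }
  invisible(x)
}
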
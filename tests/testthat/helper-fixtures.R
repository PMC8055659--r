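# Shared fixture builders and independent oracles.

# A minimal two-marker panel for hand-built tables.
toy_panel <- function(markers = c("CD3", "CD8"), id = "t") {
  rules <- lapply(markers, function(m) paste0(m, "+"))
  panel_spec(id, markers, rules)
}

# Drop auxiliary attributes (generator truth, read reports) for content
# comparisons.
strip_attrs <- function(df) {
  df <- as.data.frame(df)
  attributes(df) <- attributes(df)[c("names", "class", "row.names")]
  df
}

# Hand-build a cell table from vectors (single frame by default).
make_ct <- function(x, y, markers = list(), sample_id = "S1", roi_id = "R1",
                    timepoint = "week1", width = 931, height = 698,
                    cell_id = sprintf("c%03d", seq_along(x))) {
  n <- length(x)
  df <- data.frame(sample_id = rep_len(sample_id, n),
                   roi_id = rep_len(roi_id, n),
                   timepoint = rep_len(timepoint, n),
                   cell_id = cell_id,
                   x_um = x, y_um = y, stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (m in names(markers)) df[[m]] <- as.integer(markers[[m]])
  cell_table(df, width_um = width, height_um = height)
}

# Exhaustive O(n^2) nearest-neighbour oracle (squared-distance minimum,
# then sqrt, matching IEEE arithmetic of the implementation's candidates).
bf_nn <- function(ref, target, ref_ids = NULL, target_ids = NULL) {
  out <- numeric(nrow(ref))
  for (i in seq_len(nrow(ref))) {
    best <- Inf
    for (j in seq_len(nrow(target))) {
      if (!is.null(ref_ids) && ref_ids[i] == target_ids[j]) next
      d2 <- (ref[i, 1] - target[j, 1])^2 + (ref[i, 2] - target[j, 2])^2
      if (d2 < best) best <- d2
    }
    out[i] <- sqrt(best)
  }
  out
}

# Naive per-cell rule membership oracle (loops, no vectorisation).
bf_members <- function(ct, rule) {
  vapply(seq_len(nrow(ct)), function(i) {
    all(vapply(rule$positive, function(m) ct[[m]][i] == 1L, logical(1))) &&
      all(vapply(rule$negative, function(m) ct[[m]][i] == 0L, logical(1)))
  }, logical(1))
}

# Small simulated two-timepoint cohort for pipeline-level tests.
mini_cohort <- function(seed = 7, n_samples = 2, n_rois = 3, mixing = 0.5,
                        panels = default_panels(1)) {
  cfg <- sim_config(n_samples = n_samples, n_rois = n_rois, mixing = mixing,
                    nest_parent_rate = 4, nest_offspring_mean = 80,
                    immune_rate = 120, macrophage_rate = 30, other_rate = 150)
  simulate_cohort(cfg, panels, seed = seed)
}
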
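#' Canonical per-cell tables
#'
#' The canonical cell-seg dialect is a UTF-8 CSV with header
#' `sample_id,roi_id,timepoint,cell_id,x_um,y_um,<marker1>,<marker2>,...`;
#' one file may hold many ROIs. Coordinates follow the image convention:
#' origin at the top-left of the ROI, y increasing downward, continuous
#' microns. Marker positivity is canonically `{0,1}`; the reader also
#' accepts `pos`/`neg`, `+`/`-`, `TRUE`/`FALSE` and `yes`/`no`.
#'
#' A `cell_table` is a `data.frame` in this dialect carrying the ROI field
#' dimensions (`width_um`, `height_um`) as attributes; every segmented cell
#' is assumed nucleated (DAPI+), so a frame's total cell count is its DAPI+
#' count. Coordinates are stored at micro-micron (1e-6 um) resolution so
#' that writing and re-reading a table is the identity.
#'
#' @name cell_table
NULL

CELL_COLS <- c("sample_id", "roi_id", "timepoint", "cell_id", "x_um", "y_um")

#' Construct and validate a cell table
#'
#' @param df data.frame with the canonical columns followed by one 0/1
#'   column per marker.
#' @param panel optional [panel_spec()]; when given, every declared marker
#'   must be present as a column.
#' @param width_um,height_um ROI field dimensions in microns (default the
#'   931 x 698 um scan field, area 0.650 mm^2).
#' @param validate run invariant checks (coordinates within the field,
#'   unique cell ids per frame, marker values in `{0,1}`).
#' @return an object of class `cell_table` (a data.frame).
#' @export
cell_table <- function(df, panel = NULL, width_um = 931, height_um = 698,
                       validate = TRUE) {
  stopifnot(is.data.frame(df))
  if (width_um <= 0 || height_um <= 0) {
    stop("ROI dimensions must be strictly positive")
  }
  missing <- setdiff(CELL_COLS, names(df))
  if (length(missing) > 0L) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  markers <- setdiff(names(df), CELL_COLS)
  df <- df[, c(CELL_COLS, markers), drop = FALSE]
  for (cc in c("sample_id", "roi_id", "timepoint", "cell_id")) {
    df[[cc]] <- as.character(df[[cc]])
  }
  df$x_um <- round(as.numeric(df$x_um), 6)
  df$y_um <- round(as.numeric(df$y_um), 6)
  for (mk in markers) df[[mk]] <- as.integer(df[[mk]])
  rownames(df) <- NULL
  out <- structure(df, width_um = width_um, height_um = height_um,
                   class = c("cell_table", "data.frame"))
  if (validate) validate_cell_table(out, panel = panel)
  out
}

#' Validate a cell table against its invariants
#'
#' @param ct a [cell_table()].
#' @param panel optional [panel_spec()] whose markers must all be present.
#' @return `ct`, invisibly; stops on violation.
#' @export
validate_cell_table <- function(ct, panel = NULL) {
  w <- attr(ct, "width_um")
  h <- attr(ct, "height_um")
  if (is.null(w) || is.null(h)) stop("cell table lacks ROI dimensions")
  if (nrow(ct) > 0L) {
    if (anyNA(ct$x_um) || anyNA(ct$y_um)) stop("non-numeric coordinates")
    if (any(ct$x_um < 0 | ct$x_um > w)) {
      stop("x coordinates outside [0, ", w, "] um")
    }
    if (any(ct$y_um < 0 | ct$y_um > h)) {
      stop("y coordinates outside [0, ", h, "] um")
    }
    dup <- duplicated(paste(frame_key(ct), ct$cell_id, sep = "\r"))
    if (any(dup)) {
      stop("duplicate cell_id within a frame: ",
           paste(utils::head(unique(ct$cell_id[dup]), 5), collapse = ", "))
    }
  }
  for (mk in cell_table_markers(ct)) {
    v <- ct[[mk]]
    if (anyNA(v) || !all(v %in% c(0L, 1L))) {
      stop("marker column '", mk, "' must be 0/1")
    }
  }
  if (!is.null(panel)) {
    miss <- setdiff(panel$markers, cell_table_markers(ct))
    if (length(miss) > 0L) {
      stop("cell table lacks marker column(s) declared by panel ",
           panel$panel_id, ": ", paste(miss, collapse = ", "))
    }
  }
  invisible(ct)
}

#' Marker columns of a cell table
#' @param ct a [cell_table()].
#' @return character vector of marker column names.
#' @export
cell_table_markers <- function(ct) setdiff(names(ct), CELL_COLS)

# (sample, roi, timepoint) grouping key, one string per row.
frame_key <- function(ct) {
  paste(ct$sample_id, ct$roi_id, ct$timepoint, sep = "\r")
}

#' Split a cell table into per-ROI frames
#' @param ct a [cell_table()].
#' @return named list of `cell_table` objects, one per
#'   (sample, roi, timepoint) frame.
#' @export
split_frames <- function(ct) {
  key <- frame_key(ct)
  idx <- split(seq_len(nrow(ct)), key)
  idx <- idx[unique(key)]  # preserve first-appearance order
  lapply(idx, function(i) {
    cell_table(as.data.frame(ct)[i, , drop = FALSE],
               width_um = attr(ct, "width_um"),
               height_um = attr(ct, "height_um"), validate = FALSE)
  })
}

#' @export
print.cell_table <- function(x, ...) {
  cat("cell_table: ", nrow(x), " cells, ",
      length(unique(frame_key(x))), " frame(s), field ",
      attr(x, "width_um"), " x ", attr(x, "height_um"), " um (",
      format(roi_area_mm2(attr(x, "width_um"), attr(x, "height_um")),
             digits = 6), " mm^2)\n", sep = "")
  cat("markers: ", paste(cell_table_markers(x), collapse = ", "), "\n",
      sep = "")
  rej <- attr(x, "rejected")
  if (!is.null(rej) && nrow(rej) > 0L) {
    cat("rejected rows on read: ", nrow(rej), "\n", sep = "")
  }
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}

# Header synonyms accepted by the tolerant reader (vendor-style exports).
.header_synonyms <- list(
  sample_id = c("sample_id", "sample", "sample name", "sample id"),
  roi_id    = c("roi_id", "roi", "region", "region id", "annotation id"),
  timepoint = c("timepoint", "time point", "week", "batch"),
  cell_id   = c("cell_id", "cell id", "object id"),
  x_um      = c("x_um", "x", "cell x position", "x position"),
  y_um      = c("y_um", "y", "cell y position", "y position")
)

normalize_header <- function(nm) {
  canon <- tolower(trimws(nm))
  out <- nm
  for (target in names(.header_synonyms)) {
    hit <- canon %in% .header_synonyms[[target]]
    if (sum(hit) > 1L) stop("multiple columns map to '", target, "'")
    out[hit] <- target
  }
  out
}

# Map tolerant positivity encodings to integer 0/1 (NA if unrecognised).
parse_positivity <- function(v) {
  s <- tolower(trimws(as.character(v)))
  s <- gsub("−", "-", s)
  pos <- s %in% c("1", "pos", "positive", "+", "true", "t", "yes")
  neg <- s %in% c("0", "neg", "negative", "-", "false", "f", "no")
  ifelse(pos, 1L, ifelse(neg, 0L, NA_integer_))
}

#' Read a per-cell table
#'
#' Reads a canonical (or tolerant-synonym) cell-seg CSV, validates it and
#' returns a [cell_table()]. Rows with unparseable coordinates, coordinates
#' outside the ROI field, or unrecognised marker values are rejected — never
#' silently: each rejection is reported with its file line number and reason
#' via `message()` and tallied in the `rejected` attribute. A missing
#' mandatory column or a duplicated `cell_id` within one frame is an error.
#'
#' @param path path to a CSV file.
#' @param panel optional [panel_spec()]; all declared markers must be
#'   present as columns.
#' @param width_um,height_um ROI field dimensions in microns.
#' @param quiet suppress per-row rejection messages.
#' @return a [cell_table()] with attribute `rejected` (data.frame with
#'   columns `line`, `reason`).
#' @export
read_cell_table <- function(path, panel = NULL, width_um = 931,
                            height_um = 698, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", blank.lines.skip = FALSE)
  names(raw) <- normalize_header(names(raw))
  missing <- setdiff(CELL_COLS, names(raw))
  if (length(missing) > 0L) {
    stop("format error in ", path, ": missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  markers <- setdiff(names(raw), CELL_COLS)
  if (!is.null(panel)) {
    miss <- setdiff(panel$markers, markers)
    if (length(miss) > 0L) {
      stop("format error in ", path, ": missing marker column(s): ",
           paste(miss, collapse = ", "))
    }
  }
  lines <- seq_len(nrow(raw)) + 1L  # +1 for the header line
  x <- suppressWarnings(as.numeric(raw$x_um))
  y <- suppressWarnings(as.numeric(raw$y_um))
  reasons <- rep(NA_character_, nrow(raw))
  reasons[is.na(x) | is.na(y)] <- "non-numeric coordinate"
  oob <- !is.na(x) & !is.na(y) &
    (x < 0 | x > width_um | y < 0 | y > height_um)
  reasons[oob & is.na(reasons)] <- "coordinate outside ROI field"
  mk <- lapply(raw[markers], parse_positivity)
  if (length(markers) > 0L) {
    badmk <- Reduce(`|`, lapply(mk, is.na))
    reasons[badmk & is.na(reasons)] <- "unrecognised marker value"
  }
  keep <- is.na(reasons)
  rejected <- data.frame(line = lines[!keep], reason = reasons[!keep],
                         stringsAsFactors = FALSE)
  if (!quiet && nrow(rejected) > 0L) {
    for (i in seq_len(nrow(rejected))) {
      message("read_cell_table: rejected line ", rejected$line[i], ": ",
              rejected$reason[i])
    }
    message("read_cell_table: ", sum(keep), " row(s) kept, ",
            nrow(rejected), " rejected")
  }
  df <- data.frame(sample_id = raw$sample_id[keep],
                   roi_id = raw$roi_id[keep],
                   timepoint = raw$timepoint[keep],
                   cell_id = raw$cell_id[keep],
                   x_um = x[keep], y_um = y[keep],
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (m in markers) df[[m]] <- mk[[m]][keep]
  ct <- cell_table(df, panel = panel, width_um = width_um,
                   height_um = height_um)
  attr(ct, "rejected") <- rejected
  ct
}

#' Write a cell table in the canonical dialect
#'
#' Coordinates are written with six decimals (micro-micron resolution), the
#' precision at which [cell_table()] stores them, so
#' `read_cell_table(write_cell_table(ct))` reproduces `ct` exactly.
#'
#' @param ct a [cell_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(ct, path) {
  validate_cell_table(ct)
  df <- as.data.frame(ct)
  df$x_um <- sprintf("%.6f", df$x_um)
  df$y_um <- sprintf("%.6f", df$y_um)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write cell table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Merge per-marker cell tables on cell coordinates
#'
#' Image-analysis exports score one marker per table; co-expression
#' phenotyping needs them merged cell-by-cell. Cells are matched within a
#' (sample, roi, timepoint) frame when their coordinates, rounded to
#' `round_to` microns, agree exactly — the segmentation is shared across the
#' per-marker runs, so matching cells carry identical coordinates up to
#' export rounding. Cells present in some inputs but not all are dropped and
#' tallied per input in the `merge_report` attribute; two cells of one input
#' that collide on a rounded coordinate within a frame are an ambiguity
#' error (never a silent guess).
#'
#' Merged cells take their `cell_id` from the first input table; marker
#' columns are sorted by name and rows ordered by frame and coordinate so
#' the cell content of the result does not depend on input order.
#'
#' @param tables list of [cell_table()] objects, each carrying exactly one
#'   marker column; all must share the same (sample, roi, timepoint) frames.
#' @param round_to coordinate rounding used for the exact-match join, in
#'   microns (default 0.1).
#' @return a merged [cell_table()] with attribute `merge_report`: per-input
#'   list of `n_rows`, `n_matched`, `n_dropped`.
#' @export
merge_marker_tables <- function(tables, round_to = 0.1) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  nm <- names(tables) %||% paste0("table", seq_along(tables))
  nm[!nzchar(nm)] <- paste0("table", which(!nzchar(nm)))
  for (i in seq_along(tables)) {
    mks <- cell_table_markers(tables[[i]])
    if (length(mks) != 1L) {
      stop("input '", nm[i], "' must carry exactly one marker column, has: ",
           paste(mks, collapse = ", "))
    }
  }
  frame_sets <- lapply(tables, function(t) unique(frame_key(t)))
  common <- Reduce(intersect, frame_sets)
  if (length(common) == 0L) {
    stop("no (sample, roi, timepoint) frame is shared by all inputs")
  }
  dec <- max(0L, -floor(log10(round_to) + 1e-9))
  keys <- lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    k <- paste(frame_key(t),
               sprintf("%.*f", dec, round(t$x_um / round_to) * round_to),
               sprintf("%.*f", dec, round(t$y_um / round_to) * round_to),
               sep = "\r")
    dup <- duplicated(k) & frame_key(t) %in% common
    if (any(dup)) {
      stop("ambiguity in input '", nm[i], "': two cells within ", round_to,
           " um of each other in frame ",
           gsub("\r", "/", frame_key(t)[which(dup)[1]]))
    }
    k
  })
  in_common <- lapply(tables, function(t) frame_key(t) %in% common)
  shared <- Reduce(intersect, lapply(seq_along(keys),
                                     function(i) keys[[i]][in_common[[i]]]))
  report <- list()
  for (i in seq_along(tables)) {
    n <- nrow(tables[[i]])
    matched <- sum(keys[[i]] %in% shared)
    report[[nm[i]]] <- list(n_rows = n, n_matched = matched,
                            n_dropped = n - matched)
  }
  base <- tables[[1L]]
  sel <- match(shared, keys[[1L]])
  out <- as.data.frame(base)[sel, CELL_COLS, drop = FALSE]
  marker_cols <- list()
  for (i in seq_along(tables)) {
    mk <- cell_table_markers(tables[[i]])
    marker_cols[[mk]] <- tables[[i]][[mk]][match(shared, keys[[i]])]
  }
  for (mk in sort(names(marker_cols))) out[[mk]] <- marker_cols[[mk]]
  ord <- order(out$sample_id, out$roi_id, out$timepoint, out$x_um, out$y_um)
  out <- out[ord, , drop = FALSE]
  ct <- cell_table(out, width_um = attr(base, "width_um"),
                   height_um = attr(base, "height_um"))
  attr(ct, "merge_report") <- report
  ct
}
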
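#' Phenotype co-expression rules and panel specifications
#'
#' A phenotype rule names a cell population by the markers it must express
#' (`positive`) and, optionally, markers it must not express (`negative`),
#' e.g. `CD3+CD8+` (cytotoxic T cell) or `CD3+FOXP3+CD8-` (regulatory T
#' cell). Markers not mentioned by a rule are "don't care": membership is
#' non-exclusive, so a `CD3+CD8+` cell is also `CD3+`.
#'
#' @param name display name of the phenotype, conventionally the marker
#'   string itself (e.g. `"CD3+CD8+"`).
#' @param positive character vector of markers that must be positive
#'   (non-empty).
#' @param negative character vector of markers that must be negative
#'   (may be empty).
#' @param label optional free-text description (e.g. "Cytotoxic T-cells").
#' @return an object of class `phenotype_rule`.
#' @export
phenotype_rule <- function(name, positive, negative = character(), label = "") {
  positive <- as.character(positive)
  negative <- as.character(negative)
  if (length(positive) == 0L) {
    stop("phenotype rule '", name, "': at least one positive marker required")
  }
  if (length(intersect(positive, negative)) > 0L) {
    stop("phenotype rule '", name, "': markers ",
         paste(intersect(positive, negative), collapse = ", "),
         " listed as both positive and negative")
  }
  structure(
    list(name = as.character(name), positive = positive,
         negative = negative, label = as.character(label)),
    class = "phenotype_rule"
  )
}

#' Parse a marker string such as "CD3+FOXP3+CD8-" into a rule
#'
#' Marker names themselves may contain hyphens (PD-1, B7-H3, Arg-1), so the
#' string is parsed by greedy longest-first matching against the panel's
#' declared marker list, each marker followed by a `+` or `-` sign.
#'
#' @param spec the marker string.
#' @param markers declared marker names to match against.
#' @param label optional description.
#' @return a [phenotype_rule()].
#' @export
parse_phenotype <- function(spec, markers, label = "") {
  rest <- gsub("−", "-", trimws(spec))  # tolerate unicode minus
  markers_by_len <- markers[order(nchar(markers), decreasing = TRUE)]
  pos <- character()
  neg <- character()
  while (nzchar(rest)) {
    hit <- NULL
    for (mk in markers_by_len) {
      if (startsWith(rest, mk) &&
          substr(rest, nchar(mk) + 1L, nchar(mk) + 1L) %in% c("+", "-")) {
        hit <- mk
        break
      }
    }
    if (is.null(hit)) {
      stop("cannot parse phenotype '", spec, "': no declared marker matches '",
           rest, "' (declared: ", paste(markers, collapse = ", "), ")")
    }
    sign <- substr(rest, nchar(hit) + 1L, nchar(hit) + 1L)
    if (sign == "+") pos <- c(pos, hit) else neg <- c(neg, hit)
    rest <- substr(rest, nchar(hit) + 2L, nchar(rest))
  }
  phenotype_rule(spec, pos, neg, label = label)
}

#' Construct a panel specification
#'
#' A panel is an ordered marker list plus the collection of phenotype rules
#' scored on it. Every rule marker must be declared and rule names must be
#' unique within the panel.
#'
#' @param panel_id panel identifier (1-5 for the shipped defaults).
#' @param markers ordered character vector of marker names (DAPI is implicit:
#'   every segmented cell is nucleated and counts toward the denominator).
#' @param rules list of [phenotype_rule()] objects, or character marker
#'   strings parsed with [parse_phenotype()].
#' @param name optional panel description.
#' @return an object of class `panel_spec`.
#' @export
panel_spec <- function(panel_id, markers, rules, name = "") {
  markers <- as.character(markers)
  if (anyDuplicated(markers)) stop("duplicate marker names in panel")
  rules <- lapply(rules, function(r) {
    if (inherits(r, "phenotype_rule")) r else parse_phenotype(r, markers)
  })
  nm <- vapply(rules, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate phenotype names in panel: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  for (r in rules) {
    bad <- setdiff(c(r$positive, r$negative), markers)
    if (length(bad) > 0L) {
      stop("rule '", r$name, "' references undeclared marker(s): ",
           paste(bad, collapse = ", "))
    }
  }
  structure(
    list(panel_id = as.character(panel_id), name = as.character(name),
         markers = markers, rules = rules),
    class = "panel_spec"
  )
}

#' @export
print.panel_spec <- function(x, ...) {
  cat("mIF panel ", x$panel_id,
      if (nzchar(x$name)) paste0(" (", x$name, ")"), "\n", sep = "")
  cat("  markers: ", paste(x$markers, collapse = ", "), "\n", sep = "")
  cat("  phenotypes (", length(x$rules), "):\n", sep = "")
  for (r in x$rules) {
    cat("    ", format(r$name, width = 28), r$label, "\n", sep = "")
  }
  invisible(x)
}

#' Read a panel definition file
#'
#' Panel definitions are YAML files with fields `panel`, `name`, `markers`
#' and `phenotypes` (a list of `rule` marker strings with optional `label`).
#' The five default immuno-oncology panels are shipped under
#' `system.file("extdata/panels", package = "mifspatial")`.
#'
#' @param path path to a YAML panel file.
#' @return a [panel_spec()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  y <- yaml::read_yaml(path)
  for (f in c("panel", "markers", "phenotypes")) {
    if (is.null(y[[f]])) stop("panel file ", path, ": missing field '", f, "'")
  }
  markers <- as.character(unlist(y$markers))
  rules <- lapply(y$phenotypes, function(p) {
    parse_phenotype(p$rule, markers, label = p$label %||% "")
  })
  panel_spec(y$panel, markers, rules, name = y$name %||% "")
}

#' The five default immuno-oncology panels
#'
#' Returns the shipped panel specifications: panel 1 (PD-1/PD-L1 axis:
#' CK, CD3, CD8, PD-1, PD-L1, CD68), panel 2 (T-cell activation/regulation:
#' CK, CD3, CD8, CD45RO, GZB, FOXP3), panel 3 (immune checkpoints on
#' malignant cells: CK, CD3, PD-L1, B7-H3, B7-H4, IDO-1, CD68), panel 4
#' (T-cell co-stimulatory/inhibitory checkpoints: CK, CD3, ICOS, LAG3,
#' OX40, TIM3, VISTA) and panel 5 (myeloid/MDSC: CK, Arg-1, CD11b, CD14,
#' CD33, CD66b, CD68), with every published phenotype row encoded as a
#' non-exclusive co-expression rule.
#'
#' @param ids which panels to return (subset of 1:5).
#' @return a named list of [panel_spec()] objects ("1".."5").
#' @export
default_panels <- function(ids = 1:5) {
  dir <- system.file("extdata", "panels", package = "mifspatial")
  out <- lapply(ids, function(i) read_panel(file.path(dir, sprintf("panel%d.yaml", i))))
  names(out) <- as.character(ids)
  out
}
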
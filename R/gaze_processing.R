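# Fixation parsing, ROI assignment, per-joint aggregation -------------------

fixation_cols <- c("t_start_ms", "x", "y", "duration_ms")

#' Read a fixation export file
#'
#' Parses the tab-separated fixation dialect (`t_start_ms`, `x`, `y`,
#' `duration_ms`). Malformed rows fail loudly with their row number; events
#' are returned in time order.
#'
#' @param path Path to a file written by [write_fixation_export()] or any
#'   export in the same dialect.
#' @return A fixation stream tibble.
#' @export
read_fixation_export <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(fixation_cols, names(df))
  if (length(missing) > 0L) {
    stop("fixation export is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[, fixation_cols, drop = FALSE]
  if (nrow(df) == 0L) {
    return(tibble::tibble(t_start_ms = integer(), x = integer(),
                          y = integer(), duration_ms = integer()))
  }
  num <- lapply(df, function(col) suppressWarnings(as.numeric(col)))
  bad <- Reduce(`|`, lapply(num, function(v) !is.finite(v)))
  if (any(bad)) {
    stop("non-numeric field in fixation export at data row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  if (any(num$duration_ms <= 0)) {
    stop("non-positive duration_ms in fixation export at data row(s): ",
         paste(which(num$duration_ms <= 0), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    t_start_ms = as.integer(num$t_start_ms),
    x = as.integer(num$x),
    y = as.integer(num$y),
    duration_ms = as.integer(num$duration_ms)
  )
  out[order(out$t_start_ms), ]
}

#' Write / read an ROI layout as JSON
#'
#' The layout is a list of circles `{site_id, cx, cy, radius}` on the canvas.
#'
#' @param layout An `roi_layout` tibble (see [build_roi_layout()]).
#' @param path File path.
#' @return `write_roi_layout()`: `path`, invisibly. `read_roi_layout()`: an
#'   `roi_layout` tibble.
#' @export
write_roi_layout <- function(layout, path) {
  stopifnot(all(c("site_id", "cx", "cy", "radius") %in% names(layout)))
  jsonlite::write_json(as.data.frame(layout), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_roi_layout
#' @export
read_roi_layout <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  validate_roi_layout(df)
}

#' Validate an ROI layout
#'
#' Checks the layout invariants (non-empty, unique site ids, positive radii)
#' and stamps the `roi_layout` class.
#'
#' @param layout A data frame with `site_id`, `cx`, `cy`, `radius`.
#' @return The validated `roi_layout`.
#' @export
validate_roi_layout <- function(layout) {
  stopifnot(all(c("site_id", "cx", "cy", "radius") %in% names(layout)))
  if (nrow(layout) == 0L) stop("ROI layout is empty", call. = FALSE)
  if (anyDuplicated(layout$site_id)) {
    stop("duplicate site_id in ROI layout", call. = FALSE)
  }
  if (any(layout$radius <= 0)) stop("ROI radii must be > 0", call. = FALSE)
  if (!inherits(layout, "roi_layout")) {
    class(layout) <- c("roi_layout", class(layout))
  }
  layout
}

#' Assign fixations to joint ROIs
#'
#' A fixation whose point lies inside exactly one ROI (closed disc:
#' distance <= radius) contributes its duration to that joint. A fixation
#' inside two or more ROIs cannot be attributed -- the situation of two
#' pathological joints too close together -- and marks all those joints
#' non-analyzable for this reading (sticky: the flag is never cleared, and
#' ambiguous durations are not counted). Fixations outside every ROI are
#' background and are discarded.
#'
#' @param stream A fixation stream.
#' @param layout An ROI layout; every layout site appears exactly once in the
#'   result, in layout order.
#' @return A tibble `site_id, total_fixation_ms, n_fixations, analyzable`.
#' @export
assign_fixations <- function(stream, layout) {
  layout <- validate_roi_layout(layout)
  n_site <- nrow(layout)
  total <- rep(0, n_site)
  nfix <- rep(0L, n_site)
  analyzable <- rep(TRUE, n_site)
  if (nrow(stream) > 0L) {
    dx <- outer(stream$x, layout$cx, `-`)
    dy <- outer(stream$y, layout$cy, `-`)
    inside <- (dx * dx + dy * dy) <=
      matrix(layout$radius^2, nrow(stream), n_site, byrow = TRUE)
    hits <- rowSums(inside)
    uniq <- which(hits == 1L)
    if (length(uniq) > 0L) {
      site_of <- max.col(inside[uniq, , drop = FALSE], ties.method = "first")
      total <- total + as.vector(tapply(stream$duration_ms[uniq],
                                        factor(site_of, levels = seq_len(n_site)),
                                        sum, default = 0))
      nfix <- nfix + as.integer(table(factor(site_of, levels = seq_len(n_site))))
    }
    multi <- which(hits >= 2L)
    if (length(multi) > 0L) {
      flagged <- colSums(inside[multi, , drop = FALSE]) > 0
      analyzable[flagged] <- FALSE
    }
  }
  tibble::tibble(
    site_id = layout$site_id,
    total_fixation_ms = as.numeric(total),
    n_fixations = nfix,
    analyzable = analyzable
  )
}

#' Tabulate per-joint fixation durations
#'
#' Validates and returns the per-site summary table (one row per site, totals
#' additive over the assigned fixations, non-analyzable rows retained with
#' their flag).
#'
#' @param summaries Output of [assign_fixations()], or several such tables
#'   row-bound for distinct sites.
#' @return A tibble `site_id, total_fixation_ms, analyzable` (plus
#'   `n_fixations` if present).
#' @export
summarize_durations <- function(summaries) {
  stopifnot(all(c("site_id", "total_fixation_ms", "analyzable") %in%
                  names(summaries)))
  if (anyDuplicated(summaries$site_id)) {
    stop("duplicate site_id in summaries", call. = FALSE)
  }
  stopifnot(all(summaries$total_fixation_ms >= 0))
  tibble::as_tibble(summaries)
}

#' Write a per-site summary CSV
#'
#' Header `site_id,total_fixation_ms,n_fixations,analyzable`.
#'
#' @param summaries Output of [assign_fixations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_summary_csv <- function(summaries, path) {
  cols <- c("site_id", "total_fixation_ms", "n_fixations", "analyzable")
  stopifnot(all(cols %in% names(summaries)))
  utils::write.csv(summaries[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
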
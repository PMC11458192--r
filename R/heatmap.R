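# Heatmaps, gaze plots, severity colours ------------------------------------

#' Severity colour class of an integer Sharp score
#'
#' Joints are coloured green when the score is below 1, yellow at exactly 1,
#' and orange-to-red at 2 or more.
#'
#' @param score Integer score(s) >= 0.
#' @return Factor with levels `green`, `yellow`, `orange_red`.
#' @export
color_class <- function(score) {
  stopifnot(all(score >= 0))
  lab <- ifelse(score < 1, "green", ifelse(score == 1, "yellow", "orange_red"))
  factor(lab, levels = c("green", "yellow", "orange_red"))
}

#' Display colours for the severity classes
#'
#' @return Named character vector of hex colours for the levels of
#'   [color_class()].
#' @export
class_colors <- function() {
  c(green = "#2ECC40", yellow = "#FFDC00", orange_red = "#FF4136")
}

#' Render a fixation-duration heatmap
#'
#' Each fixation deposits mass proportional to its duration through an
#' isotropic Gaussian kernel centred at its (x, y) position, on a
#' pixel grid of the given size. The grid is max-normalized for display;
#' `normalize = FALSE` keeps the raw duration-weighted mass (used by the mass
#' conservation checks). An empty stream yields an all-zero grid.
#'
#' @param stream Fixation stream tibble.
#' @param width,height Grid size in pixels.
#' @param kernel_sigma Kernel standard deviation in pixels (default 15).
#' @param normalize Divide by the maximum value (unless all-zero)?
#' @return An `intensity_grid`: list with `width`, `height`, `values` (a
#'   `height` x `width` matrix, row = y), and `normalized`.
#' @export
render_heatmap <- function(stream, width, height, kernel_sigma = 15,
                           normalize = TRUE) {
  stopifnot(width > 0, height > 0, kernel_sigma > 0)
  values <- matrix(0, nrow = height, ncol = width)
  if (nrow(stream) > 0L) {
    half <- ceiling(5 * kernel_sigma)
    for (i in seq_len(nrow(stream))) {
      cx <- stream$x[i]
      cy <- stream$y[i]
      xs <- max(0, floor(cx - half)):min(width - 1, ceiling(cx + half))
      ys <- max(0, floor(cy - half)):min(height - 1, ceiling(cy + half))
      if (length(xs) == 0L || length(ys) == 0L) next
      kx <- stats::dnorm(xs, cx, kernel_sigma)
      ky <- stats::dnorm(ys, cy, kernel_sigma)
      values[ys + 1, xs + 1] <- values[ys + 1, xs + 1] +
        stream$duration_ms[i] * (ky %o% kx)
    }
  }
  mx <- max(values)
  if (normalize && mx > 0) values <- values / mx
  structure(
    list(width = as.integer(width), height = as.integer(height),
         values = values, normalized = normalize && mx > 0),
    class = "intensity_grid"
  )
}

#' Dump an intensity grid as a plain-text matrix
#'
#' Tab-separated values, one grid row (one y) per line.
#'
#' @param grid An `intensity_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_grid <- function(grid, path) {
  stopifnot(inherits(grid, "intensity_grid"))
  utils::write.table(grid$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an intensity grid as a PNG image
#'
#' Maps normalized intensity through a cold-to-hot ramp (transparent-free
#' grayscale-independent RGB) and writes a PNG without needing a graphics
#' device.
#'
#' @param grid An `intensity_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(grid, path) {
  stopifnot(inherits(grid, "intensity_grid"))
  v <- grid$values
  if (max(v) > 0) v <- v / max(v)
  ramp <- grDevices::colorRamp(c("#00304A", "#2ECC40", "#FFDC00", "#FF4136"))
  rgb <- ramp(as.vector(v)) / 255
  img <- array(0, dim = c(grid$height, grid$width, 3))
  img[, , 1] <- matrix(rgb[, 1], grid$height, grid$width)
  img[, , 2] <- matrix(rgb[, 2], grid$height, grid$width)
  img[, , 3] <- matrix(rgb[, 3], grid$height, grid$width)
  png::writePNG(img, path)
  invisible(path)
}

#' Ordered gaze plot of a fixation stream
#'
#' Fixations become circles in temporal order; the diameter is proportional
#' to the fixation duration (`diameter = px_per_ms * duration_ms`).
#'
#' @param stream Fixation stream tibble.
#' @param px_per_ms Diameter scale in pixels per millisecond (default 0.02,
#'   i.e. a 2 s fixation draws a 40 px circle).
#' @return A tibble `order_index, x, y, diameter`, sorted by onset time.
#' @export
render_gaze_plot <- function(stream, px_per_ms = 0.02) {
  stopifnot(px_per_ms > 0)
  if (nrow(stream) == 0L) {
    return(tibble::tibble(order_index = integer(), x = integer(),
                          y = integer(), diameter = numeric()))
  }
  ord <- order(stream$t_start_ms)
  tibble::tibble(
    order_index = seq_along(ord),
    x = stream$x[ord],
    y = stream$y[ord],
    diameter = px_per_ms * stream$duration_ms[ord]
  )
}

#' Severity overlay of joint scores on the ROI layout
#'
#' Colours each joint's ROI by its severity class and labels it with the
#' integer score, mirroring the annotated radiograph figures produced by
#' eye-tracking software.
#'
#' @param scores Score table with `site_id` and `score` (e.g. from
#'   [score_reading()]).
#' @param layout ROI layout containing every scored site.
#' @param file Optional path; when given, the plot is written there as PNG.
#' @return A list with `data` (tibble `site_id, cx, cy, radius, score,
#'   color_class, color`) and `plot` (a ggplot object, y-axis flipped to
#'   image coordinates).
#' @export
render_score_overlay <- function(scores, layout, file = NULL) {
  layout <- validate_roi_layout(layout)
  idx <- match(scores$site_id, layout$site_id)
  if (anyNA(idx)) {
    stop("site(s) not in layout: ",
         paste(scores$site_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  cls <- color_class(scores$score)
  dat <- tibble::tibble(
    site_id = scores$site_id,
    cx = layout$cx[idx],
    cy = layout$cy[idx],
    radius = layout$radius[idx],
    score = scores$score,
    color_class = cls,
    color = unname(class_colors()[as.character(cls)])
  )
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = cx, y = cy)) +
    ggplot2::geom_point(ggplot2::aes(size = radius, colour = color_class),
                        alpha = 0.6) +
    ggplot2::geom_text(ggplot2::aes(label = score), size = 3) +
    ggplot2::scale_colour_manual(values = class_colors(), drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_size_identity() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, colour = "severity") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 8, height = 5, dpi = 150)
  }
  list(data = dat, plot = p)
}
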
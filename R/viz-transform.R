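#' Plot configuration for the track-less renderer
#'
#' All datasets are superimposed in one coordinate frame: genomic position on
#' the x-axis and methylation beta from 0 (bottom) to 1 (top) on the y-axis.
#'
#' @param width_px,height_px canvas size in pixels.
#' @param margins named integer vector `top/right/bottom/left`; the bottom
#'   margin hosts the below-axis SNP/reliability marker rows and the gene
#'   track.
#' @param mode `"points"`, `"distribution"` or `"trace"`.
#' @param palette colors assigned to groups in label order, cycled; the
#'   default is a 12-color colorblind-aware list.
#' @param island_colors named colors for CpG island background shading:
#'   a deeper blue for high-density islands, a lighter blue for
#'   intermediate-density islands (configurable).
#' @param marker_colors named colors for the below-axis rows: blue squares
#'   for a SNP within the probe body, red squares for a SNP at the
#'   interrogated CpG, and dark ticks for unreliable probes.
#' @param trace_window odd integer >= 1; width of the centered moving average
#'   applied to per-probe group means in trace mode (1 = raw polyline, the
#'   default — the trace deliberately stays jagged rather than implying
#'   imputed gradients between CpGs).
#' @param distribution_glyph `"mean_range"` (mean marker + min-max whisker,
#'   default) or `"box"` (median + IQR box + min-max whiskers).
#' @param point_radius data-point circle radius, px.
#' @param glyph_fan_px total width of the horizontal fan spreading the
#'   distribution glyphs of k groups around a probe's x position.
#' @param island_pad_px horizontal padding added to island background
#'   rectangles so single-probe islands stay visible.
#' @return An object of class `plot_config`.
#' @export
plot_config <- function(width_px = 900L, height_px = 420L,
                        margins = c(top = 20L, right = 30L,
                                    bottom = 110L, left = 55L),
                        mode = c("points", "distribution", "trace"),
                        palette = default_palette(),
                        island_colors = c(high_density = "#1f4e9c",
                                          intermediate_density = "#a8c7e8"),
                        marker_colors = c(snp_in_probe = "#1f77b4",
                                          snp_at_cpg = "#d62728",
                                          unreliable = "#13306b"),
                        trace_window = 1L,
                        distribution_glyph = c("mean_range", "box"),
                        point_radius = 3,
                        glyph_fan_px = 12,
                        island_pad_px = 3) {
  mode <- match.arg(mode)
  distribution_glyph <- match.arg(distribution_glyph)
  if (width_px <= 0 || height_px <= 0) {
    bs_stop("plot width and height must be positive")
  }
  trace_window <- as.integer(trace_window)
  if (trace_window < 1L || trace_window %% 2L == 0L) {
    bs_stop("trace_window must be an odd integer >= 1")
  }
  need <- c("top", "right", "bottom", "left")
  if (!all(need %in% names(margins))) {
    bs_stop("margins must be named top/right/bottom/left")
  }
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 margins = margins[need], mode = mode, palette = palette,
                 island_colors = island_colors,
                 marker_colors = marker_colors,
                 trace_window = trace_window,
                 distribution_glyph = distribution_glyph,
                 point_radius = point_radius,
                 glyph_fan_px = glyph_fan_px,
                 island_pad_px = island_pad_px),
            class = "plot_config")
}

#' @rdname plot_config
#' @export
default_palette <- function() {
  c("#4477AA", "#EE6677", "#228833", "#CCBB44", "#66CCEE", "#AA3377",
    "#BBBBBB", "#222255", "#225555", "#553311", "#DD7788", "#117744")
}

#' Build the affine genomic/beta to pixel transform
#'
#' Maps `position = start` to the left edge of the plot box and
#' `position = end` to the right edge, linearly; beta 0 maps to the bottom
#' edge and beta 1 to the top edge (SVG y grows downward).
#'
#' @param region a [genomic_region()].
#' @param cfg a [plot_config()].
#' @return An object of class `coord_transform` with the plot-box pixel
#'   bounds `x0`, `x1`, `y_top`, `y_bottom`.
#' @export
make_transform <- function(region, cfg) {
  m <- cfg$margins
  structure(list(region = region,
                 x0 = as.numeric(m[["left"]]),
                 x1 = as.numeric(cfg$width_px - m[["right"]]),
                 y_top = as.numeric(m[["top"]]),
                 y_bottom = as.numeric(cfg$height_px - m[["bottom"]])),
            class = "coord_transform")
}

#' Map genomic positions to pixel x (vectorized)
#' @param t a `coord_transform`.
#' @param position positions within the transform's region.
#' @return pixel x coordinates.
#' @export
genomic_to_x <- function(t, position) {
  r <- t$region
  if (any(position < r$start | position > r$end)) {
    bs_stop("position outside region ", format(r))
  }
  if (r$end == r$start) {
    return(rep((t$x0 + t$x1) / 2, length(position)))
  }
  t$x0 + (position - r$start) / (r$end - r$start) * (t$x1 - t$x0)
}

#' Map beta values to pixel y (vectorized)
#' @param t a `coord_transform`.
#' @param beta values in `[0, 1]`.
#' @return pixel y coordinates (beta 0 at the bottom, beta 1 at the top).
#' @export
beta_to_y <- function(t, beta) {
  if (any(beta < 0 | beta > 1)) bs_stop("beta outside [0,1]")
  t$y_bottom - beta * (t$y_bottom - t$y_top)
}

# Centered moving average; edges use whatever window is available.
moving_average <- function(x, window) {
  if (window <= 1L || length(x) < 2L) return(x)
  h <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}
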
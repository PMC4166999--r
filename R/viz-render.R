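# The track-less scene. Layer order (bottom to top): island background,
# axes, data glyphs, below-axis marker rows, gene track, legend. All groups
# share one transform: nothing is ever rescaled per group, so superimposed
# renders are directly comparable.

group_colors <- function(groups, cfg) {
  labs <- names(groups$groups)
  setNames(rep(cfg$palette, length.out = max(1L, length(labs)))[
    seq_along(labs)], labs)
}

# sample_id -> group label lookup (excluded samples absent)
sample_group_of <- function(groups) {
  out <- character()
  for (lab in names(groups$groups)) {
    ids <- groups$groups[[lab]]
    out[ids] <- lab
  }
  out
}

#' Render the annotation layers of a region
#'
#' Produces the SVG fragments drawn around the data:
#' * island background: each maximal run of consecutive probes sharing a
#'   non-`none` island class becomes one rectangle spanning the run's
#'   x-range at full plot height, beneath all data;
#' * SNP marker rows just below the x-axis: squares in the
#'   `snp_in_probe` color (first row) and `snp_at_cpg` color (second row);
#' * a third row of ticks for probes flagged unreliable;
#' * a gene-structure track (exon boxes joined by intron lines) below the
#'   marker rows, when gene models are supplied.
#'
#' @param data a `region_dataset`.
#' @param cfg a [plot_config()].
#' @param t a `coord_transform` for the dataset's region.
#' @param genes optional list of gene structures from [parse_gene_models()].
#' @return list with character vectors `background` (under the data) and
#'   `foreground` (marker rows + gene track).
#' @export
render_annotation_layers <- function(data, cfg, t = NULL, genes = NULL) {
  if (is.null(t)) t <- make_transform(data$region, cfg)
  probes <- data$probes
  background <- character()
  foreground <- character()
  if (nrow(probes)) {
    # --- island background: merge consecutive same-class runs
    cls <- probes$island_class
    run_id <- cumsum(c(TRUE, cls[-1] != cls[-length(cls)]))
    for (rid in unique(run_id)) {
      sel <- run_id == rid
      klass <- cls[sel][1]
      if (klass == "none") next
      xs <- genomic_to_x(t, probes$position[sel])
      x_left <- max(t$x0, min(xs) - cfg$island_pad_px)
      x_right <- min(t$x1, max(xs) + cfg$island_pad_px)
      background <- c(background, svg_el("rect", c(
        class = paste0("island island-", klass),
        x = fmt_px(x_left), y = fmt_px(t$y_top),
        width = fmt_px(x_right - x_left),
        height = fmt_px(t$y_bottom - t$y_top),
        fill = cfg$island_colors[[klass]], `fill-opacity` = "0.35")))
    }
    # --- below-axis marker rows
    sq <- 6
    row_y <- c(snp_in_probe = t$y_bottom + 6,
               snp_at_cpg = t$y_bottom + 16)
    xs <- genomic_to_x(t, probes$position)
    for (i in seq_len(nrow(probes))) {
      for (flag in c("snp_in_probe", "snp_at_cpg")) {
        if (isTRUE(probes[[flag]][i])) {
          foreground <- c(foreground, svg_el("rect", c(
            class = paste0("marker-", gsub("_", "-", flag)),
            x = fmt_px(xs[i] - sq / 2), y = fmt_px(row_y[[flag]]),
            width = fmt_px(sq), height = fmt_px(sq),
            fill = cfg$marker_colors[[flag]])))
        }
      }
      if (!isTRUE(probes$reliable[i])) {
        foreground <- c(foreground, svg_el("line", c(
          class = "marker-unreliable",
          x1 = fmt_px(xs[i]), y1 = fmt_px(t$y_bottom + 26),
          x2 = fmt_px(xs[i]), y2 = fmt_px(t$y_bottom + 34),
          stroke = cfg$marker_colors[["unreliable"]],
          `stroke-width` = "2")))
      }
    }
  }
  # --- gene track
  if (length(genes)) {
    y_gene <- t$y_bottom + 58
    r <- t$region
    for (g in genes) {
      if (g$chromosome != r$chromosome || g$end < r$start ||
          g$start > r$end) next
      gx0 <- genomic_to_x(t, max(g$start, r$start))
      gx1 <- genomic_to_x(t, min(g$end, r$end))
      foreground <- c(foreground, svg_el("line", c(
        class = "gene-body",
        x1 = fmt_px(gx0), y1 = fmt_px(y_gene),
        x2 = fmt_px(gx1), y2 = fmt_px(y_gene),
        stroke = "#444444", `stroke-width` = "1")))
      for (e in seq_len(nrow(g$exons))) {
        es <- g$exons$start[e]; ee <- g$exons$end[e]
        if (ee < r$start || es > r$end) next
        ex0 <- genomic_to_x(t, max(es, r$start))
        ex1 <- genomic_to_x(t, min(ee, r$end))
        foreground <- c(foreground, svg_el("rect", c(
          class = "exon",
          x = fmt_px(ex0), y = fmt_px(y_gene - 5),
          width = fmt_px(max(ex1 - ex0, 1)), height = fmt_px(10),
          fill = "#444444")))
      }
      foreground <- c(foreground,
                      svg_text(gx0, y_gene + 18, g$name,
                               c(class = "gene-label",
                                 `font-size` = "10")))
    }
  }
  list(background = background, foreground = foreground)
}

render_axes <- function(t, cfg) {
  els <- c(
    svg_el("line", c(class = "axis", x1 = fmt_px(t$x0), y1 = fmt_px(t$y_top),
                     x2 = fmt_px(t$x0), y2 = fmt_px(t$y_bottom),
                     stroke = "#000000")),
    svg_el("line", c(class = "axis", x1 = fmt_px(t$x0),
                     y1 = fmt_px(t$y_bottom), x2 = fmt_px(t$x1),
                     y2 = fmt_px(t$y_bottom), stroke = "#000000"))
  )
  for (b in c(0, 0.25, 0.5, 0.75, 1)) {
    y <- beta_to_y(t, b)
    els <- c(els,
             svg_el("line", c(class = "tick", x1 = fmt_px(t$x0 - 4),
                              y1 = fmt_px(y), x2 = fmt_px(t$x0),
                              y2 = fmt_px(y), stroke = "#000000")),
             svg_text(t$x0 - 8, y + 3, sprintf("%.2f", b),
                      c(class = "tick-label", `font-size` = "10",
                        `text-anchor` = "end")))
  }
  r <- t$region
  els <- c(els,
           svg_text(t$x0, t$y_bottom + 50,
                    paste0(r$chromosome, ":", r$start),
                    c(class = "x-label", `font-size` = "10")),
           svg_text(t$x1, t$y_bottom + 50, as.character(r$end),
                    c(class = "x-label", `font-size` = "10",
                      `text-anchor` = "end")))
  els
}

render_legend <- function(groups, colors, t) {
  els <- character()
  labs <- names(groups$groups)
  for (i in seq_along(labs)) {
    y <- t$y_top + 14 * i
    els <- c(els,
             svg_el("rect", c(class = "legend-swatch",
                              x = fmt_px(t$x1 - 110), y = fmt_px(y - 8),
                              width = "10", height = "10",
                              fill = colors[[labs[i]]])),
             svg_text(t$x1 - 96, y, labs[i],
                      c(class = "legend-label", `font-size` = "11")))
  }
  els
}

sample_tooltip <- function(record) {
  if (is.null(record)) return("")
  md <- record$metadata
  parts <- c(record$sample_id,
             paste0("project=", record$project),
             if (length(md)) paste0(names(md), "=",
                                    vapply(md, function(v)
                                      as.character(v), character(1))))
  paste(parts, collapse = "; ")
}

layer_points <- function(data, groups, cfg, t) {
  colors <- group_colors(groups, cfg)
  grp_of <- sample_group_of(groups)
  els <- character()
  for (i in seq_len(nrow(data$probes))) {
    x <- genomic_to_x(t, data$probes$position[i])
    v <- data$betas[[i]]
    for (s in names(v)) {
      lab <- grp_of[s]
      if (is.na(lab)) next   # excluded or hidden samples are not displayed
      els <- c(els, svg_el(
        "circle",
        c(class = "point", cx = fmt_px(x), cy = fmt_px(beta_to_y(t, v[[s]])),
          r = fmt_px(cfg$point_radius), fill = colors[[lab]],
          `fill-opacity` = "0.75", `data-sample` = s),
        children = svg_el("title", character(),
                          children = xml_escape(
                            sample_tooltip(data$samples[[s]])))))
    }
  }
  els
}

layer_distribution <- function(data, groups, cfg, t) {
  colors <- group_colors(groups, cfg)
  labs <- names(groups$groups)
  els <- character()
  for (i in seq_len(nrow(data$probes))) {
    x <- genomic_to_x(t, data$probes$position[i])
    v <- data$betas[[i]]
    present <- labs[vapply(labs, function(lab) {
      any(groups$groups[[lab]] %in% names(v))
    }, logical(1))]
    k <- length(present)
    if (!k) next
    offsets <- if (k == 1L) 0 else
      seq(-cfg$glyph_fan_px / 2, cfg$glyph_fan_px / 2, length.out = k)
    for (j in seq_len(k)) {
      lab <- present[j]
      vals <- v[names(v) %in% groups$groups[[lab]]]
      xg <- x + offsets[j]
      col <- colors[[lab]]
      if (cfg$distribution_glyph == "mean_range") {
        els <- c(els,
                 svg_el("line", c(class = "dist-range", `data-group` = lab,
                                  x1 = fmt_px(xg), y1 = fmt_px(beta_to_y(t, min(vals))),
                                  x2 = fmt_px(xg), y2 = fmt_px(beta_to_y(t, max(vals))),
                                  stroke = col, `stroke-width` = "1.5")),
                 svg_el("circle", c(class = "dist-mean", `data-group` = lab,
                                    cx = fmt_px(xg),
                                    cy = fmt_px(beta_to_y(t, mean(vals))),
                                    r = "2.5", fill = col)))
      } else {
        q <- unname(quantile(vals, c(0.25, 0.5, 0.75)))
        bw <- 6
        els <- c(els,
                 svg_el("line", c(class = "dist-whisker", `data-group` = lab,
                                  x1 = fmt_px(xg), y1 = fmt_px(beta_to_y(t, min(vals))),
                                  x2 = fmt_px(xg), y2 = fmt_px(beta_to_y(t, max(vals))),
                                  stroke = col, `stroke-width` = "1")),
                 svg_el("rect", c(class = "dist-box", `data-group` = lab,
                                  x = fmt_px(xg - bw / 2),
                                  y = fmt_px(beta_to_y(t, q[3])),
                                  width = fmt_px(bw),
                                  height = fmt_px(beta_to_y(t, q[1]) -
                                                    beta_to_y(t, q[3])),
                                  fill = col, `fill-opacity` = "0.5",
                                  stroke = col)),
                 svg_el("line", c(class = "dist-median", `data-group` = lab,
                                  x1 = fmt_px(xg - bw / 2),
                                  y1 = fmt_px(beta_to_y(t, q[2])),
                                  x2 = fmt_px(xg + bw / 2),
                                  y2 = fmt_px(beta_to_y(t, q[2])),
                                  stroke = col, `stroke-width` = "2")))
      }
    }
  }
  els
}

layer_trace <- function(data, groups, cfg, t) {
  colors <- group_colors(groups, cfg)
  els <- character()
  for (lab in names(groups$groups)) {
    ids <- groups$groups[[lab]]
    xs <- numeric(); ms <- numeric()
    for (i in seq_len(nrow(data$probes))) {
      v <- data$betas[[i]]
      vals <- v[names(v) %in% ids]
      if (!length(vals)) next   # probes without group data are skipped,
      xs <- c(xs, genomic_to_x(t, data$probes$position[i]))  # not imputed
      ms <- c(ms, mean(vals))
    }
    if (!length(ms)) next
    ms <- moving_average(ms, cfg$trace_window)
    col <- colors[[lab]]
    if (length(ms) < 2L) {
      els <- c(els, svg_el("circle", c(
        class = "trace-point", `data-group` = lab,
        cx = fmt_px(xs), cy = fmt_px(beta_to_y(t, ms)), r = "3",
        fill = col)))
    } else {
      pts <- paste(fmt_px(xs), fmt_px(beta_to_y(t, ms)), sep = ",",
                   collapse = " ")
      els <- c(els, svg_el("polyline", c(
        class = "trace", `data-group` = lab, points = pts,
        fill = "none", stroke = col, `stroke-width` = "2")))
    }
  }
  els
}

#' Render a region dataset as a track-less SVG scene
#'
#' All groups share one coordinate frame — axes are never rescaled per group,
#' so superimposed datasets are directly comparable. Three modes:
#'
#' * `points`: one circle per (probe, sample) measurement, colored by group,
#'   with a hover tooltip (`<title>`) naming the sample and its metadata.
#'   Samples excluded by the grouping are not displayed.
#' * `distribution`: one summary glyph per (probe, group) — by default a
#'   mean marker with a min-max whisker; optionally a median/IQR box plot.
#'   Glyphs of several groups fan out horizontally around the probe.
#' * `trace`: per group, the per-probe mean betas connected by a polyline
#'   (probes without data for the group are skipped, never interpolated to
#'   0). An optional centered moving average smooths the series; the line is
#'   a visualization aid only, not an imputed methylation gradient.
#'
#' @param data a `region_dataset` from [query_region()].
#' @param groups a `group_assignment` from [group_samples()] /
#'   [cross_project_groups()].
#' @param cfg a [plot_config()]; `cfg$mode` selects the mode.
#' @param genes optional gene models from [parse_gene_models()].
#' @return an `svg_document`; write it with [write_svg()].
#' @export
render_region <- function(data, groups, cfg = plot_config(), genes = NULL) {
  stopifnot(inherits(data, "region_dataset"),
            inherits(groups, "group_assignment"),
            inherits(cfg, "plot_config"))
  t <- make_transform(data$region, cfg)
  layer_fun <- switch(cfg$mode,
                      points = layer_points,
                      distribution = layer_distribution,
                      trace = layer_trace)
  ann <- render_annotation_layers(data, cfg, t, genes)
  els <- c(ann$background, render_axes(t, cfg))
  if (nrow(data$probes) == 0L) {
    els <- c(els, svg_text((t$x0 + t$x1) / 2, (t$y_top + t$y_bottom) / 2,
                           "no probes in region",
                           c(class = "empty-label", `font-size` = "12",
                             `text-anchor` = "middle")))
  } else {
    els <- c(els, layer_fun(data, groups, cfg, t))
  }
  els <- c(els, ann$foreground, render_legend(groups, group_colors(groups, cfg), t))
  svg_document(cfg$width_px, cfg$height_px, els)
}

#' @rdname render_region
#' @export
render_points <- function(data, groups, cfg = plot_config(mode = "points"),
                          genes = NULL) {
  if (cfg$mode != "points") bs_stop("cfg$mode must be 'points'")
  render_region(data, groups, cfg, genes)
}

#' @rdname render_region
#' @export
render_distribution <- function(data, groups,
                                cfg = plot_config(mode = "distribution"),
                                genes = NULL) {
  if (cfg$mode != "distribution") bs_stop("cfg$mode must be 'distribution'")
  render_region(data, groups, cfg, genes)
}

#' @rdname render_region
#' @export
render_trace <- function(data, groups, cfg = plot_config(mode = "trace"),
                         genes = NULL) {
  if (cfg$mode != "trace") bs_stop("cfg$mode must be 'trace'")
  render_region(data, groups, cfg, genes)
}
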
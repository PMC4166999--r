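# The renderer is tested through its own output: emitted SVG is parsed with
# a strict XML parser and glyph geometry is compared against independent
# recomputation from the region dataset.

dataset_groups <- function(data, keys = "sex") {
  group_samples(unname(data$samples), group_spec("within_project", keys))
}

test_that("coordinate transforms are affine, monotone and bounded", {
  region <- genomic_region("chr1", 1000L, 2000L)
  cfg <- plot_config()
  t <- make_transform(region, cfg)

  expect_equal(genomic_to_x(t, 1000L), t$x0)
  expect_equal(genomic_to_x(t, 2000L), t$x1)
  expect_equal(genomic_to_x(t, 1500L), (t$x0 + t$x1) / 2)
  expect_equal(beta_to_y(t, 0), t$y_bottom)
  expect_equal(beta_to_y(t, 1), t$y_top)
  expect_equal(beta_to_y(t, 0.5), (t$y_top + t$y_bottom) / 2)

  # monotone: position up -> x up; beta up -> y down (SVG y grows downward)
  pos <- sort(sample(1000:2000, 50))
  expect_false(is.unsorted(genomic_to_x(t, pos), strictly = FALSE))
  betas <- sort(runif(50))
  expect_false(is.unsorted(rev(beta_to_y(t, betas))))

  expect_error(genomic_to_x(t, 999L), "outside region")
  expect_error(beta_to_y(t, 1.2), "outside")
})

test_that("points mode draws one tooltip-carrying circle per measurement", {
  set.seed(21)
  data <- random_region_dataset(n_probes = 2, n_samples = 3, missing_p = 0)
  groups <- dataset_groups(data)
  doc <- render_points(data, groups)
  x <- svg_xml(doc)
  pts <- nodes_by_class(x, "point")
  expect_length(pts, 6L)
  # every circle carries a <title> tooltip naming the sample
  titles <- xml2::xml_text(xml2::xml_find_first(pts, "./*"))
  samp <- xml2::xml_attr(pts, "data-sample")
  expect_true(all(mapply(grepl, samp, titles, fixed = TRUE)))
  expect_true(all(grepl("sex=", titles)))
})

test_that("points recomputed from the SVG match the transform within 0.5 px", {
  set.seed(22)
  for (rep in 1:5) {
    data <- random_region_dataset(n_probes = sample(3:12, 1),
                                  n_samples = sample(2:10, 1))
    groups <- dataset_groups(data)
    cfg <- plot_config(mode = "points")
    t <- make_transform(data$region, cfg)
    doc <- render_points(data, groups, cfg)
    x <- svg_xml(doc)
    pts <- nodes_by_class(x, "point")

    shown <- unlist(lapply(groups$groups, identity), use.names = FALSE)
    expected <- list()
    for (i in seq_len(nrow(data$probes))) {
      v <- data$betas[[i]]
      v <- v[names(v) %in% shown]
      for (s in names(v)) {
        expected[[length(expected) + 1L]] <- c(
          genomic_to_x(t, data$probes$position[i]), beta_to_y(t, v[[s]]))
      }
    }
    expect_length(pts, length(expected))
    got <- cbind(attr_num(pts, "cx"), attr_num(pts, "cy"))
    exp_m <- do.call(rbind, expected)
    ord_g <- order(got[, 1], got[, 2]); ord_e <- order(exp_m[, 1], exp_m[, 2])
    expect_true(all(abs(got[ord_g, ] - exp_m[ord_e, ]) <= 0.5))
    # all data glyphs stay inside the plot box
    expect_true(all(got[, 1] >= t$x0 - 0.51 & got[, 1] <= t$x1 + 0.51))
    expect_true(all(got[, 2] >= t$y_top - 0.51 & got[, 2] <= t$y_bottom + 0.51))
  }
})

test_that("excluded samples are not displayed", {
  set.seed(23)
  data <- random_region_dataset(n_probes = 4, n_samples = 5, missing_p = 0)
  # strip the grouping key from one sample -> it gets excluded
  data$samples[["t01"]]$metadata$sex <- NULL
  groups <- dataset_groups(data)
  expect_true("t01" %in% groups$excluded)
  doc <- render_points(data, groups)
  pts <- nodes_by_class(svg_xml(doc), "point")
  expect_length(pts, 16L)
  expect_false("t01" %in% xml2::xml_attr(pts, "data-sample"))
})

test_that("distribution glyphs match brute-force group statistics", {
  set.seed(24)
  data <- random_region_dataset(n_probes = 6, n_samples = 10,
                                missing_p = 0.2)
  groups <- dataset_groups(data)
  t <- make_transform(data$region, plot_config())

  for (glyph in c("mean_range", "box")) {
    cfg <- plot_config(mode = "distribution", distribution_glyph = glyph)
    x <- svg_xml(render_distribution(data, groups, cfg))
    whiskers <- nodes_by_class(x, if (glyph == "mean_range") "dist-range"
                               else "dist-whisker")
    # expected extents per (probe, group with >= 1 value), label order
    exp_rows <- list()
    for (i in seq_len(nrow(data$probes))) {
      v <- data$betas[[i]]
      for (lab in names(groups$groups)) {
        vals <- v[names(v) %in% groups$groups[[lab]]]
        if (!length(vals)) next
        exp_rows[[length(exp_rows) + 1L]] <-
          list(lab = lab, min = min(vals), max = max(vals),
               mean = mean(vals), median = median(vals),
               q = unname(quantile(vals, c(0.25, 0.75))))
      }
    }
    expect_length(whiskers, length(exp_rows))
    y_lo <- pmax(attr_num(whiskers, "y1"), attr_num(whiskers, "y2"))
    y_hi <- pmin(attr_num(whiskers, "y1"), attr_num(whiskers, "y2"))
    for (j in seq_along(exp_rows)) {
      expect_equal(y_lo[j], beta_to_y(t, exp_rows[[j]]$min), tolerance = 0.5)
      expect_equal(y_hi[j], beta_to_y(t, exp_rows[[j]]$max), tolerance = 0.5)
    }
    if (glyph == "mean_range") {
      means <- nodes_by_class(x, "dist-mean")
      for (j in seq_along(exp_rows)) {
        expect_equal(attr_num(means, "cy")[j],
                     beta_to_y(t, exp_rows[[j]]$mean), tolerance = 0.5)
      }
    } else {
      boxes <- nodes_by_class(x, "dist-box")
      medians <- nodes_by_class(x, "dist-median")
      for (j in seq_along(exp_rows)) {
        expect_equal(attr_num(boxes, "y")[j],
                     beta_to_y(t, exp_rows[[j]]$q[2]), tolerance = 0.5)
        expect_equal(attr_num(boxes, "y")[j] + attr_num(boxes, "height")[j],
                     beta_to_y(t, exp_rows[[j]]$q[1]), tolerance = 0.5)
        expect_equal(attr_num(medians, "y1")[j],
                     beta_to_y(t, exp_rows[[j]]$median), tolerance = 0.5)
      }
    }
  }
})

test_that("mean_range arithmetic: betas {0.2, 0.4} give mean 0.3 whisker 0.2-0.4", {
  region <- genomic_region("chr1", 100L, 300L)
  ann <- probe_annotation("cgP", "chr1", 200L)
  samples <- list(a = sample_record("a", "p", list(g = "x")),
                  b = sample_record("b", "p", list(g = "x")))
  data <- region_dataset(region, ann, list(c(a = 0.2, b = 0.4)), samples)
  groups <- dataset_groups(data, "g")
  cfg <- plot_config(mode = "distribution")
  t <- make_transform(region, cfg)
  x <- svg_xml(render_distribution(data, groups, cfg))
  expect_equal(attr_num(nodes_by_class(x, "dist-mean"), "cy"),
               beta_to_y(t, 0.3), tolerance = 0.005)
  w <- nodes_by_class(x, "dist-range")
  expect_equal(sort(c(attr_num(w, "y1"), attr_num(w, "y2"))),
               sort(beta_to_y(t, c(0.4, 0.2))), tolerance = 0.005)

  # single-member group -> degenerate zero-length whisker
  data1 <- region_dataset(region, ann, list(c(a = 0.2)), samples["a"])
  x1 <- svg_xml(render_distribution(data1, dataset_groups(data1, "g"), cfg))
  w1 <- nodes_by_class(x1, "dist-range")
  expect_equal(attr_num(w1, "y1"), attr_num(w1, "y2"))
})

test_that("trace vertices equal per-probe group means after smoothing", {
  region <- genomic_region("chr1", 100L, 500L)
  ann <- probe_annotation(c("cg1", "cg2", "cg3"), "chr1",
                          c(100L, 300L, 500L))
  samples <- list(a = sample_record("a", "p", list(g = "x")),
                  b = sample_record("b", "p", list(g = "x")))
  betas <- list(c(a = 0.2, b = 0.4), c(a = 0.6, b = 0.8), c(a = 0.9, b = 0.9))
  data <- region_dataset(region, ann, betas, samples)
  groups <- dataset_groups(data, "g")

  cfg <- plot_config(mode = "trace")
  t <- make_transform(region, cfg)
  x <- svg_xml(render_trace(data, groups, cfg))
  v <- polyline_vertices(nodes_by_class(x, "trace")[[1]])
  expect_equal(v[, 2], beta_to_y(t, c(0.3, 0.7, 0.9)), tolerance = 0.005)

  # window 3 over means (0.1, 0.5, 0.9): middle vertex at the centered mean
  betas2 <- list(c(a = 0.1), c(a = 0.5), c(a = 0.9))
  data2 <- region_dataset(region, ann, betas2, samples["a"])
  cfg3 <- plot_config(mode = "trace", trace_window = 3)
  x3 <- svg_xml(render_trace(data2, dataset_groups(data2, "g"), cfg3))
  v3 <- polyline_vertices(nodes_by_class(x3, "trace")[[1]])
  expect_equal(v3[2, 2], beta_to_y(t, 0.5), tolerance = 0.005)
  # edges use the available window
  expect_equal(v3[1, 2], beta_to_y(t, mean(c(0.1, 0.5))), tolerance = 0.005)

  # probes without group data are skipped, not interpolated to zero
  betas3 <- list(c(a = 0.2), numeric(), c(a = 0.8))
  data3 <- region_dataset(region, ann, betas3, samples["a"])
  xg <- svg_xml(render_trace(data3, dataset_groups(data3, "g"), cfg))
  vg <- polyline_vertices(nodes_by_class(xg, "trace")[[1]])
  expect_equal(nrow(vg), 2L)

  # a group with data at < 2 probes degrades to a point marker
  betas4 <- list(c(a = 0.2), numeric(), numeric())
  data4 <- region_dataset(region, ann, betas4, samples["a"])
  x4 <- svg_xml(render_trace(data4, dataset_groups(data4, "g"), cfg))
  expect_length(nodes_by_class(x4, "trace"), 0L)
  expect_length(nodes_by_class(x4, "trace-point"), 1L)
})

test_that("random trace renders match oracle recomputation", {
  set.seed(25)
  for (rep in 1:5) {
    data <- random_region_dataset(n_probes = sample(4:12, 1),
                                  n_samples = sample(4:10, 1))
    groups <- dataset_groups(data)
    w <- sample(c(1L, 3L, 5L), 1)
    cfg <- plot_config(mode = "trace", trace_window = w)
    t <- make_transform(data$region, cfg)
    x <- svg_xml(render_trace(data, groups, cfg))
    traces <- nodes_by_class(x, "trace")
    got_groups <- xml2::xml_attr(traces, "data-group")
    for (lab in names(groups$groups)) {
      ids <- groups$groups[[lab]]
      means <- c(); pos <- c()
      for (i in seq_len(nrow(data$probes))) {
        vals <- data$betas[[i]][names(data$betas[[i]]) %in% ids]
        if (!length(vals)) next
        means <- c(means, mean(vals)); pos <- c(pos, data$probes$position[i])
      }
      if (length(means) < 2) next
      h <- (w - 1) %/% 2
      sm <- vapply(seq_along(means), function(i)
        mean(means[max(1, i - h):min(length(means), i + h)]), numeric(1))
      v <- polyline_vertices(traces[[which(got_groups == lab)]])
      expect_equal(v[, 1], genomic_to_x(t, pos), tolerance = 0.5)
      expect_equal(v[, 2], beta_to_y(t, sm), tolerance = 0.5)
    }
  }
})

test_that("annotation layers: island run-merging, SNP marker rows, gene track", {
  region <- genomic_region("chr1", 100L, 900L)
  ann <- probe_annotation(
    sprintf("cg%d", 1:6), "chr1", c(100L, 200L, 300L, 500L, 700L, 900L),
    island_class = c("high_density", "high_density", "high_density",
                     "none", "intermediate_density", "none"),
    snp_in_probe = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
    snp_at_cpg = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
    reliable = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  samples <- list(a = sample_record("a", "p", list(g = "x")))
  betas <- rep(list(c(a = 0.5)), 6)
  data <- region_dataset(region, ann, betas, samples)
  x <- svg_xml(render_points(data, dataset_groups(data, "g")))

  # 3 consecutive high-density probes merge into ONE rectangle
  expect_length(nodes_by_class(x, "island-high_density"), 1L)
  expect_length(nodes_by_class(x, "island-intermediate_density"), 1L)
  # probe 6 has both SNP flags -> one square in each marker row
  expect_length(nodes_by_class(x, "marker-snp-in-probe"), 2L)
  expect_length(nodes_by_class(x, "marker-snp-at-cpg"), 2L)
  expect_length(nodes_by_class(x, "marker-unreliable"), 1L)

  # marker rows sit below the x-axis; snp-at-cpg markers use the cpg color
  t <- make_transform(region, plot_config())
  cpg <- nodes_by_class(x, "marker-snp-at-cpg")
  expect_true(all(attr_num(cpg, "y") > t$y_bottom))
  expect_equal(unique(xml2::xml_attr(cpg, "fill")),
               unname(plot_config()$marker_colors[["snp_at_cpg"]]))

  # island rectangles span their probes' x-range at full plot height
  isl <- nodes_by_class(x, "island-high_density")
  pad <- plot_config()$island_pad_px
  expect_equal(attr_num(isl, "x"), genomic_to_x(t, 100L) - pad,
               tolerance = 0.5)
  expect_equal(attr_num(isl, "x") + attr_num(isl, "width"),
               genomic_to_x(t, 300L) + pad, tolerance = 0.5)
  expect_equal(attr_num(isl, "height"), t$y_bottom - t$y_top,
               tolerance = 0.01)

  # gene track: 3-exon gene -> 3 exon boxes
  gene <- list(list(name = "G", chromosome = "chr1", strand = "+",
                    start = 120L, end = 880L,
                    exons = data.frame(start = c(120L, 400L, 800L),
                                       end = c(180L, 480L, 880L)),
                    introns = data.frame(start = c(181L, 481L),
                                         end = c(399L, 799L))))
  xg <- svg_xml(render_points(data, dataset_groups(data, "g"),
                              plot_config(mode = "points"), genes = gene))
  expect_length(nodes_by_class(xg, "exon"), 3L)
  expect_length(nodes_by_class(xg, "gene-body"), 1L)
})

test_that("every render is well-formed XML, deterministic, and empty regions are labeled", {
  set.seed(26)
  data <- random_region_dataset()
  groups <- dataset_groups(data)
  for (m in c("points", "distribution", "trace")) {
    cfg <- plot_config(mode = m)
    s1 <- as.character(render_region(data, groups, cfg))
    s2 <- as.character(render_region(data, groups, cfg))
    expect_identical(s1, s2)   # byte-identical, no timestamps/randomness
    x <- xml2::read_xml(s1)    # strict parser accepts it
    expect_equal(xml2::xml_name(x), "svg")
    expect_false(is.na(xml2::xml_attr(x, "width")))
    expect_false(is.na(xml2::xml_attr(x, "height")))
  }

  empty <- region_dataset(genomic_region("chr9", 1L, 100L),
                          tiny_annotation()[0], list(), list())
  xe <- svg_xml(render_points(empty, dataset_groups(data)))
  expect_length(nodes_by_class(xe, "empty-label"), 1L)
  expect_length(nodes_by_class(xe, "axis"), 2L)
})

test_that("superimposition: per-group renders cover exactly the combined glyphs", {
  set.seed(27)
  data <- random_region_dataset(n_probes = 8, n_samples = 10,
                                missing_p = 0.1)
  groups <- dataset_groups(data)
  cfg <- plot_config(mode = "points")
  combined <- svg_xml(render_points(data, groups, cfg))
  comb <- nodes_by_class(combined, "point")
  comb_xy <- sort(paste(xml2::xml_attr(comb, "cx"),
                        xml2::xml_attr(comb, "cy"),
                        xml2::xml_attr(comb, "data-sample")))
  single_xy <- character()
  for (lab in names(groups$groups)) {
    solo <- filter_groups(groups, groups$groups[[lab]])
    xs <- svg_xml(render_points(data, solo, cfg))
    pts <- nodes_by_class(xs, "point")
    single_xy <- c(single_xy, paste(xml2::xml_attr(pts, "cx"),
                                    xml2::xml_attr(pts, "cy"),
                                    xml2::xml_attr(pts, "data-sample")))
  }
  # same transform for every subset: the union reproduces the combined render
  expect_identical(sort(single_xy), comb_xy)
})

test_that("plot_config validates its invariants", {
  expect_error(plot_config(width_px = 0), "positive")
  expect_error(plot_config(trace_window = 2), "odd")
  expect_silent(plot_config(trace_window = 5))
  expect_error(render_points(random_region_dataset(),
                             dataset_groups(random_region_dataset()),
                             plot_config(mode = "trace")),
               "points")
})
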
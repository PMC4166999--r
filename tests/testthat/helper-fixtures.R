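# Shared fixtures (built in code, no files) and SVG parsing helpers.

# A small annotation: chr7 probes incl. a known probe id and a TP53-like
# two-probe gene on chr17, plus island/SNP structure for the viz layers.
tiny_annotation <- function() {
  probe_annotation(
    probe_id = c("cg000001", "cg000002", "cg000003", "cg08691422",
                 "cg000005", "cg000006", "cg100001", "cg100002"),
    chromosome = c(rep("chr7", 6), "chr17", "chr17"),
    position = c(100L, 200L, 300L, 1000L, 1100L, 1200L,
                 7565097L, 7590856L),
    strand = "+",
    genes = c("", "GENEA", "GENEA", "GENEB", "GENEB", "",
              "TP53", "TP53"),
    island_class = c("none", "high_density", "high_density", "none",
                     "intermediate_density", "none", "none", "none"),
    snp_in_probe = c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    snp_at_cpg = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE),
    reliable = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE)
  )
}

tiny_samples <- function(project = "projA", n = 3L, prefix = "s") {
  lapply(seq_len(n), function(i) {
    sample_record(sprintf("%s%s%02d", project, prefix, i), project,
                  list(sex = if (i %% 2 == 0) "male" else "female",
                       tissuetype = "blood"))
  })
}

# A populated in-memory store: 2 projects x 3 samples over the tiny
# annotation, deterministic betas.
tiny_store <- function(seed = 42L) {
  set.seed(seed)
  st <- open_store(backend = "memory")
  ann <- tiny_annotation()
  load_annotation(st, ann)
  for (p in c("projA", "projB")) {
    samples <- tiny_samples(p)
    register_samples(st, p, samples)
    for (r in samples) {
      v <- round(runif(nrow(ann)), 6)
      names(v) <- ann$probe_id
      deposit_betas(st, p, r$sample_id, v)
    }
  }
  st
}

# Random sample records with randomly present keys, for grouping properties.
random_samples <- function(n, project = "rnd", keys = c("sex", "age_bin",
                                                        "treatment"),
                           p_present = 0.8) {
  values <- list(sex = c("female", "male"),
                 age_bin = c("young", "mid", "old"),
                 treatment = c("ctrl", "drug"))
  lapply(seq_len(n), function(i) {
    md <- list()
    for (k in keys) {
      if (runif(1) < p_present) md[[k]] <- sample(values[[k]], 1)
    }
    sample_record(sprintf("%s_%04d", project, i), project, md)
  })
}

# Brute-force grouping oracle: nested filtering, independent of the
# implementation's bookkeeping.
brute_force_groups <- function(samples, keys) {
  has_all <- vapply(samples, function(r) {
    all(vapply(keys, function(k) {
      if (k == "project") TRUE else !is.null(r$metadata[[k]])
    }, logical(1)))
  }, logical(1))
  included <- samples[has_all]
  labels <- vapply(included, function(r) {
    paste(vapply(keys, function(k) {
      if (k == "project") r$project else as.character(r$metadata[[k]])
    }, character(1)), collapse = " / ")
  }, character(1))
  ids <- vapply(included, function(r) r$sample_id, character(1))
  groups <- split(ids, labels)
  list(groups = groups[sort(names(groups))],
       excluded = vapply(samples[!has_all], function(r) r$sample_id,
                         character(1)))
}

# A random region dataset built directly (no store), for renderer fuzzing.
random_region_dataset <- function(n_probes = 10L, n_samples = 8L,
                                  missing_p = 0.15) {
  region <- genomic_region("chrT", 1000L, 9000L)
  pos <- sort(sample(seq(1000L, 9000L), n_probes))
  ann <- probe_annotation(
    probe_id = sprintf("cgT%05d", seq_len(n_probes)),
    chromosome = "chrT", position = pos,
    island_class = sample(c("none", "high_density",
                            "intermediate_density"), n_probes,
                          replace = TRUE),
    snp_in_probe = runif(n_probes) < 0.2,
    snp_at_cpg = runif(n_probes) < 0.2,
    reliable = runif(n_probes) > 0.2)
  samples <- lapply(seq_len(n_samples), function(i) {
    sample_record(sprintf("t%02d", i), "projT",
                  list(sex = sample(c("female", "male"), 1)))
  })
  ids <- vapply(samples, function(r) r$sample_id, character(1))
  betas <- lapply(seq_len(n_probes), function(i) {
    v <- round(runif(n_samples), 6)
    names(v) <- ids
    v[runif(n_samples) >= missing_p]
  })
  region_dataset(region, ann, betas,
                 stats::setNames(samples, ids))
}

# ---- SVG parsing helpers ----------------------------------------------------

svg_xml <- function(doc) xml2::read_xml(as.character(doc))

nodes_by_class <- function(x, class) {
  xml2::xml_find_all(x, sprintf(
    "//*[contains(concat(' ', normalize-space(@class), ' '), ' %s ')]",
    class))
}

attr_num <- function(nodes, a) as.numeric(xml2::xml_attr(nodes, a))

# Parses a polyline "x,y x,y ..." points attribute into a 2-col matrix.
polyline_vertices <- function(node) {
  pts <- strsplit(trimws(xml2::xml_attr(node, "points")), " ")[[1]]
  do.call(rbind, lapply(strsplit(pts, ",", fixed = TRUE), as.numeric))
}
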
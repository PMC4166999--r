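# Seeded synthetic fixtures: annotation manifests, projects with key-value
# metadata, and beta matrices with planted group structure. Everything is
# deterministic given the seed and writes exactly the formats the importers
# read, so all modules are testable without downloads.

clip01 <- function(x) pmin(1, pmax(0, x))

#' Specify a synthetic methylation dataset
#'
#' The generator draws a per-probe baseline from a bimodal background
#' mixture (the familiar genome-wide beta landscape: mostly unmethylated or
#' mostly methylated probes), adds per-sample Gaussian noise, and overrides
#' probes inside planted effects with group-conditional Gaussians — the
#' structure used for sex-specific X-inactivation patterns.
#'
#' @param seed integer RNG seed; identical specs produce byte-identical
#'   outputs.
#' @param n_probes number of annotated probes.
#' @param chromosomes chromosome names probes are spread over.
#' @param island_fraction expected fraction of probes inside CpG islands
#'   (assigned in short runs, split between high- and intermediate-density).
#' @param snp_fraction per-probe probability of each SNP flag.
#' @param projects list of project specs: `list(name=, n_samples=,
#'   metadata=)` where `metadata` maps a key to the vector of values sampled
#'   uniformly (or `list(values=, probs=)` for weighted sampling).
#' @param effects list of planted effects: `list(gene=, group_key=,
#'   groups=)` where `groups` maps a metadata value to `c(mean, sd)` of the
#'   betas drawn for samples with that value. Each effect gene gets a
#'   contiguous block of probes annotated to it.
#' @param effect_probes probes allocated per effect gene.
#' @param noise_sd sd of the additive per-sample noise around the baseline,
#'   clipped to `[0, 1]`.
#' @param background baseline mixture: `means`, `sd`, `weights`.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(seed = 1L, n_probes = 500L,
                     chromosomes = c("chr1", "chr2"),
                     island_fraction = 0.3, snp_fraction = 0.05,
                     projects = list(list(name = "sim_project",
                                          n_samples = 20L,
                                          metadata = list(
                                            sex = c("female", "male")))),
                     effects = list(), effect_probes = 8L,
                     noise_sd = 0.05,
                     background = list(means = c(0.1, 0.9), sd = 0.05,
                                       weights = c(0.5, 0.5))) {
  stopifnot(island_fraction >= 0, island_fraction <= 1,
            snp_fraction >= 0, snp_fraction <= 1, noise_sd >= 0)
  for (e in effects) {
    if (is.null(e$gene) || is.null(e$group_key) || is.null(e$groups)) {
      bs_stop("each effect needs gene, group_key and groups")
    }
    known <- unlist(lapply(projects, function(p) names(p$metadata)))
    if (!e$group_key %in% known) {
      bs_stop("effect on gene ", e$gene, " references unknown metadata key '",
              e$group_key, "'")
    }
    for (m in e$groups) {
      if (m[1] < 0 || m[1] > 1) bs_stop("planted means must lie in [0,1]")
    }
  }
  structure(list(seed = as.integer(seed), n_probes = as.integer(n_probes),
                 chromosomes = chromosomes,
                 island_fraction = island_fraction,
                 snp_fraction = snp_fraction, projects = projects,
                 effects = effects, effect_probes = as.integer(effect_probes),
                 noise_sd = noise_sd, background = background),
            class = "sim_spec")
}

sim_annotation <- function(spec) {
  n <- spec$n_probes
  chroms <- sort(rep_len(spec$chromosomes, n))
  position <- integer(n)
  for (ch in unique(chroms)) {
    sel <- chroms == ch
    position[sel] <- cumsum(sample(50:500, sum(sel), replace = TRUE))
  }
  island <- rep("none", n)
  i <- 1L
  while (i <= n) {
    len <- sample(2:6, 1L)
    run <- i:min(n, i + len - 1L)
    if (runif(1) < spec$island_fraction) {
      island[run] <- if (runif(1) < 0.5) "high_density" else
        "intermediate_density"
    }
    i <- i + len
  }
  ann <- data.table(
    probe_id = sprintf("cg%08d", seq_len(n)),
    chromosome = chroms, position = position,
    strand = sample(c("+", "-"), n, replace = TRUE),
    genes = "",
    island_class = island,
    snp_in_probe = runif(n) < spec$snp_fraction,
    snp_at_cpg = runif(n) < spec$snp_fraction,
    reliable = runif(n) >= 0.02
  )
  # allocate a contiguous probe block to each effect gene
  effect_genes <- unique(vapply(spec$effects, function(e) e$gene,
                                character(1)))
  if (length(effect_genes)) {
    block <- spec$effect_probes
    if (length(effect_genes) * block > n) {
      bs_stop("not enough probes for ", length(effect_genes),
              " effect genes of ", block, " probes each")
    }
    for (g in seq_along(effect_genes)) {
      idx <- ((g - 1L) * block + 1L):(g * block)
      ann$genes[idx] <- effect_genes[g]
    }
  }
  validate_annotation(ann)
}

sim_metadata_value <- function(dist) {
  if (is.list(dist)) {
    sample(dist$values, 1L, prob = dist$probs)
  } else {
    sample(dist, 1L)
  }
}

sim_samples <- function(spec) {
  out <- list()
  for (p in spec$projects) {
    for (i in seq_len(p$n_samples)) {
      md <- lapply(p$metadata, sim_metadata_value)
      out[[length(out) + 1L]] <-
        sample_record(sprintf("%s_s%03d", p$name, i), p$name, md)
    }
  }
  out
}

sim_betas_project <- function(spec, ann, samples) {
  n <- nrow(ann)
  ids <- vapply(samples, function(r) r$sample_id, character(1))
  base <- clip01(rnorm(
    n,
    mean = sample(spec$background$means, n, replace = TRUE,
                  prob = spec$background$weights),
    sd = spec$background$sd))
  vals <- matrix(NA_real_, n, length(samples))
  for (j in seq_along(samples)) {
    vals[, j] <- clip01(base + rnorm(n, 0, spec$noise_sd))
  }
  gene_lists <- split_genes(ann$genes)
  for (e in spec$effects) {
    rows <- which(vapply(gene_lists, function(g) e$gene %in% g, logical(1)))
    if (!length(rows)) next
    for (j in seq_along(samples)) {
      v <- samples[[j]]$metadata[[e$group_key]]
      if (is.null(v)) next
      m <- e$groups[[as.character(v)]]
      if (is.null(m)) next
      vals[rows, j] <- clip01(rnorm(length(rows), m[1], m[2]))
    }
  }
  beta_matrix(ann$probe_id, ids, vals)
}

sim_gene_models <- function(ann) {
  gene_lists <- split_genes(ann$genes)
  symbols <- unique(unlist(gene_lists))
  genes <- list()
  for (g in symbols) {
    rows <- which(vapply(gene_lists, function(x) g %in% x, logical(1)))
    chrom <- ann$chromosome[rows][1]
    rows <- rows[ann$chromosome[rows] == chrom]
    lo <- min(ann$position[rows]); hi <- max(ann$position[rows])
    span <- max(hi - lo, 300L)
    # three exons over the probe span
    e1 <- c(lo - 100L, lo - 100L + span %/% 5L)
    e2 <- c(lo + span %/% 3L, lo + span %/% 3L + span %/% 6L)
    e3 <- c(hi, hi + 150L)
    exons <- data.frame(start = pmax(1L, c(e1[1], e2[1], e3[1])),
                        end = c(e1[2], e2[2], e3[2]))
    genes[[length(genes) + 1L]] <- list(
      name = g, chromosome = chrom, strand = "+",
      start = exons$start[1], end = exons$end[3],
      exons = exons,
      introns = data.frame(start = exons$end[-3] + 1L,
                           end = exons$start[-1] - 1L))
  }
  genes
}

#' Write a beta matrix as a GenomeStudio-style final report
#'
#' Tab-separated with a `[Header]` preamble, a `TargetID` column and
#' `<sample>.AVG_Beta` / `<sample>.Detection Pval` column pairs. Detection
#' p-values are a constant 0.001 for present measurements.
#'
#' @param bm a [beta_matrix()].
#' @param path output path.
#' @param preamble include the `[Header]` block (default `TRUE`).
#' @export
write_genomestudio <- function(bm, path, preamble = TRUE) {
  header <- c("TargetID",
              as.vector(rbind(paste0(bm$sample_ids, ".AVG_Beta"),
                              paste0(bm$sample_ids, ".Detection Pval"))))
  rows <- vapply(seq_along(bm$probe_ids), function(i) {
    v <- bm$values[i, ]
    cells <- as.vector(rbind(
      ifelse(is.na(v), "", sprintf("%.17g", v)),
      ifelse(is.na(v), "", "0.001")))
    paste(c(bm$probe_ids[i], cells), collapse = "\t")
  }, character(1))
  lines <- c(if (preamble) c("[Header]",
                             "Processing\tsynthetic final report",
                             "[Sample Methylation Profile]"),
             paste(header, collapse = "\t"), rows)
  writeLines(lines, path)
  invisible(path)
}

#' Generate a synthetic methylation dataset
#'
#' Deterministic given `spec$seed`. When `dir` is supplied the fixture is
#' written in the importers' formats: `annotation.csv`, `samples.jsonl`,
#' `genes.bed`, and per project `<name>.betas.csv` plus
#' `<name>.genomestudio.txt`.
#'
#' @param spec a [sim_spec()].
#' @param dir optional output directory (created if needed).
#' @return list with `annotation`, `samples`, `betas` (named list of
#'   [beta_matrix()] per project), `genes`, and `spec`, invisibly when `dir`
#'   is given.
#' @export
simulate_methylation <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  ann <- sim_annotation(spec)
  samples <- sim_samples(spec)
  projects <- vapply(spec$projects, function(p) p$name, character(1))
  betas <- list()
  for (p in projects) {
    in_p <- Filter(function(r) r$project == p, samples)
    betas[[p]] <- sim_betas_project(spec, ann, in_p)
  }
  genes <- sim_gene_models(ann)
  out <- list(annotation = ann, samples = samples, betas = betas,
              genes = genes, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_annotation_csv(ann, file.path(dir, "annotation.csv"))
    write_sample_json(samples, file.path(dir, "samples.jsonl"))
    write_gene_models(genes, file.path(dir, "genes.bed"))
    for (p in projects) {
      write_beta_csv(betas[[p]], file.path(dir, paste0(p, ".betas.csv")))
      write_genomestudio(betas[[p]],
                         file.path(dir, paste0(p, ".genomestudio.txt")))
    }
    return(invisible(out))
  }
  out
}

# Planted per-probe, per-sex means for the X-inactivation fixture. Island
# probes follow the sex-specific patterns of genes subject to (or escaping)
# X inactivation; flanks are sex-neutral.
xci_plan <- function() {
  plan <- list(
    # XIST-like: ~50% in females, high in males at the two promoter islands
    list(gene = "XIST", offset = 1e6L, probes = list(
      list(n = 3L, island = "none", female = c(0.70, 0.05), male = c(0.70, 0.05)),
      list(n = 4L, island = "high_density", female = c(0.50, 0.05), male = c(0.85, 0.05)),
      list(n = 1L, island = "none", female = c(0.70, 0.05), male = c(0.70, 0.05)),
      list(n = 3L, island = "intermediate_density", female = c(0.50, 0.05), male = c(0.85, 0.05)),
      list(n = 1L, island = "none", female = c(0.70, 0.05), male = c(0.70, 0.05)))),
    # MAOA-like: subject to XCI — ~50% in females, very low in males
    list(gene = "MAOA", offset = 2e6L, probes = list(
      list(n = 2L, island = "none", female = c(0.80, 0.05), male = c(0.80, 0.05)),
      list(n = 4L, island = "high_density", female = c(0.50, 0.05), male = c(0.05, 0.03)),
      list(n = 2L, island = "none", female = c(0.80, 0.05), male = c(0.80, 0.05)))),
    # RPS4X-like: escapes XCI — island low in both sexes, flanks high; two
    # flank probes carry a SNP at the CpG (their apparent sex difference is
    # the SNP caveat, not methylation)
    list(gene = "RPS4X", offset = 3e6L, probes = list(
      list(n = 2L, island = "none", female = c(0.85, 0.05), male = c(0.85, 0.05)),
      list(n = 4L, island = "high_density", female = c(0.05, 0.03), male = c(0.05, 0.03)),
      list(n = 1L, island = "none", snp_at_cpg = TRUE,
           female = c(0.35, 0.05), male = c(0.75, 0.05)),
      list(n = 1L, island = "none", snp_at_cpg = TRUE,
           female = c(0.35, 0.05), male = c(0.75, 0.05)),
      list(n = 1L, island = "none", female = c(0.85, 0.05), male = c(0.85, 0.05))))
  )
  rows <- list()
  k <- 0L
  for (locus in plan) {
    pos <- locus$offset
    for (blk in locus$probes) {
      for (i in seq_len(blk$n)) {
        k <- k + 1L
        pos <- pos + 400L
        rows[[k]] <- data.table(
          probe_id = sprintf("cgX%06d", k), chromosome = "chrX",
          position = pos, strand = "+", genes = locus$gene,
          island_class = blk$island,
          snp_in_probe = FALSE,
          snp_at_cpg = isTRUE(blk$snp_at_cpg),
          reliable = !isTRUE(blk$snp_at_cpg),
          mean_female = blk$female[1], sd_female = blk$female[2],
          mean_male = blk$male[1], sd_male = blk$male[2])
      }
    }
  }
  rbindlist(rows)
}

#' Generate the X-chromosome-inactivation validation fixture
#'
#' One blood project of 46 samples (22 females, 24 males) over three
#' synthetic X-chromosome loci whose CpG island probes are planted to the
#' canonical patterns: an XIST-like gene (island ~50% methylated in females,
#' >75% in males at two promoter islands), a MAOA-like gene subject to
#' inactivation (island ~50% in females, low in males), and an RPS4X-like
#' escapee (island low in both sexes, flanks high in both). Two RPS4X flank
#' probes carry `snp_at_cpg = TRUE` with a planted pseudo-difference,
#' mirroring how a CpG-site SNP can masquerade as differential methylation.
#'
#' @param seed RNG seed.
#' @param dir optional directory; when given, the fixture files are written
#'   in the importers' formats (see [simulate_methylation()]).
#' @return list with `annotation`, `samples`, `betas` (a [beta_matrix()]),
#'   `genes`, `project` and `planted` (the per-probe planted means, for
#'   recovery checks).
#' @export
make_x_inactivation_fixture <- function(seed = 1L, dir = NULL) {
  set.seed(seed)
  plan <- xci_plan()
  ann <- plan[, ANNOTATION_COLUMNS, with = FALSE]
  project <- "xci_blood"
  samples <- c(
    lapply(seq_len(22L), function(i) {
      sample_record(sprintf("F%02d", i), project,
                    list(sex = "female", tissuetype = "blood"))
    }),
    lapply(seq_len(24L), function(i) {
      sample_record(sprintf("M%02d", i), project,
                    list(sex = "male", tissuetype = "blood"))
    })
  )
  ids <- vapply(samples, function(r) r$sample_id, character(1))
  sex <- vapply(samples, function(r) r$metadata$sex, character(1))
  vals <- matrix(NA_real_, nrow(plan), length(samples))
  for (j in seq_along(samples)) {
    mu <- if (sex[j] == "female") plan$mean_female else plan$mean_male
    sd <- if (sex[j] == "female") plan$sd_female else plan$sd_male
    vals[, j] <- clip01(rnorm(nrow(plan), mu, sd))
  }
  bm <- beta_matrix(plan$probe_id, ids, vals)
  genes <- sim_gene_models(ann)
  out <- list(annotation = ann, samples = samples, betas = bm,
              genes = genes, project = project, planted = plan)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_annotation_csv(ann, file.path(dir, "annotation.csv"))
    write_sample_json(samples, file.path(dir, "samples.jsonl"))
    write_gene_models(genes, file.path(dir, "genes.bed"))
    write_beta_csv(bm, file.path(dir, paste0(project, ".betas.csv")))
    write_genomestudio(bm, file.path(dir, paste0(project,
                                                 ".genomestudio.txt")))
    return(invisible(out))
  }
  out
}

#' Load an X-inactivation fixture into a store
#'
#' Convenience wrapper: annotation, samples and betas of
#' [make_x_inactivation_fixture()] deposited into `handle`.
#' @param handle a `beta_store`.
#' @param fixture result of [make_x_inactivation_fixture()].
#' @return the handle, invisibly.
#' @export
load_fixture <- function(handle, fixture) {
  load_annotation(handle, fixture$annotation)
  register_samples(handle, fixture$project, fixture$samples)
  deposit_matrix(handle, fixture$project, fixture$betas)
  invisible(handle)
}

#' Generate a synthetic full-array annotation manifest
#'
#' Emits exactly [FULL_ARRAY_PROBE_COUNT] (485,577) synthetic annotation
#' rows with unique probe ids and valid positions, spread over chr1-chr22,
#' chrX and chrY. Deterministic per seed.
#'
#' @param seed RNG seed.
#' @param path optional CSV output path.
#' @param n_probes row count; defaults to the full-array constant.
#' @return the annotation `data.table` (invisibly when `path` is given).
#' @export
make_full_array_manifest <- function(seed = 1L, path = NULL,
                                     n_probes = FULL_ARRAY_PROBE_COUNT) {
  set.seed(seed)
  chroms <- c(paste0("chr", 1:22), "chrX", "chrY")
  chrom <- sort(rep_len(chroms, n_probes))
  position <- integer(n_probes)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    position[sel] <- cumsum(sample(20:300, sum(sel), replace = TRUE))
  }
  ann <- data.table(
    probe_id = sprintf("cg%08d", seq_len(n_probes)),
    chromosome = chrom, position = position,
    strand = sample(c("+", "-"), n_probes, replace = TRUE),
    genes = "",
    island_class = sample(ISLAND_CLASSES, n_probes, replace = TRUE,
                          prob = c(0.15, 0.1, 0.75)),
    snp_in_probe = runif(n_probes) < 0.05,
    snp_at_cpg = runif(n_probes) < 0.02,
    reliable = runif(n_probes) >= 0.02
  )
  if (!is.null(path)) {
    write_annotation_csv(ann, path)
    return(invisible(ann))
  }
  ann
}
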
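#' Domain types: annotation tables, sample records, regions, region datasets
#'
#' @name betascope-types
#' @keywords internal
NULL

ISLAND_CLASSES <- c("high_density", "intermediate_density", "none")
ANNOTATION_COLUMNS <- c("probe_id", "chromosome", "position", "strand",
                        "genes", "island_class", "snp_in_probe",
                        "snp_at_cpg", "reliable")

#' Build a probe annotation table
#'
#' One row per array probe: genomic location, linked gene symbols, CpG island
#' density class, and reliability/SNP flags from a probe re-annotation.
#' `genes` is a `;`-separated string of gene symbols (possibly empty).
#'
#' @param probe_id character, unique probe identifiers (e.g. `"cg..."`).
#' @param chromosome character.
#' @param position integer, 1-based coordinate of the interrogated CpG.
#' @param strand `"+"`, `"-"` or `"unknown"`.
#' @param genes `;`-separated gene symbols per probe, `""` for none.
#' @param island_class one of `"high_density"`, `"intermediate_density"`,
#'   `"none"` per probe.
#' @param snp_in_probe,snp_at_cpg logical flags: a SNP falls within the probe
#'   body, or at the interrogated CpG itself (both can confound betas).
#' @param reliable logical, probe considered reliable by the re-annotation.
#' @return A `data.table` with the nine annotation columns, validated.
#' @export
probe_annotation <- function(probe_id, chromosome, position,
                             strand = "unknown", genes = "",
                             island_class = "none",
                             snp_in_probe = FALSE, snp_at_cpg = FALSE,
                             reliable = TRUE) {
  ann <- data.table(
    probe_id = as.character(probe_id),
    chromosome = as.character(chromosome),
    position = as.integer(position),
    strand = as.character(strand),
    genes = as.character(genes),
    island_class = as.character(island_class),
    snp_in_probe = as.logical(snp_in_probe),
    snp_at_cpg = as.logical(snp_at_cpg),
    reliable = as.logical(reliable)
  )
  validate_annotation(ann)
}

# Validates invariants shared by all annotation ingestion paths.
validate_annotation <- function(ann) {
  ann <- as.data.table(ann)
  missing_cols <- setdiff(ANNOTATION_COLUMNS, names(ann))
  if (length(missing_cols)) {
    bs_stop("annotation is missing column(s): ",
            paste(missing_cols, collapse = ", "))
  }
  ann <- ann[, ANNOTATION_COLUMNS, with = FALSE]
  ann[, position := as.integer(position)]
  if (nrow(ann) == 0L) return(ann)
  if (anyNA(ann$position) || any(ann$position < 1L)) {
    bad <- ann$probe_id[which(is.na(ann$position) | ann$position < 1L)[1]]
    bs_stop("probe ", bad, ": position must be an integer >= 1")
  }
  dup <- ann$probe_id[duplicated(ann$probe_id)]
  if (length(dup)) {
    bs_stop("duplicate probe_id in annotation: ", dup[1])
  }
  bad_class <- setdiff(unique(ann$island_class), ISLAND_CLASSES)
  if (length(bad_class)) {
    bs_stop("invalid island_class '", bad_class[1], "'; must be one of ",
            paste(ISLAND_CLASSES, collapse = ", "))
  }
  ann
}

split_genes <- function(genes) {
  lapply(strsplit(as.character(genes), ";", fixed = TRUE),
         function(g) g[nzchar(g)])
}

#' Create a sample metadata record
#'
#' A sample is identified by `sample_id` (unique within its project) and
#' carries free-form scalar key-value metadata. Keys that are not known for a
#' sample are simply absent: no placeholder or null values are ever stored.
#' The keys `project` and `tissuetype` are reserved names with cross-project
#' meaning.
#'
#' @param sample_id non-empty string.
#' @param project project name (a virtual grouping describing the origin of
#'   the sample, the unit of data integrity).
#' @param metadata named list of scalar values (string / number / boolean).
#' @return An object of class `sample_record`.
#' @export
sample_record <- function(sample_id, project, metadata = list()) {
  if (!is.character(sample_id) || length(sample_id) != 1L ||
      !nzchar(sample_id)) {
    bs_stop("sample_id must be a non-empty string")
  }
  if (!is.character(project) || length(project) != 1L || !nzchar(project)) {
    bs_stop("project must be a non-empty string")
  }
  if (length(metadata)) {
    if (is.null(names(metadata)) || any(!nzchar(names(metadata)))) {
      bs_stop("sample ", sample_id, ": all metadata entries must be named")
    }
    ok <- vapply(metadata, function(v) {
      length(v) == 1L && (is.character(v) || is.numeric(v) || is.logical(v))
    }, logical(1))
    if (!all(ok)) {
      bs_stop("sample ", sample_id, ": metadata values must be scalar ",
              "strings, numbers or booleans (offending key: ",
              names(metadata)[!ok][1], ")")
    }
    # drop NULLs so absent keys are truly absent
    metadata <- metadata[!vapply(metadata, is.null, logical(1))]
  }
  structure(list(sample_id = sample_id, project = project,
                 metadata = metadata),
            class = "sample_record")
}

#' @export
print.sample_record <- function(x, ...) {
  cat("<sample_record> ", x$project, "/", x$sample_id, "\n", sep = "")
  if (length(x$metadata)) {
    for (k in names(x$metadata)) {
      cat("  ", k, " = ", format(x$metadata[[k]]), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Create a genomic region
#'
#' Coordinates are 1-based with inclusive ends throughout the package
#' (the Illumina manifest convention).
#'
#' @param chromosome chromosome name, kept verbatim.
#' @param start,end integers with `1 <= start <= end`.
#' @return An object of class `genomic_region`.
#' @export
genomic_region <- function(chromosome, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end) {
    bs_stop("invalid region: require 1 <= start <= end (got ",
            start, "-", end, ")")
  }
  structure(list(chromosome = as.character(chromosome),
                 start = start, end = end),
            class = "genomic_region")
}

#' @export
print.genomic_region <- function(x, ...) {
  cat("<genomic_region> ", x$chromosome, ":", x$start, "-", x$end, "\n",
      sep = "")
  invisible(x)
}

#' @export
format.genomic_region <- function(x, ...) {
  paste0(x$chromosome, ":", x$start, "-", x$end)
}

# A region dataset joins annotation with per-sample betas over a window:
#   region      genomic_region
#   probes      annotation data.table, strictly ascending (position, probe_id)
#   betas       list parallel to probes rows; each element a named numeric
#               vector sample_id -> beta (missing samples absent)
#   samples     named list of sample_record (union of samples with >= 1 value)
region_dataset <- function(region, probes, betas, samples) {
  stopifnot(inherits(region, "genomic_region"),
            nrow(probes) == length(betas))
  if (nrow(probes) > 1L) {
    o <- order(probes$position, probes$probe_id)
    probes <- probes[o]
    betas <- betas[o]
  }
  structure(list(region = region, probes = probes, betas = betas,
                 samples = samples),
            class = "region_dataset")
}

#' @export
print.region_dataset <- function(x, ...) {
  cat("<region_dataset> ", format(x$region), ": ", nrow(x$probes),
      " probes, ", length(x$samples), " samples\n", sep = "")
  invisible(x)
}
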
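#' Construct a beta matrix
#'
#' The in-memory form of an imported beta table: probes in rows, samples in
#' columns, `NA` marking missing measurements (a missing cell is never zero).
#'
#' @param probe_ids,sample_ids ordered character vectors.
#' @param values numeric matrix `length(probe_ids) x length(sample_ids)`;
#'   non-missing entries must lie in `[0, 1]`.
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(probe_ids, sample_ids, values) {
  values <- as.matrix(values)
  if (nrow(values) != length(probe_ids) ||
      ncol(values) != length(sample_ids)) {
    bs_stop("beta matrix dimensions do not match probe/sample id lists")
  }
  if (anyDuplicated(probe_ids)) {
    bs_stop("duplicate probe id: ", probe_ids[duplicated(probe_ids)][1])
  }
  rng <- range(values, na.rm = TRUE)
  if (any(!is.na(values)) && (rng[1] < 0 || rng[2] > 1)) {
    bs_stop("beta values outside [0,1]")
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(list(probe_ids = as.character(probe_ids),
                 sample_ids = as.character(sample_ids),
                 values = values),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("<beta_matrix> ", length(x$probe_ids), " probes x ",
      length(x$sample_ids), " samples (", sum(!is.na(x$values)),
      " values)\n", sep = "")
  invisible(x)
}

MISSING_TOKENS <- c("", "NA", "NaN")

parse_beta_cell <- function(cell, row, col_name) {
  if (cell %in% MISSING_TOKENS) return(NA_real_)
  v <- suppressWarnings(as.numeric(cell))
  if (is.na(v)) {
    bs_stop("non-numeric beta value '", cell, "' at row ", row,
            ", column '", col_name, "'")
  }
  if (v < 0 || v > 1) {
    bs_stop("beta value out of range [0,1] at row ", row, ", column '",
            col_name, "': ", cell)
  }
  v
}

#' Parse a CSV beta table
#'
#' First column: probe id; remaining columns: one per sample. Empty cells,
#' `NA` and `NaN` are missing measurements, recorded as absent (never 0).
#'
#' @param path CSV file path.
#' @return a [beta_matrix()].
#' @export
parse_beta_csv <- function(path) {
  dt <- fread(path, sep = ",", header = TRUE, colClasses = "character",
              na.strings = NULL)
  if (ncol(dt) < 1L) bs_stop("beta CSV has no columns")
  probe_ids <- dt[[1L]]
  dup <- probe_ids[duplicated(probe_ids)]
  if (length(dup)) bs_stop("duplicate probe row: ", dup[1])
  sample_ids <- names(dt)[-1L]
  vals <- matrix(NA_real_, nrow(dt), length(sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- dt[[j + 1L]]
    for (i in seq_along(col)) {
      vals[i, j] <- parse_beta_cell(col[i], i, sample_ids[j])
    }
  }
  beta_matrix(probe_ids, sample_ids, vals)
}

#' Write a beta matrix as CSV
#'
#' Missing cells become empty strings; values are written at full float
#' precision so that write -> parse is an exact identity.
#'
#' @param bm a [beta_matrix()].
#' @param path output CSV path.
#' @export
write_beta_csv <- function(bm, path) {
  stopifnot(inherits(bm, "beta_matrix"))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  header <- paste(c("probe_id", bm$sample_ids), collapse = ",")
  rows <- vapply(seq_along(bm$probe_ids), function(i) {
    paste(c(bm$probe_ids[i], fmt(bm$values[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Parse a GenomeStudio-style final report
#'
#' Tab-separated, with a `TargetID` column and per-sample `<sample>.AVG_Beta`
#' columns; `<sample>.Detection Pval` columns are optional. Preamble lines
#' (e.g. `[Header]` / `[Sample Methylation Profile]` blocks) before the
#' column header are skipped. When `detection_p` is supplied and detection
#' p-value columns are present, betas whose p-value exceeds the threshold
#' become missing. Masking is opt-in: quality control is treated as an
#' upstream concern.
#'
#' @param path report file path.
#' @param detection_p optional detection p-value threshold.
#' @return a [beta_matrix()].
#' @export
parse_genomestudio <- function(path, detection_p = NULL) {
  lines <- readLines(path)
  header_at <- which(vapply(lines, function(l) {
    "TargetID" %in% strsplit(l, "\t", fixed = TRUE)[[1]]
  }, logical(1)))[1]
  if (is.na(header_at)) {
    bs_stop("no header line with a TargetID column found in ", path)
  }
  header <- strsplit(lines[header_at], "\t", fixed = TRUE)[[1]]
  target_col <- which(header == "TargetID")[1]

  beta_cols <- grep("\\.AVG_Beta$", header)
  if (!length(beta_cols)) {
    bs_stop("no .AVG_Beta columns found in ", path)
  }
  sample_ids <- sub("\\.AVG_Beta$", "", header[beta_cols])
  pval_cols <- match(paste0(sample_ids, ".Detection Pval"), header)

  body <- lines[-seq_len(header_at)]
  body <- body[nzchar(body)]
  probe_ids <- character(length(body))
  vals <- matrix(NA_real_, length(body), length(sample_ids))
  for (i in seq_along(body)) {
    fields <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    # trailing empty fields are dropped by strsplit; pad before checking
    if (length(fields) < length(header)) {
      padded <- c(fields, rep("", length(header) - length(fields)))
      raw_width <- length(gregexpr("\t", body[i], fixed = TRUE)[[1]]) + 1L
      if (raw_width != length(header)) {
        bs_stop("ragged row at line ", header_at + i, ": expected ",
                length(header), " fields, found ", raw_width)
      }
      fields <- padded
    } else if (length(fields) > length(header)) {
      bs_stop("ragged row at line ", header_at + i, ": expected ",
              length(header), " fields, found ", length(fields))
    }
    probe_ids[i] <- fields[target_col]
    for (j in seq_along(beta_cols)) {
      v <- parse_beta_cell(fields[beta_cols[j]], i, header[beta_cols[j]])
      if (!is.na(v) && !is.null(detection_p) && !is.na(pval_cols[j])) {
        p <- suppressWarnings(as.numeric(fields[pval_cols[j]]))
        if (!is.na(p) && p > detection_p) v <- NA_real_
      }
      vals[i, j] <- v
    }
  }
  dup <- probe_ids[duplicated(probe_ids)]
  if (length(dup)) bs_stop("duplicate probe row: ", dup[1])
  beta_matrix(probe_ids, sample_ids, vals)
}

#' Parse JSON-lines sample metadata
#'
#' One JSON object per line. `sample_id` and the reserved key `project` are
#' required; every other key is preserved verbatim as metadata. Keys a record
#' does not mention stay absent.
#'
#' @param path JSON-lines file path.
#' @return list of [sample_record()].
#' @export
parse_sample_json <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    doc <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) {
                      bs_stop("malformed JSON at line ", i, ": ",
                              conditionMessage(e))
                    })
    sid <- doc$sample_id; proj <- doc$project
    if (is.null(sid) || is.null(proj)) {
      bs_stop("line ", i, ": sample record requires sample_id and project")
    }
    md <- doc$metadata %||% doc[setdiff(names(doc), c("sample_id", "project"))]
    out[[length(out) + 1L]] <-
      sample_record(as.character(sid), as.character(proj),
                    lapply(md, identity))
  }
  out
}

#' Write sample records as JSON lines
#' @param records list of [sample_record()].
#' @param path output path.
#' @export
write_sample_json <- function(records, path) {
  lines <- vapply(records, function(r) {
    md <- r$metadata
    if (length(md)) md <- md[order(names(md))]
    as.character(jsonlite::toJSON(
      list(sample_id = r$sample_id, project = r$project,
           metadata = if (length(md)) md else structure(list(),
                                                        names = character())),
      auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Parse BED12 gene models for the gene-structure track
#'
#' Converts each record's exon blocks to 1-based inclusive intervals and
#' derives the intron gaps between them. A strict reader: every row must have
#' 12 tab-separated fields with consistent block counts.
#'
#' @param path BED12 file path.
#' @return list of gene structures, each with `name`, `chromosome`, `strand`,
#'   `start`, `end` and data.frames `exons` / `introns` (1-based inclusive).
#' @export
parse_gene_models <- function(path) {
  lines <- readLines(path)
  genes <- list()
  for (i in seq_along(lines)) {
    l <- lines[i]
    if (!nzchar(trimws(l)) || startsWith(l, "#") || startsWith(l, "track")) next
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) != 12L) {
      bs_stop("malformed BED12 at line ", i, ": expected 12 fields, found ",
              length(f))
    }
    start0 <- suppressWarnings(as.integer(f[2]))
    end0 <- suppressWarnings(as.integer(f[3]))
    n_blocks <- suppressWarnings(as.integer(f[10]))
    if (is.na(start0) || is.na(end0) || is.na(n_blocks) || start0 < 0L ||
        end0 <= start0) {
      bs_stop("malformed BED12 at line ", i, ": bad coordinates")
    }
    sizes <- suppressWarnings(
      as.integer(strsplit(sub(",$", "", f[11]), ",", fixed = TRUE)[[1]]))
    starts <- suppressWarnings(
      as.integer(strsplit(sub(",$", "", f[12]), ",", fixed = TRUE)[[1]]))
    if (length(sizes) != n_blocks || length(starts) != n_blocks ||
        anyNA(sizes) || anyNA(starts)) {
      bs_stop("malformed BED12 at line ", i,
              ": block sizes/starts do not match blockCount")
    }
    # BED is 0-based half-open; convert to 1-based inclusive
    exon_start <- start0 + starts + 1L
    exon_end <- start0 + starts + sizes
    introns <- if (n_blocks > 1L) {
      data.frame(start = exon_end[-n_blocks] + 1L,
                 end = exon_start[-1L] - 1L)
    } else {
      data.frame(start = integer(), end = integer())
    }
    genes[[length(genes) + 1L]] <- list(
      name = f[4], chromosome = f[1],
      strand = if (f[6] %in% c("+", "-")) f[6] else "unknown",
      start = start0 + 1L, end = end0,
      exons = data.frame(start = exon_start, end = exon_end),
      introns = introns
    )
  }
  genes
}

#' Write gene structures as BED12 (inverse of [parse_gene_models()])
#' @param genes list of gene structures.
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  lines <- vapply(genes, function(g) {
    start0 <- g$start - 1L
    sizes <- g$exons$end - g$exons$start + 1L
    starts <- g$exons$start - 1L - start0
    paste(c(g$chromosome, start0, g$end, g$name, 0,
            if (g$strand %in% c("+", "-")) g$strand else ".",
            start0, g$end, "0", nrow(g$exons),
            paste0(paste(sizes, collapse = ","), ","),
            paste0(paste(starts, collapse = ","), ",")),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
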
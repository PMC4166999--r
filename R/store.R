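#' Open (or create) a beta-value document store
#'
#' The store holds three kinds of documents: probe annotation records, sample
#' metadata records, and beta documents. Beta documents are the unit of
#' storage: one document per (project, probe) holding the beta values of all
#' samples of that project at that probe. The collection therefore scales
#' with the number of projects, never with the number of samples.
#'
#' Backends are pluggable behind one contract:
#' * `"file"` — an embedded, file-backed store: plain-text tables under
#'   `path`, loaded on open and persisted by [store_flush()] /
#'   [store_close()]. Opening an existing path reopens it, never clobbers.
#' * `"memory"` — same semantics, nothing persisted (`path` ignored).
#'
#' @param path directory for the store (created if needed).
#' @param backend `"file"` or `"memory"`.
#' @return A `beta_store` handle (an environment) accepted by all store
#'   operations.
#' @examples
#' st <- open_store(backend = "memory")
#' load_annotation(st, probe_annotation("cg001", "chr1", 100))
#' register_samples(st, "demo", list(sample_record("s1", "demo")))
#' deposit_betas(st, "demo", "s1", c(cg001 = 0.42))
#' @export
open_store <- function(path = NULL, backend = c("file", "memory")) {
  if (length(backend) != 1L || !backend %in% c("file", "memory")) {
    if (length(backend) > 1L) backend <- backend[1L]
    if (!backend %in% c("file", "memory")) {
      bs_stop("unknown backend '", backend,
              "'; valid backends are: file, memory")
    }
  }
  h <- new.env(parent = emptyenv())
  h$backend <- backend
  h$path <- path
  h$ann <- empty_annotation()
  h$betas <- empty_betas()
  h$samples <- list()     # key "<project>\r<sample_id>" -> sample_record
  h$projects <- character()
  class(h) <- "beta_store"

  if (backend == "file") {
    if (is.null(path)) bs_stop("the file backend requires a path")
    marker <- file.path(path, "betascope.json")
    if (dir.exists(path) && file.exists(marker)) {
      tryCatch(store_load_files(h), error = function(e) {
        bs_stop("failed to open store at '", path, "': ",
                conditionMessage(e))
      })
    } else {
      if (!dir.exists(path) &&
          !dir.create(path, recursive = TRUE, showWarnings = FALSE)) {
        bs_stop("cannot create store directory '", path, "'")
      }
      writeLines(jsonlite::toJSON(list(format = "betascope-store",
                                       version = 1L),
                                  auto_unbox = TRUE), marker)
    }
  }
  h
}

empty_annotation <- function() {
  data.table(probe_id = character(), chromosome = character(),
             position = integer(), strand = character(),
             genes = character(), island_class = character(),
             snp_in_probe = logical(), snp_at_cpg = logical(),
             reliable = logical())
}

empty_betas <- function() {
  data.table(project = character(), probe_id = character(),
             sample_id = character(), beta = numeric())
}

sample_key <- function(project, sample_id) paste(project, sample_id, sep = "\r")

#' @export
print.beta_store <- function(x, ...) {
  cat("<beta_store> backend=", x$backend,
      if (!is.null(x$path)) paste0(" path=", x$path) else "",
      "\n  ", nrow(x$ann), " annotated probes, ",
      length(x$projects), " projects, ", length(x$samples), " samples, ",
      store_document_count(x), " beta documents\n", sep = "")
  invisible(x)
}

# ---- persistence (file backend) ---------------------------------------------

store_files <- function(h) {
  list(ann = file.path(h$path, "annotation.csv"),
       samples = file.path(h$path, "samples.jsonl"),
       betas = file.path(h$path, "betas.tsv"))
}

store_load_files <- function(h) {
  f <- store_files(h)
  if (file.exists(f$ann)) h$ann <- read_annotation_csv(f$ann)
  if (file.exists(f$samples)) {
    recs <- parse_sample_json(f$samples)
    for (r in recs) {
      h$samples[[sample_key(r$project, r$sample_id)]] <- r
      h$projects <- union(h$projects, r$project)
    }
  }
  if (file.exists(f$betas)) {
    b <- fread(f$betas, sep = "\t", header = TRUE,
               colClasses = list(character = c("project", "probe_id",
                                               "sample_id"),
                                 numeric = "beta"))
    if (nrow(b) && (anyNA(b$beta) || any(b$beta < 0) || any(b$beta > 1))) {
      stop("beta values outside [0,1] in ", f$betas)
    }
    h$betas <- b
  }
  invisible(h)
}

#' Persist a file-backed store to disk
#'
#' A no-op for the memory backend. Betas are written at full float precision.
#' @param handle a `beta_store`.
#' @return the handle, invisibly.
#' @export
store_flush <- function(handle) {
  if (handle$backend != "file") return(invisible(handle))
  f <- store_files(handle)
  write_annotation_csv(handle$ann, f$ann)
  write_sample_json(unname(handle$samples), f$samples)
  b <- copy(handle$betas)
  b[, beta := sprintf("%.17g", beta)]   # exact double round-trip
  fwrite(b, f$betas, sep = "\t", quote = FALSE)
  invisible(handle)
}

#' @rdname store_flush
#' @export
store_close <- function(handle) store_flush(handle)

# ---- annotation -------------------------------------------------------------

#' Load probe annotation records into a store
#'
#' The annotation (an independent re-annotation of the array's probes) makes
#' probes queryable by id and by genomic interval, and contributes the CpG
#' island density classes and SNP/reliability flags used by the renderer.
#'
#' @param handle a `beta_store`.
#' @param records annotation rows: a data.frame with the columns of
#'   [probe_annotation()].
#' @return number of records loaded, invisibly.
#' @export
load_annotation <- function(handle, records) {
  ann <- validate_annotation(records)
  clash <- intersect(ann$probe_id, handle$ann$probe_id)
  if (length(clash)) {
    bs_stop("duplicate probe_id in annotation: ", clash[1])
  }
  handle$ann <- rbind(handle$ann, ann)
  setkey(handle$ann, probe_id)
  invisible(nrow(ann))
}

# ---- samples ----------------------------------------------------------------

#' Register sample metadata records in a project
#'
#' Metadata is stored verbatim; keys a sample does not have are truly absent
#' (never materialized as nulls). Registering samples is what brings a
#' project into existence.
#'
#' @param handle a `beta_store`.
#' @param project project name; every record's `project` field must match.
#' @param records list of [sample_record()] objects.
#' @return number of records registered, invisibly.
#' @export
register_samples <- function(handle, project, records) {
  if (inherits(records, "sample_record")) records <- list(records)
  ids <- vapply(records, function(r) r$sample_id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    bs_stop("duplicate sample_id within project '", project, "': ", dup[1])
  }
  for (r in records) {
    if (!inherits(r, "sample_record")) bs_stop("records must be sample_record")
    if (r$project != project) {
      bs_stop("record ", r$sample_id, " belongs to project '", r$project,
              "', not '", project, "'")
    }
    if (!is.null(handle$samples[[sample_key(project, r$sample_id)]])) {
      bs_stop("duplicate sample_id within project '", project, "': ",
              r$sample_id)
    }
  }
  for (r in records) {
    handle$samples[[sample_key(project, r$sample_id)]] <- r
  }
  handle$projects <- union(handle$projects, project)
  invisible(length(records))
}

#' Retrieve the sample records of one or more projects
#' @param handle a `beta_store`.
#' @param projects character vector of project names.
#' @return list of `sample_record`, ordered by (project, sample_id).
#' @export
store_samples <- function(handle, projects = handle$projects) {
  check_projects(handle, projects)
  keys <- names(handle$samples)
  out <- list()
  for (p in projects) {
    k <- keys[startsWith(keys, paste0(p, "\r"))]
    out <- c(out, handle$samples[sort(k)])
  }
  unname(out)
}

check_projects <- function(handle, projects) {
  unknown <- setdiff(projects, handle$projects)
  if (length(unknown)) {
    bs_stop("unknown project: ", paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

# ---- betas ------------------------------------------------------------------

#' Deposit one sample's beta values
#'
#' Each value is merged into the single (project, probe) document, which is
#' created on first touch. Re-depositing the same (project, sample, probe)
#' overwrites the stored value. Probes absent from the loaded annotation are
#' skipped and counted, not stored.
#'
#' @param handle a `beta_store`.
#' @param project an existing project.
#' @param sample_id a sample registered in `project`.
#' @param values named numeric vector, `probe_id -> beta` in `[0, 1]`.
#'   `NA` entries are treated as missing measurements and dropped.
#' @return list with `n_written` and `n_unannotated_skipped`.
#' @export
deposit_betas <- function(handle, project, sample_id, values) {
  check_projects(handle, project)
  if (is.null(handle$samples[[sample_key(project, sample_id)]])) {
    bs_stop("unknown sample '", sample_id, "' in project '", project,
            "'; register it first")
  }
  if (length(values) && is.null(names(values))) {
    bs_stop("values must be named by probe_id")
  }
  values <- values[!is.na(values)]
  bad <- which(values < 0 | values > 1)
  if (length(bad)) {
    bs_stop("beta value out of range [0,1] for probe ",
            names(values)[bad[1]], ": ",
            format(values[bad[1]], digits = 15))
  }
  annotated <- names(values) %in% handle$ann$probe_id
  skipped <- sum(!annotated)
  values <- values[annotated]
  if (length(values)) {
    new <- data.table(project = project, probe_id = names(values),
                      sample_id = sample_id, beta = unname(values))
    old <- handle$betas
    keep <- !(old$project == project & old$sample_id == sample_id &
                old$probe_id %in% new$probe_id)
    handle$betas <- rbind(old[keep], new)
  }
  list(n_written = length(values), n_unannotated_skipped = skipped)
}

#' Deposit a beta matrix, one sample column at a time
#'
#' @param handle a `beta_store`.
#' @param project target project.
#' @param bm a [beta_matrix()].
#' @param auto_register if `TRUE`, sample ids not yet registered in `project`
#'   are registered with empty metadata before depositing.
#' @return aggregated list with `n_written` and `n_unannotated_skipped`.
#' @export
deposit_matrix <- function(handle, project, bm, auto_register = FALSE) {
  stopifnot(inherits(bm, "beta_matrix"))
  n_written <- 0L; n_skipped <- 0L
  for (s in bm$sample_ids) {
    if (auto_register &&
        is.null(handle$samples[[sample_key(project, s)]])) {
      register_samples(handle, project, list(sample_record(s, project)))
    }
    v <- bm$values[, s]
    names(v) <- bm$probe_ids
    st <- deposit_betas(handle, project, s, v)
    n_written <- n_written + st$n_written
    n_skipped <- n_skipped + st$n_unannotated_skipped
  }
  list(n_written = n_written, n_unannotated_skipped = n_skipped)
}

#' Count beta documents held by the store
#'
#' One document exists per (project, probe) with at least one value, however
#' many samples contributed — the scaling property of the document model.
#' @param handle a `beta_store`.
#' @param project optional project filter.
#' @return integer document count.
#' @export
store_document_count <- function(handle, project = NULL) {
  b <- handle$betas
  if (!is.null(project)) b <- b[b$project %in% project]
  if (nrow(b) == 0L) return(0L)
  uniqueN(b, by = c("project", "probe_id"))
}

# ---- queries ----------------------------------------------------------------

#' Query all probes and betas in a genomic window
#'
#' Returns annotated probes whose position lies in `region` (both ends
#' inclusive) joined with the beta values of the named projects, sorted by
#' ascending position (probe_id breaks ties). The sample list is the union of
#' samples with at least one value in the window.
#'
#' Sample ids must be unique across the queried projects, since beta maps are
#' keyed by sample id; a collision is an error.
#'
#' @param handle a `beta_store`.
#' @param region a [genomic_region()].
#' @param projects character vector of existing project names.
#' @return a `region_dataset`.
#' @export
query_region <- function(handle, region, projects) {
  stopifnot(inherits(region, "genomic_region"))
  check_projects(handle, projects)

  ann <- handle$ann
  sub <- ann[ann$chromosome == region$chromosome &
               ann$position >= region$start & ann$position <= region$end]
  sub <- sub[order(sub$position, sub$probe_id)]

  b <- handle$betas
  b <- b[b$project %in% projects & b$probe_id %in% sub$probe_id]

  if (nrow(b)) {
    per_sample_projects <- unique(b[, c("project", "sample_id")])
    dup <- per_sample_projects$sample_id[duplicated(per_sample_projects$sample_id)]
    if (length(dup)) {
      bs_stop("sample id '", dup[1], "' occurs in more than one of the ",
              "queried projects; sample ids must be unique across a query")
    }
  }

  betas <- vector("list", nrow(sub))
  for (i in seq_len(nrow(sub))) {
    rows <- b[b$probe_id == sub$probe_id[i]]
    v <- rows$beta
    names(v) <- rows$sample_id
    betas[[i]] <- v[order(names(v))]
  }

  sample_ids <- sort(unique(b$sample_id))
  samples <- list()
  if (length(sample_ids)) {
    proj_of <- setNames(per_sample_projects$project,
                        per_sample_projects$sample_id)
    for (s in sample_ids) {
      samples[[s]] <- handle$samples[[sample_key(proj_of[[s]], s)]]
    }
  }
  region_dataset(region, sub, betas, samples)
}

#' Resolve a locus string to a genomic region
#'
#' Three query forms are accepted:
#' * a coordinate string `"chrN:start-end"` (commas permitted in numbers),
#'   parsed directly;
#' * a probe id known to the annotation, yielding
#'   `[position - flank, position + flank]`;
#' * a gene name (case-insensitive match against annotation gene symbols),
#'   yielding `[min probe position - flank, max probe position + flank]` over
#'   the probes annotated to that gene.
#'
#' A string matching both a probe id and a gene name resolves as a probe id.
#' Regions are clipped at position 1.
#'
#' @param handle a `beta_store` with annotation loaded.
#' @param query the locus string.
#' @param flank flank in base pairs applied to probe/gene resolution.
#' @return a [genomic_region()].
#' @export
resolve_locus <- function(handle, query, flank = 0L) {
  stopifnot(is.character(query), length(query) == 1L)
  flank <- as.integer(flank)
  query <- trimws(query)

  m <- regmatches(query,
                  regexec("^([^: ]+):([0-9][0-9,]*)-([0-9][0-9,]*)$", query))[[1]]
  if (length(m) == 4L) {
    start <- as.integer(gsub(",", "", m[3], fixed = TRUE))
    end <- as.integer(gsub(",", "", m[4], fixed = TRUE))
    return(genomic_region(m[2], start, end))
  }

  ann <- handle$ann
  hit <- which(ann$probe_id == query)
  if (length(hit) == 1L) {
    pos <- ann$position[hit]
    return(genomic_region(ann$chromosome[hit],
                          max(1L, pos - flank), pos + flank))
  }

  gene_lists <- split_genes(ann$genes)
  has_gene <- vapply(gene_lists,
                     function(g) any(toupper(g) == toupper(query)),
                     logical(1))
  if (any(has_gene)) {
    sub <- ann[has_gene]
    # a symbol annotated on several chromosomes: take the modal chromosome
    tab <- sort(table(sub$chromosome), decreasing = TRUE)
    sub <- sub[sub$chromosome == names(tab)[1]]
    return(genomic_region(sub$chromosome[1],
                          max(1L, min(sub$position) - flank),
                          max(sub$position) + flank))
  }

  bs_stop("cannot resolve locus '", query, "'; accepted forms are a ",
          "coordinate string 'chrN:start-end', a probe id, or a gene name")
}

# ---- metadata repair --------------------------------------------------------

#' Rename a metadata key across a project
#'
#' Fixes misspelled keys (e.g. `sxe` -> `sex`) so queries on the corrected
#' key see all samples. Every sample carrying `old_key` has it renamed, with
#' values preserved; samples without it are untouched. If any sample already
#' carries both keys the repair aborts before touching anything
#' (all-or-nothing). Applying the same repair twice equals applying it once.
#'
#' @param handle a `beta_store`.
#' @param project an existing project.
#' @param old_key,new_key key names; `old_key == new_key` is a no-op.
#' @return number of samples changed.
#' @export
repair_metadata_key <- function(handle, project, old_key, new_key) {
  check_projects(handle, project)
  if (identical(old_key, new_key)) return(0L)
  keys <- names(handle$samples)
  keys <- keys[startsWith(keys, paste0(project, "\r"))]
  carriers <- character()
  for (k in keys) {
    md <- handle$samples[[k]]$metadata
    if (old_key %in% names(md)) {
      if (new_key %in% names(md)) {
        bs_stop("sample '", handle$samples[[k]]$sample_id,
                "' already has key '", new_key,
                "'; no samples were modified")
      }
      carriers <- c(carriers, k)
    }
  }
  for (k in carriers) {
    md <- handle$samples[[k]]$metadata
    names(md)[names(md) == old_key] <- new_key
    handle$samples[[k]]$metadata <- md
  }
  length(carriers)
}

#' Rewrite a metadata value across a project
#'
#' Comparison is exact and case-sensitive (`"Female" != "female"`);
#' normalization is deliberately the researcher's job, done through these
#' repair utilities.
#'
#' @param handle a `beta_store`.
#' @param project an existing project.
#' @param key metadata key to inspect.
#' @param old_value,new_value scalar values; samples whose `key` equals
#'   `old_value` exactly get `new_value`.
#' @return number of samples changed.
#' @export
repair_metadata_value <- function(handle, project, key, old_value, new_value) {
  check_projects(handle, project)
  keys <- names(handle$samples)
  keys <- keys[startsWith(keys, paste0(project, "\r"))]
  n <- 0L
  for (k in keys) {
    md <- handle$samples[[k]]$metadata
    if (key %in% names(md) && identical(md[[key]], old_value)) {
      handle$samples[[k]]$metadata[[key]] <- new_value
      n <- n + 1L
    }
  }
  n
}

# ---- dump / restore ---------------------------------------------------------

#' Dump a store as JSON lines
#'
#' Lossless export of annotation, samples and beta documents, one JSON object
#' per line with a `"_type"` discriminator in `{annotation, sample, betas}`.
#' Output order and object keys are deterministic, so
#' dump -> restore -> dump is byte-identical.
#'
#' @param handle a `beta_store`.
#' @param path optional file to write; when `NULL` the lines are returned.
#' @return character vector of JSON lines (invisibly when `path` given).
#' @export
store_dump <- function(handle, path = NULL) {
  lines <- character()

  ann <- handle$ann[order(handle$ann$probe_id)]
  for (i in seq_len(nrow(ann))) {
    rec <- c(list(`_type` = "annotation"), as.list(ann[i]))
    lines <- c(lines, jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }

  for (r in store_samples(handle, sort(handle$projects))) {
    md <- r$metadata
    if (length(md)) md <- md[order(names(md))]
    rec <- list(`_type` = "sample", project = r$project,
                sample_id = r$sample_id,
                metadata = if (length(md)) md else structure(list(),
                                                             names = character()))
    lines <- c(lines, jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }

  b <- handle$betas
  if (nrow(b)) {
    docs <- unique(b[, c("project", "probe_id")])
    docs <- docs[order(docs$project, docs$probe_id)]
    pos <- setNames(handle$ann$position, handle$ann$probe_id)
    chr <- setNames(handle$ann$chromosome, handle$ann$probe_id)
    for (i in seq_len(nrow(docs))) {
      p <- docs$project[i]; pr <- docs$probe_id[i]
      rows <- b[b$project == p & b$probe_id == pr]
      v <- as.list(setNames(rows$beta, rows$sample_id))
      v <- v[order(names(v))]
      rec <- list(`_type` = "betas", project = p, probe_id = pr,
                  chromosome = unname(chr[pr]),
                  position = unname(pos[pr]), betas = v)
      lines <- c(lines, jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
    }
  }

  lines <- as.character(lines)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Restore a store from JSON lines produced by [store_dump()]
#'
#' @param lines character vector of JSON lines, or a file path.
#' @param path,backend forwarded to [open_store()].
#' @return a new `beta_store`.
#' @export
store_restore <- function(lines, path = NULL, backend = "memory") {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  h <- open_store(path, backend)
  ann_rows <- list(); sample_recs <- list(); beta_rows <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    doc <- jsonlite::fromJSON(lines[i], simplifyVector = FALSE)
    type <- doc[["_type"]]
    if (identical(type, "annotation")) {
      doc[["_type"]] <- NULL
      ann_rows[[length(ann_rows) + 1L]] <- doc
    } else if (identical(type, "sample")) {
      sample_recs[[length(sample_recs) + 1L]] <-
        sample_record(doc$sample_id, doc$project,
                      lapply(doc$metadata, identity))
    } else if (identical(type, "betas")) {
      beta_rows[[length(beta_rows) + 1L]] <- doc
    } else {
      bs_stop("line ", i, ": unknown document _type")
    }
  }
  if (length(ann_rows)) {
    load_annotation(h, rbindlist(ann_rows))
  }
  by_project <- split(sample_recs,
                      vapply(sample_recs, function(r) r$project, character(1)))
  for (p in names(by_project)) register_samples(h, p, by_project[[p]])
  for (doc in beta_rows) {
    for (s in names(doc$betas)) {
      v <- setNames(as.numeric(doc$betas[[s]]), doc$probe_id)
      deposit_betas(h, doc$project, s, v)
    }
  }
  h
}

# ---- annotation CSV interface ----------------------------------------------

#' Read / write the annotation CSV interchange format
#'
#' Header `probe_id,chromosome,position,strand,genes,island_class,
#' snp_in_probe,snp_at_cpg,reliable`; `genes` is `;`-separated; booleans are
#' written `true`/`false`.
#'
#' @param path CSV file path.
#' @return `read_annotation_csv`: a validated annotation `data.table`.
#' @export
read_annotation_csv <- function(path) {
  ann <- fread(path, sep = ",", header = TRUE, colClasses = "character",
               na.strings = NULL)
  missing_cols <- setdiff(ANNOTATION_COLUMNS, names(ann))
  if (length(missing_cols)) {
    bs_stop("annotation CSV ", path, " is missing column(s): ",
            paste(missing_cols, collapse = ", "))
  }
  ann[, position := as.integer(position)]
  for (col in c("snp_in_probe", "snp_at_cpg", "reliable")) {
    v <- tolower(ann[[col]])
    if (!all(v %in% c("true", "false"))) {
      bs_stop("annotation CSV column ", col, " must be true/false")
    }
    set(ann, j = col, value = v == "true")
  }
  validate_annotation(ann)
}

#' @rdname read_annotation_csv
#' @param ann annotation table.
#' @export
write_annotation_csv <- function(ann, path) {
  out <- as.data.table(ann)[, ANNOTATION_COLUMNS, with = FALSE]
  for (col in c("snp_in_probe", "snp_at_cpg", "reliable")) {
    set(out, j = col, value = ifelse(out[[col]], "true", "false"))
  }
  fwrite(out, path, sep = ",", quote = FALSE)
  invisible(path)
}
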
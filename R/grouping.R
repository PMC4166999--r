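#' Specify how samples are partitioned into display groups
#'
#' Two modes exist. Within a single project, samples may be stratified by the
#' values of up to three metadata keys simultaneously (e.g. age bin, sex and
#' treatment arm). Across projects, comparison is only offered on the two
#' reserved keys, `project` and `tissuetype`.
#'
#' @param mode `"within_project"` or `"cross_project"`.
#' @param keys metadata key names: 1 to 3 keys in `within_project` mode;
#'   exactly one of `"project"` / `"tissuetype"` in `cross_project` mode.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(mode = c("within_project", "cross_project"), keys) {
  mode <- match.arg(mode)
  keys <- as.character(keys)
  if (length(keys) == 0L) bs_stop("at least one grouping key is required")
  if (mode == "within_project") {
    if (length(keys) > 3L) {
      bs_stop("samples can be grouped by at most three keys within a ",
              "project; got ", length(keys))
    }
  } else {
    if (length(keys) != 1L || !keys %in% c("project", "tissuetype")) {
      bs_stop("cross-project grouping is only available on the reserved ",
              "keys 'project' or 'tissuetype'")
    }
  }
  structure(list(mode = mode, keys = keys), class = "group_spec")
}

# Scalar values compare exactly: the internal group key carries the value's
# type, so numeric 1 and string "1" land in different groups. Displayed
# labels join the values with " / " in key order.
value_token <- function(v) paste0(typeof(v), "\x1f", as.character(v))

group_label <- function(values) {
  paste(vapply(values, as.character, character(1)), collapse = " / ")
}

# Looks a metadata key up on a record; the reserved key "project" always
# resolves to the record's project field.
sample_value <- function(record, key) {
  if (key == "project") return(record$project)
  record$metadata[[key]]
}

#' Partition samples into groups by metadata values
#'
#' Each sample possessing all of the spec's keys joins the group labeled by
#' its value tuple; a sample missing any key is excluded (it will not be
#' displayed). Group order is deterministic: labels sort lexicographically by
#' value tuple.
#'
#' @param samples list of [sample_record()].
#' @param spec a [group_spec()].
#' @return An object of class `group_assignment`: list with `groups` (named
#'   list, label -> character vector of sample ids), `excluded` (character
#'   vector), `keys` and `mode`.
#' @export
group_samples <- function(samples, spec) {
  stopifnot(inherits(spec, "group_spec"))
  tokens <- character(length(samples))
  labels <- character(length(samples))
  has_all <- logical(length(samples))
  for (i in seq_along(samples)) {
    r <- samples[[i]]
    vals <- lapply(spec$keys, function(k) sample_value(r, k))
    if (any(vapply(vals, is.null, logical(1)))) {
      has_all[i] <- FALSE
    } else {
      has_all[i] <- TRUE
      tokens[i] <- paste(vapply(vals, value_token, character(1)),
                         collapse = "\x1e")
      labels[i] <- group_label(vals)
    }
  }
  ids <- vapply(samples, function(r) r$sample_id, character(1))
  excluded <- ids[!has_all]
  groups <- list()
  if (any(has_all)) {
    tok_in <- tokens[has_all]; ids_in <- ids[has_all]; lab_in <- labels[has_all]
    toks <- sort(unique(tok_in))
    # distinct value tuples can share a display label (e.g. numeric 1 vs
    # string "1"); disambiguate rather than silently merging
    labs <- make.unique(vapply(toks, function(tok)
      lab_in[tok_in == tok][1], character(1)), sep = " #")
    for (i in seq_along(toks)) {
      groups[[labs[i]]] <- ids_in[tok_in == toks[i]]
    }
  }
  structure(list(groups = groups, excluded = excluded,
                 keys = spec$keys, mode = spec$mode),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("<group_assignment> by (", paste(x$keys, collapse = ", "), "): ",
      length(x$groups), " groups, ", length(x$excluded), " excluded\n",
      sep = "")
  for (lab in names(x$groups)) {
    cat("  ", lab, ": ", length(x$groups[[lab]]), " samples\n", sep = "")
  }
  invisible(x)
}

#' Group samples across projects on a reserved key
#'
#' Pools the samples of several projects and partitions them on `"project"`
#' (never excludes anyone: every sample belongs to a project) or
#' `"tissuetype"` (samples lacking the key are excluded from display).
#'
#' @param handle a `beta_store`.
#' @param projects character vector of existing project names.
#' @param key `"project"` or `"tissuetype"`.
#' @return a `group_assignment`.
#' @export
cross_project_groups <- function(handle, projects, key) {
  spec <- group_spec("cross_project", key)
  samples <- store_samples(handle, projects)
  ids <- vapply(samples, function(r) r$sample_id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    bs_stop("sample id '", dup[1], "' occurs in more than one project; ",
            "sample ids must be unique across grouped projects")
  }
  group_samples(samples, spec)
}

#' Restrict a group assignment to a subset of samples
#'
#' Used by the renderer and the CLI's `--hide` option: hidden samples are
#' dropped from groups and from the excluded list alike.
#'
#' @param assignment a `group_assignment`.
#' @param keep character vector of sample ids to keep.
#' @return a `group_assignment` over the kept samples; empty groups vanish.
#' @export
filter_groups <- function(assignment, keep) {
  groups <- lapply(assignment$groups, function(ids) ids[ids %in% keep])
  groups <- groups[vapply(groups, length, integer(1)) > 0L]
  structure(list(groups = groups,
                 excluded = assignment$excluded[assignment$excluded %in% keep],
                 keys = assignment$keys, mode = assignment$mode),
            class = "group_assignment")
}
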
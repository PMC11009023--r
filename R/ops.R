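#' Extract 0-indexed region coordinates for one modality
#'
#' Walks the modality's atomic regions in 5' to 3' order, accumulating
#' cumulative minimum and maximum lengths, and assigns each leaf a 0-based
#' half-open interval: `[start_min, stop_min)` under the all-minimum length
#' assignment and `[start_max, stop_max)` under the all-maximum one. An
#' interval is `fixed` only when the leaf and everything upstream of it have
#' `min_len == max_len`, i.e. when its absolute offset is the same in every
#' molecule -- the property fixed-geometry preprocessors rely on and that
#' variable-length barcode designs (inDrops-style) violate.
#'
#' Consecutive intervals tile the layout with no gaps or overlaps:
#' `start(i+1) = stop(i)` on both the min and max tracks.
#'
#' @param assay An [assay()].
#' @param modality One of `assay$modalities`.
#' @param subset Optional character vector of `region_type`s; only matching
#'   intervals are returned, but coordinates are still computed against the
#'   full layout (filtering never shifts positions).
#' @return An object of class `"index_result"`: a list with `modality` and
#'   `intervals`, a data frame with columns `region_id`, `region_type`,
#'   `start_min`, `start_max`, `stop_min`, `stop_max`, `fixed`.
#' @export
spec_index <- function(assay, modality, subset = NULL) {
  tree <- modality_tree(assay, modality)
  lv <- leaves(tree)
  if (length(lv) == 1L && identical(lv[[1L]]$sequence_type, "joined")) {
    stop(sprintf("modality '%s' has an empty region tree", modality),
         call. = FALSE)
  }
  n <- length(lv)
  df <- data.frame(
    region_id = vapply(lv, function(l) l$region_id, character(1)),
    region_type = vapply(lv, function(l) l$region_type, character(1)),
    start_min = integer(n), start_max = integer(n),
    stop_min = integer(n), stop_max = integer(n),
    fixed = logical(n), stringsAsFactors = FALSE
  )
  cmin <- 0L; cmax <- 0L; rigid <- TRUE
  for (i in seq_len(n)) {
    l <- lv[[i]]
    df$start_min[i] <- cmin
    df$start_max[i] <- cmax
    df$stop_min[i] <- cmin + l$min_len
    df$stop_max[i] <- cmax + l$max_len
    df$fixed[i] <- rigid && l$min_len == l$max_len
    cmin <- cmin + l$min_len
    cmax <- cmax + l$max_len
    rigid <- rigid && l$min_len == l$max_len
  }
  if (!is.null(subset)) {
    df <- df[df$region_type %in% subset, , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(list(modality = modality, intervals = df),
            class = "index_result")
}

#' @export
print.index_result <- function(x, ...) {
  cat(sprintf("<index> modality %s\n", x$modality))
  print(x$intervals, row.names = FALSE)
  invisible(x)
}

#' Auto-populate meta-region metadata across a document
#'
#' Applies [resolve_joined()] to every top-level region; the header is
#' untouched. Idempotent.
#'
#' @param assay An [assay()].
#' @return The formatted [assay()].
#' @export
spec_format <- function(assay) {
  stopifnot(inherits(assay, "assay"))
  assay$library_spec <- lapply(assay$library_spec, resolve_joined)
  assay
}

#' Modify attributes of one region
#'
#' Replaces the named fields of the region identified by `region_id`,
#' re-applies [spec_format()] so every ancestor's joined metadata stays
#' consistent, and rejects the update if it would leave the document with
#' any error-severity violation (the error message carries the violation
#' code, e.g. `FIXED_SEQ_LEN` or `DUP_ID`). The input assay is unchanged
#' (value semantics).
#'
#' @param assay An [assay()] that passes [spec_check()] structurally.
#' @param region_id Identifier of the region to edit.
#' @param updates Named list of field replacements; names must be region
#'   schema fields other than `regions`.
#' @return The updated, re-formatted [assay()].
#' @export
spec_modify <- function(assay, region_id, updates) {
  stopifnot(inherits(assay, "assay"), is.list(updates))
  if (is.null(find_by_id(assay, region_id))) {
    stop(sprintf("unknown region_id '%s'", region_id), call. = FALSE)
  }
  editable <- setdiff(REGION_KEYS, "regions")
  bad <- setdiff(names(updates), editable)
  if (length(bad) > 0L) {
    stop(sprintf("schema error: unknown region field(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out <- assay
  out$library_spec <- lapply(out$library_spec, function(tree) {
    edit_region(tree, region_id, updates)
  })
  out <- spec_format(out)
  v <- spec_check(out, resolve_files = FALSE)
  ne <- v[v$severity == "error", , drop = FALSE]
  if (nrow(ne) > 0L) {
    stop(sprintf("modify rejected: %s (%s)", ne$code[1L], ne$message[1L]),
         call. = FALSE)
  }
  out
}

edit_region <- function(r, region_id, updates) {
  if (r$region_id == region_id) {
    for (k in names(updates)) {
      val <- updates[[k]]
      r[[k]] <- if (k %in% c("min_len", "max_len")) as.integer(val) else val
    }
    return(r)
  }
  r$regions <- lapply(r$regions, edit_region, region_id = region_id,
                      updates = updates)
  r
}

#' Split a multi-modality document into single-modality documents
#'
#' @param assay An [assay()].
#' @return A list of [assay()]s, one per modality in original order; each
#'   keeps the full header with `modalities` reduced to the one modality.
#'   Concatenating the outputs' `library_spec`s restores the input's.
#' @export
spec_split <- function(assay) {
  stopifnot(inherits(assay, "assay"))
  lapply(assay$modalities, function(m) {
    out <- assay
    out$modalities <- m
    out$library_spec <- list(modality_tree(assay, m))
    out
  })
}

#' Resolve the onlist for a region type
#'
#' With exactly one matching onlist-bearing region, returns its onlist path
#' verbatim. With several (split-pool designs carry multiple barcode
#' rounds), the behavior is chosen by `combine`: `"multifile"` returns all
#' paths in 5' to 3' order; `"product"` materializes a new file whose lines
#' are every ordered concatenation of one sequence from each list (the
#' Cartesian product, row-major in 5' to 3' order -- the order in which the
#' segments appear in a read) and returns its path.
#'
#' @param assay An [assay()].
#' @param modality One of `assay$modalities`.
#' @param region_type Type whose onlists are wanted (typically
#'   `"barcode"`).
#' @param combine `"multifile"` or `"product"`.
#' @param dir Base directory for resolving relative onlist paths; defaults
#'   to the spec's directory.
#' @param outdir Directory the materialized product file is written to
#'   (`combine = "product"` only).
#' @return A character path (single match or `combine = "product"`) or a
#'   character vector of paths (`combine = "multifile"`).
#' @export
onlist_resolve <- function(assay, modality, region_type = "barcode",
                           combine = c("multifile", "product"),
                           dir = attr(assay, "base_dir"),
                           outdir = tempdir()) {
  combine <- match.arg(combine)
  regions <- find_by_type(assay, modality, region_type)
  regions <- Filter(function(r) !is.null(r$onlist), regions)
  if (length(regions) == 0L) {
    stop(sprintf("no region of type '%s' with an onlist under modality '%s'",
                 region_type, modality), call. = FALSE)
  }
  paths <- vapply(regions, function(r) onlist_path(r$onlist, dir), character(1))
  if (length(regions) == 1L) return(regions[[1L]]$onlist$filename)
  if (combine == "multifile") return(paths)
  remote <- vapply(regions, function(r) !identical(r$onlist$location, "local"),
                   logical(1))
  if (any(remote)) {
    stop("cannot take the product: remote onlist(s): ",
         paste(vapply(regions[remote], function(r) r$onlist$filename,
                      character(1)), collapse = ", "), call. = FALSE)
  }
  lists <- lapply(regions, function(r) read_onlist(r$onlist, dir))
  combined <- onlist_product(lists)
  out <- file.path(outdir, sprintf("onlist_%s_%s_product.txt", modality,
                                   region_type))
  writeLines(combined, out)
  out
}

#' Cartesian product of onlists
#'
#' Row-major in 5' to 3' list order: the first list varies slowest. For
#' lists of sizes `m` and `n` the result has exactly `m * n` lines.
#'
#' @param lists List of character vectors of sequences, 5' to 3'.
#' @return Character vector of concatenated sequences.
#' @export
onlist_product <- function(lists) {
  out <- ""
  for (l in lists) {
    out <- paste0(rep(out, each = length(l)), rep(l, times = length(out)))
  }
  out
}

#' Summarize an assay document
#'
#' @param assay An [assay()].
#' @return A list with `assay_id`, `name`, `description` (`NULL` when absent
#'   or empty), `modalities`, `seqspec_version`, and `per_modality`, a data
#'   frame with one row per modality giving its leaf count and total
#'   minimum/maximum length in bases.
#' @export
spec_info <- function(assay) {
  stopifnot(inherits(assay, "assay"))
  per <- do.call(rbind, lapply(assay$modalities, function(m) {
    tree <- modality_tree(assay, m)
    lv <- leaves(tree)
    data.frame(modality = m, n_leaves = length(lv),
               min_len = sum_leaf(tree, "min_len"),
               max_len = sum_leaf(tree, "max_len"),
               stringsAsFactors = FALSE)
  }))
  desc <- assay$description
  if (!is.null(desc) && !nzchar(desc)) desc <- NULL
  structure(list(
    assay_id = assay$assay_id, name = assay$name, description = desc,
    modalities = assay$modalities, seqspec_version = assay$seqspec_version,
    per_modality = per
  ), class = "spec_info")
}

#' @export
print.spec_info <- function(x, ...) {
  cat(sprintf("%s (%s), format v%s\n", x$assay_id, x$name, x$seqspec_version))
  if (!is.null(x$description)) cat(x$description, "\n")
  print(x$per_modality, row.names = FALSE)
  invisible(x)
}

#' Report toolkit and document format versions
#'
#' @param assay Optional [assay()]; when given, its `seqspec_version` is
#'   echoed (with a warning if it is not a well-formed semantic version).
#' @return A list with `tool_version` and, when an assay is given,
#'   `spec_version`.
#' @export
spec_version <- function(assay = NULL) {
  out <- list(tool_version = as.character(utils::packageVersion("assayspec")))
  if (!is.null(assay)) {
    sv <- assay$seqspec_version
    if (!grepl("^[0-9]+\\.[0-9]+\\.[0-9]+$", sv)) {
      warning(sprintf("malformed seqspec_version string '%s'", sv),
              call. = FALSE)
    }
    out$spec_version <- sv
  }
  out
}
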
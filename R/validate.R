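violation <- function(code, path, message, severity = "error") {
  data.frame(code = code, path = path, message = message,
             severity = severity, stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(code = character(), path = character(), message = character(),
             severity = character(), stringsAsFactors = FALSE)
}

#' Validate an assay document
#'
#' Verifies a parsed assay against every semantic invariant of the format
#' and returns the complete list of violations (no early exit), ordered by
#' node path. An empty result means the document is valid. Checks performed:
#'
#' * `DUP_ID` -- region identifiers must be unique across the document;
#' * `LEN_ORDER` -- `min_len <= max_len` on every region;
#' * `FIXED_SEQ_LEN` -- a fixed-sequence region must carry a non-empty
#'   sequence without `N`/`X` placeholders whose length equals both bounds;
#' * `JOIN_MISMATCH` -- meta regions must be `joined` and agree with the
#'   recomputation by [resolve_joined()]; atomic regions must not be
#'   `joined`;
#' * `ONLIST_MISSING` -- onlist-type regions must reference an onlist (and,
#'   with `resolve_files = TRUE`, the local file must exist and pass its
#'   md5);
#' * `ONLIST_LEN` -- with `resolve_files = TRUE`, every sequence in a local
#'   onlist must have length within the owning region's
#'   `[min_len, max_len]` (variable-length barcode lists are therefore
#'   legal);
#' * `MODALITY_MAP` -- modalities must be non-empty, duplicate-free, and in
#'   bijection with the top-level regions (matched by `region_id`);
#' * `UNKNOWN_TYPE` -- a `region_type` outside the controlled vocabulary is
#'   reported at *warning* severity, so novel designs remain expressible.
#'
#' All codes except `UNKNOWN_TYPE` have severity `"error"`.
#'
#' @param assay An [assay()].
#' @param resolve_files Whether local onlist files are opened and checked
#'   (existence, md5, sequence alphabet and lengths).
#' @param dir Base directory for relative onlist paths; defaults to the
#'   directory the spec was read from, if any.
#' @return A data frame with columns `code`, `path`, `message`, `severity`;
#'   zero rows iff the document is valid.
#' @export
spec_check <- function(assay, resolve_files = TRUE,
                       dir = attr(assay, "base_dir")) {
  stopifnot(inherits(assay, "assay"))
  v <- no_violations()
  nodes <- walk_assay(assay)
  ids <- vapply(nodes, function(n) n$region$region_id, character(1))
  paths <- vapply(nodes, function(n) n$path, character(1))

  ## DUP_ID: one violation per duplicated id, naming every path involved
  for (id in unique(ids[duplicated(ids)])) {
    at <- paths[ids == id]
    v <- rbind(v, violation(
      "DUP_ID", at[1L],
      sprintf("region_id '%s' is used by %d regions: %s",
              id, length(at), paste(at, collapse = ", "))))
  }

  ## MODALITY_MAP: header-level bijection
  mods <- assay$modalities
  if (length(mods) == 0L) {
    v <- rbind(v, violation("MODALITY_MAP", "/", "modalities list is empty"))
  }
  if (anyDuplicated(mods)) {
    v <- rbind(v, violation(
      "MODALITY_MAP", "/",
      sprintf("duplicate modality: %s",
              paste(unique(mods[duplicated(mods)]), collapse = ", "))))
  }
  top_ids <- vapply(assay$library_spec, function(r) r$region_id, character(1))
  for (m in setdiff(mods, top_ids)) {
    v <- rbind(v, violation(
      "MODALITY_MAP", "/",
      sprintf("modality '%s' has no top-level region", m)))
  }
  for (t in setdiff(top_ids, mods)) {
    v <- rbind(v, violation(
      "MODALITY_MAP", paste0("/", t),
      sprintf("top-level region '%s' is not a declared modality", t)))
  }
  if (anyDuplicated(top_ids)) {
    for (t in unique(top_ids[duplicated(top_ids)])) {
      v <- rbind(v, violation(
        "MODALITY_MAP", paste0("/", t),
        sprintf("modality '%s' has more than one top-level region", t)))
    }
  }

  for (node in nodes) {
    r <- node$region
    p <- node$path
    if (r$min_len > r$max_len) {
      v <- rbind(v, violation(
        "LEN_ORDER", p,
        sprintf("min_len (%d) exceeds max_len (%d)", r$min_len, r$max_len)))
    }
    if (!r$region_type %in% REGION_TYPES) {
      v <- rbind(v, violation(
        "UNKNOWN_TYPE", p,
        sprintf("region_type '%s' is outside the controlled vocabulary",
                r$region_type), severity = "warning"))
    }
    if (is_meta(r)) {
      resolved <- tryCatch(resolve_joined(r), error = function(e) NULL)
      if (!identical(r$sequence_type, "joined")) {
        v <- rbind(v, violation(
          "JOIN_MISMATCH", p,
          sprintf("meta region has sequence_type '%s'; must be 'joined'",
                  r$sequence_type)))
      } else if (!is.null(resolved) &&
                 !(identical(r$sequence, resolved$sequence) &&
                   r$min_len == resolved$min_len &&
                   r$max_len == resolved$max_len)) {
        v <- rbind(v, violation(
          "JOIN_MISMATCH", p,
          sprintf(paste0("joined metadata disagrees with children: stored ",
                         "%d-%d bp, recomputed %d-%d bp"),
                  r$min_len, r$max_len, resolved$min_len, resolved$max_len)))
      }
    } else {
      switch(r$sequence_type,
        joined = {
          v <- rbind(v, violation(
            "JOIN_MISMATCH", p,
            "atomic region cannot have sequence_type 'joined'"))
        },
        fixed = {
          if (!nzchar(r$sequence) || grepl("[NX]", r$sequence) ||
              nchar(r$sequence) != r$min_len ||
              nchar(r$sequence) != r$max_len) {
            v <- rbind(v, violation(
              "FIXED_SEQ_LEN", p,
              sprintf(paste0("fixed region requires a concrete sequence with ",
                             "min_len = max_len = length(sequence); have ",
                             "%d bases, bounds %d-%d"),
                      nchar(r$sequence), r$min_len, r$max_len)))
          }
        },
        onlist = {
          if (is.null(r$onlist)) {
            v <- rbind(v, violation(
              "ONLIST_MISSING", p,
              "onlist-type region has no onlist reference"))
          } else if (resolve_files &&
                     identical(r$onlist$location, "local")) {
            v <- rbind(v, check_onlist_file(r, p, dir))
          }
        }
      )
    }
  }

  v <- v[order(v$path, v$code), , drop = FALSE]
  rownames(v) <- NULL
  v
}

check_onlist_file <- function(r, path, dir) {
  seqs <- tryCatch(read_onlist(r$onlist, dir), error = function(e) e)
  if (inherits(seqs, "error")) {
    return(violation("ONLIST_MISSING", path, conditionMessage(seqs)))
  }
  lens <- nchar(seqs)
  bad <- lens < r$min_len | lens > r$max_len
  if (any(bad)) {
    return(violation(
      "ONLIST_LEN", path,
      sprintf("%d of %d onlist sequences have lengths outside [%d, %d]",
              sum(bad), length(seqs), r$min_len, r$max_len)))
  }
  no_violations()
}

#' Count error-severity violations
#' @param violations Result of [spec_check()].
#' @return Integer count of rows with severity `"error"`.
#' @export
n_errors <- function(violations) sum(violations$severity == "error")
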
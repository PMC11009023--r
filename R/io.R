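HEADER_KEYS <- c("seqspec_version", "assay_id", "name", "doi", "date",
                 "description", "modalities", "library_spec")
REGION_KEYS <- c("region_id", "region_type", "name", "sequence_type",
                 "sequence", "min_len", "max_len", "onlist", "regions")
REQUIRED_REGION_KEYS <- c("region_id", "region_type", "sequence_type",
                          "min_len", "max_len")
REQUIRED_HEADER_KEYS <- c("assay_id", "name", "modalities",
                          "seqspec_version", "library_spec")

#' Parse an assay specification document
#'
#' Parses a YAML document into an [assay()]. Two dialects are accepted: the
#' canonical plain-mapping form that [write_spec()] emits, and a tagged-node
#' form (mappings prefixed with document tags such as `!Region`), which
#' parses to the identical assay. Unknown top-level keys are preserved in
#' `$meta` so a round trip is lossless. Semantic invariants are *not*
#' verified here -- that is [spec_check()]'s job; only structural schema
#' requirements (required keys present, correct nesting) are enforced.
#'
#' @param text A single string holding the YAML document.
#' @return An [assay()].
#' @seealso [read_spec()] to parse from a file, [write_spec()] for the
#'   inverse.
#' @export
parse_spec <- function(text) {
  doc <- tryCatch(
    yaml::yaml.load(text),
    error = function(e) stop("YAML parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (!is.list(doc)) stop("YAML parse error: document is not a mapping",
                          call. = FALSE)
  for (k in REQUIRED_HEADER_KEYS) {
    if (!k %in% names(doc)) {
      stop(sprintf("schema error: missing required key '%s' at document root", k),
           call. = FALSE)
    }
  }
  spec <- doc$library_spec
  if (!is.list(spec)) {
    stop("schema error: 'library_spec' must be a sequence of regions",
         call. = FALSE)
  }
  regions <- lapply(seq_along(spec), function(i) {
    parse_region(spec[[i]], path = sprintf("library_spec[%d]", i))
  })
  extra <- doc[setdiff(names(doc), HEADER_KEYS)]
  assay(
    assay_id = doc$assay_id,
    name = doc$name,
    doi = doc$doi,
    date = if (is.null(doc$date)) NULL else as.character(doc$date),
    description = doc$description,
    modalities = as.character(unlist(doc$modalities)),
    seqspec_version = doc$seqspec_version,
    library_spec = regions,
    meta = extra
  )
}

parse_region <- function(node, path) {
  if (!is.list(node)) {
    stop(sprintf("schema error: expected a region mapping at %s", path),
         call. = FALSE)
  }
  here <- if (!is.null(node$region_id)) {
    paste0(path, "/", node$region_id)
  } else path
  for (k in REQUIRED_REGION_KEYS) {
    if (!k %in% names(node)) {
      stop(sprintf("schema error: missing required key '%s' at %s", k, here),
           call. = FALSE)
    }
  }
  ol <- NULL
  if (!is.null(node$onlist)) {
    if (!is.list(node$onlist) || is.null(node$onlist$filename)) {
      stop(sprintf("schema error: malformed onlist at %s", here), call. = FALSE)
    }
    ol <- onlist_ref(node$onlist$filename,
                     location = node$onlist$location %||% "local",
                     md5 = node$onlist$md5)
  }
  kids <- node$regions
  children <- if (is.null(kids) || length(kids) == 0L) list() else {
    lapply(seq_along(kids), function(i) parse_region(kids[[i]], here))
  }
  region(
    region_id = node$region_id,
    region_type = node$region_type,
    name = node$name %||% as.character(node$region_id),
    sequence_type = node$sequence_type,
    sequence = node$sequence %||% "",
    min_len = node$min_len,
    max_len = node$max_len,
    onlist = ol,
    regions = children
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an assay specification from a file
#'
#' @param path Path to a `.yaml` assay specification.
#' @return An [assay()]; the file's directory is recorded in the `"base_dir"`
#'   attribute so relative onlist paths can be resolved later.
#' @export
read_spec <- function(path) {
  if (!file.exists(path)) stop("spec file not found: ", path, call. = FALSE)
  a <- parse_spec(paste(readLines(path, warn = FALSE), collapse = "\n"))
  attr(a, "base_dir") <- dirname(normalizePath(path))
  a
}

region_to_list <- function(r) {
  list(
    region_id = r$region_id,
    region_type = r$region_type,
    name = r$name,
    sequence_type = r$sequence_type,
    sequence = r$sequence,
    min_len = r$min_len,
    max_len = r$max_len,
    onlist = if (is.null(r$onlist)) NULL else {
      ol <- list(filename = r$onlist$filename, location = r$onlist$location)
      if (!is.null(r$onlist$md5)) ol$md5 <- r$onlist$md5
      ol
    },
    regions = lapply(r$regions, region_to_list)
  )
}

#' Serialize an assay specification to YAML
#'
#' Emits canonical, untagged block-style YAML: fixed key order, 2-space
#' indentation, byte-deterministic. `parse_spec(write_spec(a))` restores `a`
#' for every well-formed assay; child order is preserved, so two assays that
#' differ only in region order serialize to distinct texts.
#'
#' @param assay An [assay()].
#' @return A single YAML string.
#' @export
write_spec <- function(assay) {
  stopifnot(inherits(assay, "assay"))
  doc <- list(seqspec_version = assay$seqspec_version,
              assay_id = assay$assay_id,
              name = assay$name)
  if (!is.null(assay$doi)) doc$doi <- assay$doi
  if (!is.null(assay$date)) doc$date <- assay$date
  if (!is.null(assay$description)) doc$description <- assay$description
  doc$modalities <- as.list(assay$modalities)
  for (k in names(assay$meta)) doc[[k]] <- assay$meta[[k]]
  doc$library_spec <- lapply(assay$library_spec, region_to_list)
  yaml::as.yaml(doc, indent = 2, indent.mapping.sequence = FALSE)
}

#' Write an assay specification file
#' @param assay An [assay()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spec_file <- function(assay, path) {
  writeLines(sub("\n$", "", write_spec(assay)), path)
  invisible(path)
}

#' Resolve an onlist reference to a concrete file path
#'
#' @param ref An [onlist_ref()].
#' @param dir Directory against which a relative local filename is resolved
#'   (typically the spec file's directory); `NULL` leaves it as-is.
#' @return Character path.
#' @export
onlist_path <- function(ref, dir = NULL) {
  stopifnot(inherits(ref, "onlist"))
  if (identical(ref$location, "local") && !is.null(dir) &&
      !grepl("^(/|[A-Za-z]:)", ref$filename)) {
    file.path(dir, ref$filename)
  } else {
    ref$filename
  }
}

#' Read the sequences of an onlist file
#'
#' Reads one sequence per non-empty line, uppercased, in file order. Files
#' whose name ends in `.gz` are decompressed transparently; both LF and CRLF
#' line endings are accepted. When the reference carries an `md5`, the
#' checksum of the file's raw bytes must match. Sequences must be over the
#' alphabet `A,C,G,T`.
#'
#' @param ref An [onlist_ref()] with `location = "local"`.
#' @param dir Base directory for relative paths (see [onlist_path()]).
#' @return Character vector of sequences.
#' @export
read_onlist <- function(ref, dir = NULL) {
  stopifnot(inherits(ref, "onlist"))
  if (!identical(ref$location, "local")) {
    stop("cannot read remote onlist '", ref$filename,
         "': remote onlists are never fetched", call. = FALSE)
  }
  path <- onlist_path(ref, dir)
  if (!file.exists(path)) {
    stop("onlist file not found: ", path, call. = FALSE)
  }
  if (!is.null(ref$md5)) {
    have <- unname(tools::md5sum(path))
    if (!identical(tolower(have), tolower(ref$md5))) {
      stop(sprintf("onlist integrity error: md5 mismatch for %s (expected %s, got %s)",
                   path, ref$md5, have), call. = FALSE)
    }
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  raw_lines <- sub("\r$", "", readLines(con, warn = FALSE))
  keep <- nzchar(raw_lines)
  seqs <- toupper(raw_lines[keep])
  bad <- which(grepl("[^ACGT]", seqs))
  if (length(bad) > 0L) {
    lineno <- which(keep)[bad[1L]]
    stop(sprintf("onlist content error: line %d of %s contains characters outside {A,C,G,T}",
                 lineno, path), call. = FALSE)
  }
  seqs
}

## ---- newick ----------------------------------------------------------------

#' Parse a newick string into a region tree
#'
#' Grammar (fixed by this package, documented in the CLI help): a leaf is
#' `id:length` with a non-negative integer length in bases; an internal node
#' is `(child,child,...)id` with a bare label; the tree ends with `;`.
#' Each leaf becomes an atomic region (`sequence_type = "random"`,
#' `region_type = "custom"`, `min_len = max_len = length`); each internal
#' node becomes a meta region. Child order is preserved. Labels must be
#' unique.
#'
#' @param s A single rooted newick string.
#' @return The root [region()].
#' @examples
#' parse_newick("((bc:16,umi:12,cdna:90)rna)root;")
#' @export
parse_newick <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  chars <- strsplit(s, "")[[1L]]
  pos <- 1L
  n <- length(chars)
  err <- function(msg, at = pos) {
    stop(sprintf("newick parse error at character %d: %s", at, msg),
         call. = FALSE)
  }
  peek <- function() if (pos <= n) chars[pos] else ""
  read_label <- function() {
    start <- pos
    while (pos <= n && !chars[pos] %in% c("(", ")", ",", ":", ";")) {
      pos <<- pos + 1L
    }
    paste(chars[start:(pos - 1L)][seq_len(pos - start)], collapse = "")
  }
  parse_node <- function() {
    if (peek() == "(") {
      open_at <- pos
      pos <<- pos + 1L
      children <- list(parse_node())
      while (peek() == ",") {
        pos <<- pos + 1L
        children <- c(children, list(parse_node()))
      }
      if (peek() != ")") err("unbalanced parentheses", open_at)
      pos <<- pos + 1L
      label <- read_label()
      if (!nzchar(label)) err("internal node missing label")
      if (peek() == ":") err("internal nodes take a bare label, not a length")
      region(region_id = label, region_type = "custom",
             sequence_type = "joined", regions = children)
    } else {
      label <- read_label()
      if (!nzchar(label)) err("expected a leaf label")
      if (peek() != ":") err(sprintf("leaf '%s' missing ':length'", label))
      pos <<- pos + 1L
      lenstr <- read_label()
      if (!grepl("^[0-9]+$", lenstr)) {
        err(sprintf("leaf '%s' has non-integer length '%s'", label, lenstr))
      }
      len <- as.integer(lenstr)
      region(region_id = label, region_type = "custom",
             sequence_type = "random", min_len = len, max_len = len)
    }
  }
  root <- parse_node()
  if (peek() != ";") err("missing terminating ';'")
  pos <- pos + 1L
  if (pos <= n && any(nzchar(trimws(chars[pos:n])))) {
    err("trailing characters after ';'")
  }
  ids <- vapply(walk_regions(root), function(x) x$region$region_id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(sprintf("newick parse error: duplicate label '%s'", dup[1L]),
         call. = FALSE)
  }
  root
}

#' Initialize an assay from a newick string
#'
#' The root's children become the top-level per-modality regions; their
#' labels become the modality names. Meta metadata is populated with
#' [spec_format()].
#'
#' @param newick A rooted newick string, e.g.
#'   `"((bc:16,umi:12,cdna:90)rna)root;"`.
#' @param assay_id,name Header fields of the new document.
#' @return An [assay()].
#' @export
init_assay <- function(newick, assay_id = "assay", name = assay_id) {
  root <- parse_newick(newick)
  tops <- if (is_meta(root)) root$regions else list(root)
  tops <- lapply(tops, function(r) { r$region_type <- r$region_id; r })
  a <- assay(
    assay_id = assay_id, name = name,
    modalities = vapply(tops, function(r) r$region_id, character(1)),
    library_spec = tops
  )
  spec_format(a)
}
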
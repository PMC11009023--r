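#' @keywords internal
"_PACKAGE"

## Controlled vocabulary for region_type. Values outside this list are legal
## but draw a warning-severity violation from spec_check(), so new assay
## designs stay expressible. Modality-level types (rna, atac, ...) are
## included so top-level regions can carry a recognized type.
REGION_TYPES <- c(
  "barcode", "umi", "cdna", "gdna", "illumina_p5", "illumina_p7",
  "truseq_read1", "truseq_read2", "index5", "index7", "fastq", "linker",
  "poly_A", "named_adapter", "custom",
  "rna", "atac", "protein", "tag", "crispr", "dna"
)

SEQUENCE_TYPES <- c("fixed", "onlist", "random", "joined")

#' Create a library region
#'
#' A region is one node of the library-structure tree. Atomic regions carry
#' sequence; meta regions carry an ordered list of child regions whose
#' concatenation, 5' to 3', is the region's sequence. Constructors perform
#' only type coercion -- semantic invariants (length ordering, fixed-sequence
#' consistency, joined-region bookkeeping) are the job of [spec_check()], so
#' deliberately broken documents can be represented.
#'
#' @param region_id Unique identifier within one assay document.
#' @param region_type Role of the element (e.g. `"barcode"`, `"umi"`,
#'   `"cdna"`, `"linker"`, `"fastq"` for a read container). See
#'   [region_types()] for the recognized vocabulary.
#' @param name Free-text descriptive label.
#' @param sequence_type One of `"fixed"` (literal sequence), `"onlist"`
#'   (drawn from a list of permissible sequences), `"random"`, or `"joined"`
#'   (concatenation of children; meta regions only).
#' @param sequence Nucleotide string over `A,C,G,T,N,X`, or `""`.
#' @param min_len,max_len Length bounds in bases, `0 <= min_len <= max_len`.
#' @param onlist Optional [onlist_ref()] for onlist-type regions.
#' @param regions Ordered list of child regions (order is significant: it is
#'   the 5' to 3' order of the library molecule).
#' @return An object of class `"region"`.
#' @examples
#' bc <- region("barcode-1", "barcode", sequence_type = "onlist",
#'              min_len = 16, max_len = 16,
#'              onlist = onlist_ref("barcodes.txt"))
#' umi <- region("umi-1", "umi", sequence_type = "random",
#'               min_len = 12, max_len = 12)
#' r1 <- region("read1", "fastq", sequence_type = "joined",
#'              regions = list(bc, umi))
#' @export
region <- function(region_id, region_type = "custom", name = region_id,
                   sequence_type = "random", sequence = "",
                   min_len = 0L, max_len = min_len,
                   onlist = NULL, regions = list()) {
  stopifnot(is.character(region_id), length(region_id) == 1L)
  structure(list(
    region_id = as.character(region_id),
    region_type = as.character(region_type),
    name = as.character(name),
    sequence_type = as.character(sequence_type),
    sequence = as.character(sequence),
    min_len = as.integer(min_len),
    max_len = as.integer(max_len),
    onlist = onlist,
    regions = regions
  ), class = "region")
}

#' Reference to an onlist file
#'
#' An onlist is the list of permissible sequences for a region (e.g. a cell
#' barcode whitelist): plain text, one sequence per line, optionally
#' gzip-compressed. Remote onlists can be referenced but are never fetched.
#'
#' @param filename Path (relative paths resolve against the spec file's
#'   directory) or URL.
#' @param location `"local"` or `"remote"`.
#' @param md5 Optional 32-character hex checksum of the file's raw bytes.
#' @return An object of class `"onlist"`.
#' @export
onlist_ref <- function(filename, location = "local", md5 = NULL) {
  stopifnot(is.character(filename), length(filename) == 1L, nzchar(filename))
  structure(list(
    filename = as.character(filename),
    location = as.character(location),
    md5 = if (is.null(md5)) NULL else as.character(md5)
  ), class = "onlist")
}

#' Create an assay document
#'
#' The document root: header metadata plus one top-level region per
#' modality. Each top-level region's `region_id` must equal its modality
#' name (checked by [spec_check()], not here).
#'
#' @param assay_id Short identifier for the assay.
#' @param name Descriptive assay name.
#' @param modalities Ordered character vector of measured modalities
#'   (e.g. `c("rna", "atac")`), duplicate-free.
#' @param library_spec Ordered list of top-level [region()] trees, one per
#'   modality.
#' @param seqspec_version Semantic version of the document format.
#' @param doi,date,description Optional header metadata.
#' @param meta Named list of unknown top-level keys preserved for lossless
#'   round-trip.
#' @return An object of class `"assay"`.
#' @export
assay <- function(assay_id, name = assay_id, modalities, library_spec,
                  seqspec_version = "0.3.0", doi = NULL, date = NULL,
                  description = NULL, meta = list()) {
  structure(list(
    assay_id = as.character(assay_id),
    name = as.character(name),
    doi = if (is.null(doi)) NULL else as.character(doi),
    date = if (is.null(date)) NULL else as.character(date),
    description = if (is.null(description)) NULL else as.character(description),
    modalities = as.character(modalities),
    seqspec_version = as.character(seqspec_version),
    library_spec = library_spec,
    meta = if (length(meta) > 0L) meta else list()
  ), class = "assay")
}

#' Recognized region types
#' @return Character vector of the controlled `region_type` vocabulary.
#' @export
region_types <- function() REGION_TYPES

is_meta <- function(r) length(r$regions) > 0L

#' Atomic descendants of a region, 5' to 3'
#'
#' Returns all childless descendant regions in left-to-right (pre-order)
#' traversal order, which by construction is the 5' to 3' order of the
#' sequenced molecule. A childless input returns itself.
#'
#' @param region A [region()].
#' @return Ordered list of atomic regions.
#' @export
leaves <- function(region) {
  stopifnot(inherits(region, "region"))
  if (!is_meta(region)) return(list(region))
  out <- list()
  for (child in region$regions) out <- c(out, leaves(child))
  out
}

## Pre-order traversal of all nodes (meta and atomic) in one tree,
## returning list of list(region=, path=) with slash-separated id paths.
walk_regions <- function(region, prefix = "") {
  path <- paste0(prefix, "/", region$region_id)
  out <- list(list(region = region, path = path))
  for (child in region$regions) out <- c(out, walk_regions(child, path))
  out
}

## All nodes across the whole document, pre-order within each top-level tree.
walk_assay <- function(assay) {
  out <- list()
  for (r in assay$library_spec) out <- c(out, walk_regions(r))
  out
}

#' Look up a region by identifier
#'
#' Scans every modality tree in pre-order and returns the unique region with
#' the given `region_id`, or `NULL` when absent (absence is a normal empty
#' result, not an error).
#'
#' @param assay An [assay()].
#' @param region_id Identifier to look for.
#' @return A [region()] or `NULL`.
#' @export
find_by_id <- function(assay, region_id) {
  stopifnot(inherits(assay, "assay"))
  for (node in walk_assay(assay)) {
    if (node$region$region_id == region_id) return(node$region)
  }
  NULL
}

## Top-level region for a modality, or error naming the modality.
modality_tree <- function(assay, modality) {
  if (!modality %in% assay$modalities) {
    stop(sprintf("unknown modality '%s' (have: %s)", modality,
                 paste(assay$modalities, collapse = ", ")), call. = FALSE)
  }
  for (r in assay$library_spec) if (r$region_id == modality) return(r)
  stop(sprintf("no top-level region for modality '%s'", modality),
       call. = FALSE)
}

#' Find regions of a given type under one modality
#'
#' Returns every region (meta or atomic) under the modality whose
#' `region_type` matches, in 5' to 3' pre-order; the empty list when none
#' match. An unknown modality is an error.
#'
#' @param assay An [assay()].
#' @param modality One of `assay$modalities`.
#' @param region_type Type to match, e.g. `"barcode"`.
#' @return Ordered list of regions (possibly empty).
#' @export
find_by_type <- function(assay, modality, region_type) {
  tree <- modality_tree(assay, modality)
  nodes <- walk_regions(tree)
  Filter(Negate(is.null), lapply(nodes, function(n) {
    if (n$region$region_type == region_type) n$region else NULL
  }))
}

## Sequence a resolved child contributes to its parent's joined sequence.
## random -> all-X placeholder of max_len; onlist -> stored sequence when
## present, else all-N of max_len; fixed/joined -> stored sequence.
joined_contribution <- function(r) {
  switch(r$sequence_type,
    random = strrep("X", r$max_len),
    onlist = if (nzchar(r$sequence)) r$sequence else strrep("N", r$max_len),
    r$sequence
  )
}

#' Populate meta-region metadata from the leaves
#'
#' Recomputes, bottom-up, every meta region's `sequence_type` (forced to
#' `"joined"`), `sequence` (ordered concatenation of the resolved children,
#' with random children contributing all-`X` placeholders of their maximum
#' length), `min_len` (sum of child minima) and `max_len` (sum of child
#' maxima). Atomic regions are returned untouched, so the operation is
#' idempotent and never changes the number, identifiers, or order of leaves.
#'
#' @param region A [region()] whose atomic descendants are individually
#'   consistent.
#' @return A structurally identical region tree with meta metadata filled in.
#' @export
resolve_joined <- function(region) {
  stopifnot(inherits(region, "region"))
  if (!is_meta(region)) {
    if (identical(region$sequence_type, "joined")) {
      stop(sprintf("region '%s': sequence_type 'joined' requires children",
                   region$region_id), call. = FALSE)
    }
    return(region)
  }
  region$regions <- lapply(region$regions, resolve_joined)
  region$sequence_type <- "joined"
  region$sequence <- paste(
    vapply(region$regions, joined_contribution, character(1)),
    collapse = ""
  )
  region$min_len <- sum(vapply(region$regions, function(r) r$min_len, integer(1)))
  region$max_len <- sum(vapply(region$regions, function(r) r$max_len, integer(1)))
  region
}

#' @export
print.region <- function(x, ...) {
  lab <- if (x$min_len == x$max_len) x$min_len else
    paste0(x$min_len, "-", x$max_len)
  cat(sprintf("<region> %s [%s, %s, %s bp]%s\n", x$region_id, x$region_type,
              x$sequence_type, lab,
              if (is_meta(x)) sprintf(" + %d children", length(x$regions)) else ""))
  invisible(x)
}

#' @export
print.assay <- function(x, ...) {
  cat(sprintf("<assay> %s (%s) v%s\n", x$assay_id, x$name, x$seqspec_version))
  cat(sprintf("  modalities: %s\n", paste(x$modalities, collapse = ", ")))
  for (r in x$library_spec) {
    cat(sprintf("  %s: %d leaves, %d-%d bp\n", r$region_id,
                length(leaves(r)), sum_leaf(r, "min_len"), sum_leaf(r, "max_len")))
  }
  invisible(x)
}

sum_leaf <- function(tree, field) {
  sum(vapply(leaves(tree), function(l) l[[field]], integer(1)))
}
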
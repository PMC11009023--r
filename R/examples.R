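#' Bundled example library specifications
#'
#' Three small, representative specifications ship with the package, each a
#' self-contained workspace (spec plus onlist files) that passes
#' [spec_check()]:
#'
#' * `"tenx-like"` -- fixed geometry, one modality: a 16 bp onlist barcode
#'   and 12 bp UMI in read 1, 90 bp cDNA in read 2 (the layout of
#'   droplet-based 3' scRNA-seq kits).
#' * `"indrops-like"` -- variable geometry: an 8-12 bp first-round barcode
#'   followed by a fixed UMI and second barcode, so downstream offsets are
#'   not constant across molecules.
#' * `"shareseq-like"` -- two modalities (rna, atac) sharing a split-pool
#'   design of three linker-separated 8 bp barcode rounds.
#'
#' @param name Which example.
#' @return `example_spec()`: path to the spec file; `example_assay()`: the
#'   parsed [assay()].
#' @export
example_spec <- function(name = c("tenx-like", "indrops-like",
                                  "shareseq-like")) {
  name <- match.arg(name)
  system.file("extdata", name, "spec.yaml", package = "assayspec",
              mustWork = TRUE)
}

#' @rdname example_spec
#' @export
example_assay <- function(name = c("tenx-like", "indrops-like",
                                   "shareseq-like")) {
  read_spec(example_spec(name))
}
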
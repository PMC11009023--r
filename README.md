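# assayspec

Machine-readable specifications of sequencing-library structure, with an R
toolkit to validate, query, and translate them.

## The problem

Every genomics assay produces library molecules with the same overall shape
— an *adapter–insert–adapter* construct — but wildly different internals:
cell barcodes of fixed or variable length, unique molecular identifiers
(UMIs), linkers, and the biological cDNA/gDNA insert, arranged differently
by every protocol. Preprocessing tools need to know exactly where those
elements sit in each read, and today that knowledge lives in custom scripts
and prose README files. `assayspec` makes it a datum: a YAML document that
annotates the library as an **ordered tree of Regions**, assuming perfect
end-to-end sequencing of a perfectly constructed library.

Each *Region* carries `region_id`, `region_type` (barcode, umi, cdna,
linker, fastq read container, …), a `sequence_type` (`fixed`, `onlist`,
`random`, or `joined`), a concrete or placeholder `sequence`, length bounds
`min_len`/`max_len`, and optionally an *onlist* — the list of permissible
sequences (e.g. a barcode whitelist). *Meta* Regions contain child Regions;
subtree order is significant and equals the 5′→3′ order of the molecule, so
the atomic Regions read left to right are the library layout.

From that single document the toolkit derives everything downstream:

* **validation** (`spec_check`) — schema plus semantic invariants, returning
  a complete, path-ordered violation list (`DUP_ID`, `LEN_ORDER`,
  `FIXED_SEQ_LEN`, `JOIN_MISMATCH`, `ONLIST_MISSING`, `ONLIST_LEN`,
  `MODALITY_MAP`, and the warning-level `UNKNOWN_TYPE`);
* **coordinates** (`spec_index`) — 0-based half-open intervals
  `[start, stop)` for every leaf, on both the all-minimum and all-maximum
  length tracks, with a `fixed` flag that is true only when nothing
  upstream is variable;
* **technology strings** (`emit_geometry`) — the per-tool read-geometry
  encodings of kallisto|bustools, STARsolo, and simpleaf/alevin-fry;
* **onlist resolution** (`onlist_resolve`) — single files, multi-file
  lists, or the materialized Cartesian product for split-pool barcoding;
* **diagrams** (`render_spec`) — ascii read diagrams, markdown, HTML;
* **simulation** (`make_fixture`, `simulate_reads`) — deterministic
  synthetic specs and idealized FASTQ reads for testing extraction logic.

An eleven-subcommand CLI (`check find format index info init modify onlist
print split version`) wraps the same functions; the entry script installs
at `system.file("cli", "assayspec", package = "assayspec")`.

## Worked example

The package bundles three representative specs (a fixed-geometry
droplet-style assay, a variable-length split-barcode assay, and a
two-modality split-pool assay). Starting from the fixed-geometry one:

```r
library(assayspec)
a <- example_assay("tenx-like")
spec_index(a, "rna")
#> <index> modality rna
#>  region_id region_type start_min start_max stop_min stop_max fixed
#>    barcode     barcode         0         0       16       16  TRUE
#>        umi         umi        16        16       28       28  TRUE
#>       cdna        cdna        28        28      118      118  TRUE
```

The 16 bp onlist barcode occupies `[0,16)` of the construct, the 12 bp UMI
`[16,28)`, and the cDNA `[28,118)`; every offset is constant across
molecules (`fixed`), so all three preprocessor dialects can be emitted:

```r
emit_geometry(a, "rna", "kb")$text
#> [1] "0,0,16:0,16,28:1,0,0"
emit_geometry(a, "rna", "starsolo")$text
#> [1] "--soloCBstart 1 --soloCBlen 16 --soloUMIstart 17 --soloUMIlen 12"
emit_geometry(a, "rna", "simpleaf")$text
#> [1] "1{b[16]u[12]}2{r}"
```

Read these as: *kb* — barcode at read 0 positions `[0,16)`, UMI at
`[16,28)`, biological sequence from read 1 position 0 to its end;
*STARsolo* — the same offsets 1-based; *simpleaf* — read 1 is a 16 bp
barcode then a 12 bp UMI, read 2 is all biological sequence. The ascii
diagram shows the layout with its read containers:

```r
cat(render_spec(a, "ascii"))
#> === rna ===
#> [----- read1 -----] [------]
#> +-----------+-------+--------+
#> |barcode(16)|umi(12)|cdna(90)|
#> +-----------+-------+--------+
```

The variable-geometry example (`example_assay("indrops-like")`) carries an
8–12 bp first-round barcode; `spec_index` reports the downstream UMI at
`start_min 8, start_max 12, fixed = FALSE`, and `emit_geometry` refuses all
three dialects with a geometry error — exactly the property that makes
such designs incompatible with fixed-offset preprocessors.

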
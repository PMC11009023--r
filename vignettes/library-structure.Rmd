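---
title: "Annotating sequencing-library structure as an ordered region tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating sequencing-library structure as an ordered region tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assayspec)
```

## The model

A sequencing library molecule is modeled as an **ordered, labeled tree**.
Atomic regions — the leaves — carry sequence: a literal string (`fixed`), a
draw from a list of permissible sequences (`onlist`, e.g. a cell-barcode
whitelist), or arbitrary nucleotides (`random`, e.g. a UMI or the cDNA
insert). Meta regions group children; their sequence type is `joined`, and
their sequence, minimum length, and maximum length are *derived*: the
ordered concatenation and sums over their children. Subtree order is
significant — reading the leaves left to right is reading the molecule
5′→3′ — so pre-order traversal is the single traversal used everywhere and
ties cannot arise.

The derived nature of meta metadata gives the model its one non-obvious
invariant, conservation of length: for any tree, the sum of leaf
minima/maxima equals the resolved root's `min_len`/`max_len`. `spec_format()`
(re)establishes this bottom-up via `resolve_joined()`, and `spec_check()`
flags any document where stored meta metadata disagrees with the
recomputation (`JOIN_MISMATCH`). Because `resolve_joined()` touches only
meta nodes it is idempotent and can never change the number, order, or
identity of leaves.

Placeholder conventions make joined sequences concrete text: a `random`
child contributes all-`X` of its maximum length. For `onlist` children the
format is silent on what text to use, so this package uses the stored
sequence when one is present and an all-`N` placeholder of maximum length
otherwise; the choice only affects the cosmetic joined sequence, never
lengths or coordinates. Zero-length regions (`min_len = max_len = 0`) are
legal and contribute empty intervals, which keeps optional linkers
expressible.

A document (an *assay*) holds header metadata plus one top-level region per
modality (rna, atac, …), matched by `region_id`; identifiers are unique
document-wide, and a duplicate is a hard error rather than something to
disambiguate silently. A meta region may freely mix atomic and meta
children — heterogeneous nesting is exactly how adapter–insert–adapter
constructs are written down.

## Serialization choices

Documents are YAML. On output the package emits one canonical dialect:
plain untagged block mappings, fixed key order, two-space indentation —
deterministic to the byte, so `diff` on specs is meaningful. On input a
second, tagged dialect (nodes prefixed with document tags such as
`!Region`) is also accepted for interoperability and parses to the
identical document; it is never emitted. Unknown top-level keys are
preserved in a `meta` map so a parse→write round trip is lossless; unknown
`region_type` values are accepted with a warning-severity violation so new
assay designs remain expressible without a format release.

Parsing enforces only structural schema (required keys, nesting); all
semantic checking lives in `spec_check()`, which never exits early and
returns every violation ordered by node path. This split means deliberately
broken documents can be represented, which the defect-injection tests rely
on. Only `UNKNOWN_TYPE` is a warning; the CLI exits non-zero exactly when
an error-severity violation exists, and `--skip-files` skips file-system
checks for specs that reference remote onlists (which are represented but
never fetched).

Onlist files are plain text, one sequence per non-empty line, optionally
gzip-compressed, read fully into memory (multi-gigabyte streaming is out of
scope); LF and CRLF are both accepted, an optional md5 is verified against
the raw bytes, and sequence lengths are checked against the *owning
region's* `[min_len, max_len]` interval rather than for equality, so
variable-length barcode lists validate.

The newick grammar for `init` is not standardized anywhere for this
purpose, so the package fixes one: leaves are `id:length` with integer
lengths in bases, internal nodes carry a bare `id` label, labels are
unique, and errors report a character offset. The parser is a small
recursive-descent routine; the test suite cross-checks its topology against
`ape::read.tree` on the documented example.

## Coordinates and the fixed/variable distinction

`spec_index()` walks a modality's leaves 5′→3′, accumulating cumulative
minimum and maximum lengths; each leaf gets 0-based half-open intervals on
both tracks. Consecutive intervals tile the layout exactly (no gaps, no
overlaps), and the final stop equals the modality's total length — both
properties are tested over random trees, and the intervals themselves are
tested against an oracle that *enumerates every concrete length assignment*
within the per-leaf ranges and takes the min/max of realized offsets
(feasible for ≤ 8 leaves with ≤ 3 values per range, which is what the
property tests generate).

An interval is `fixed` only when the leaf *and everything upstream* have
equal bounds. This propagation rule is what downstream tools care about: an
8–12 bp first-round barcode makes every later element's absolute offset
molecule-dependent. Filtering (`subset`) never shifts coordinates — they
are always computed against the full layout.

## Technology strings

Three emitters translate the layout into preprocessor dialects. The tools
address *reads*, not the whole construct, so regions of type `fastq` are
designated read containers, numbered 1..R in 5′→3′ order, and element
offsets restart at 0 inside each read. The emitted grammars are fixed by
this package (the tools' historical grammars vary by version and none is
formally specified):

* **kb**: colon-separated `read,start,stop` triplets, 0-based half-open,
  barcodes first, then UMI, then cDNA with `stop = 0` meaning
  "to end of read";
* **STARsolo**: `--soloCBstart/--soloCBlen/--soloUMIstart/--soloUMIlen`
  with 1-based starts; multiple barcodes are concatenated only when
  adjacent in one read, otherwise the design is rejected;
* **simpleaf**: per-read blocks `N{...}` of `b[len]`, `u[len]`, `r`
  (rest-of-read), `x[len]` (skip).

Preconditions: at least one barcode, exactly one UMI, exactly one
cDNA/gDNA leaf inside the read containers, and fixed barcode/UMI intervals
— variable-length designs are rejected with a geometry error rather than
silently mis-addressed. Cross-dialect consistency (every embedded length
equals the corresponding interval width; STARsolo starts = kb starts + 1)
is asserted on every fixture. Emitters sit behind one dispatch point so
further dialects can be added without touching the indexer.

## The synthetic-data generator

`make_fixture()` builds the canonical construct: fixed P5/P7 Illumina
adapters flanking read containers that hold onlist barcodes, a random UMI,
fixed linkers, and a random biological insert. Defaults model common
practice: barcodes 8–16 bp, UMIs 8–12 bp, inserts 50–100 bp, linkers
4–10 bp, 16 sequences per onlist, 2–8 insert leaves, 1–3 modalities.
Variable-length leaves shrink `min_len` by 1–3 bases below `max_len` with
probability `variable_fraction`. All randomness flows through one seeded
generator whose state is saved and restored, so identical configurations
give byte-identical workspaces and callers' RNG streams are untouched.
With `defect` set, exactly one of the eight violation codes is injected
into an otherwise-valid document (e.g. a renamed leaf for `DUP_ID`, an
over-long appended onlist line for `ONLIST_LEN`).

`simulate_reads()` draws molecules under the format's own idealization —
perfect end-to-end sequencing of a perfectly constructed library — then
adds the minimal noise needed to exercise extraction logic: independent
per-base substitutions at `error_rate`, each to a *different* base, so the
rate is the realized per-base mismatch probability and a 16 bp barcode
mismatches with probability 1 − (1 − e)¹⁶ exactly. Qualities are constant
`I`. What the simulator deliberately does **not** model: indels, PCR
duplicates and chimeras, position- or motif-dependent error profiles,
quality-score distributions, or imperfect library construction. Passing
recovery tests therefore demonstrates that coordinate extraction is
correct, not that any tool is robust to real sequencing artifacts.

Three bundled specs complement the generator as fixed reference points: a
fixed-geometry droplet-style design (16 bp barcode + 12 bp UMI + 90 bp
cDNA), a variable-length split-barcode design, and a two-modality
split-pool design whose three 8 bp barcode rounds are shared between rna
and atac. All three pass `spec_check()` with files resolved; they are
synthetic constructions in the style of the well-known assays, not copies
of any vendor's actual barcode lists.

## Numerical and interface choices

* Coordinates are 0-based half-open everywhere except inside the STARsolo
  emitter, whose dialect demands 1-based starts.
* `spec_modify()` re-runs `spec_format()` after every edit and rejects any
  update that would leave an error-severity violation, naming the code
  (`FIXED_SEQ_LEN`, `DUP_ID`, …). Silent inconsistency after mutation is
  the failure mode this prevents; the cost — meta metadata cannot be
  hand-pinned against the children — is intentional.
* The Cartesian onlist product is row-major in 5′→3′ region order, i.e.
  the first barcode round varies slowest, matching read-concatenation
  order; for `m × n` lists the output has exactly `m·n` lines.
* CLI exit codes: 0 success, 1 validation/processing failure, 2 usage
  error. Machine-parsable output goes to standard output only.
* The ascii renderer uses a box row with proportional-but-bounded widths
  (identifiers truncated beyond 20 characters), wraps banks of boxes to the
  configured width (minimum 40 columns), and draws read-container brackets
  when `fastq` regions exist — the "read diagram" is this annotated
  variant of the ascii format rather than a fourth format.

## Problem sizes used in the checks

The shipped tests and the acceptance script use: 200 random specs for
round-trip identity; 100 random trees (≤ 8 leaves, ≤ 3 length values per
leaf) for the exhaustive interval oracle; 8 defect types × 25 fixtures for
detection completeness; 10,000 simulated molecules for barcode recovery at
error rates 0 and 0.01 (compared against the binomial expectation within
three standard errors); 20 random list-size pairs up to 50 × 50 for the
onlist product. These sizes give the property tests enough variety to
exercise every branch while keeping any single oracle enumeration below a
few thousand combinations.

## Known limitations

Only the first (sequenced) strand is modeled — no reverse-complement view.
Per-base quality modeling, fetching of remote onlists, in-place YAML
editing, and emitting for specific historical versions of the three
preprocessors are out of scope. The violation taxonomy (the eight codes) is
defined by this package, not by any external standard.
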
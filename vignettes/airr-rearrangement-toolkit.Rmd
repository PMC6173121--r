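---
title: "Working with AIRR Rearrangement TSV data in airrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Working with AIRR Rearrangement TSV data in airrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airrkit)
```

## The data model

High-throughput sequencing of antibody and T-cell receptor repertoires
(AIRR-seq) produces *annotated rearrangements*: a recombined V(D)J
receptor chain sequence together with the outputs of a V(D)J
assignment pipeline — gene calls, the junction across the joining
region, per-gene alignments, framework/CDR region coordinates, and
copy-number information.  The community standard for exchanging these
records is a plain, tab-delimited table with a typed schema: one row
per rearrangement, one column per variable, UTF-8, a mandatory header
of unique column names, and no quoting or escaping.  The simplicity is
deliberate.  A newline is always a record boundary, which keeps files
*splittable* (readable in parallel from arbitrary byte offsets), and
any spreadsheet, R, or Python tool can ingest the format directly.

`airrkit` implements this standard end to end: the schema as data, a
strictly typed reader/writer, rule-based validation, the alignment-
encoding algebra (CIGAR, BTOP, coordinate conventions), mapping-driven
conversion of legacy dialects, and a synthetic rearrangement generator
that makes the whole toolchain testable without any external data.

### Schema, typing, and nulls

The column catalogue ships as a YAML document
(`default_schema_file()`) and loads into an `airr_schema` object.
Fields belong to one of seven categories (input, primary annotations,
alignment annotations, alignment positions, region sequences, region
positions, junction lengths) and carry one of nine value kinds.  Kinds
with a mandated name suffix (`_aa`, `_start`, `_end`, `_cigar`,
`_alignment`, `_score`, `_identity`, `_support`) are re-derived and
cross-checked at load time, so a mislabelled catalogue cannot load.

Two typing rules do a lot of work:

* **Null is the empty string.**  Every field — including required
  ones — may be null.  "Required" constrains the *header*, not the
  values.  In R, nulls are `NA` and render back to `""`, so read/write
  round trips are byte-exact.
* **Coordinates are 1-based closed intervals** (the SAM/VCF/GFF/IMGT
  convention).  A coordinate cell must be an integer ≥ 1; the interval
  length is `end - start + 1`.  `interval_to_zero_based()` /
  `zero_based_to_interval()` and `end_from_length()` /
  `length_from_end()` are the bijections to the internal and legacy
  conventions, and a zero-length feature deliberately has *no* closed
  interval (`end_from_length(s, 0)` is null).

The schema is versioned `X.Y.Z` under the standard's semantic-
versioning variant (major: cross-standard changes; minor: schema/API
changes; patch: software/documentation only);
`classify_version_change()` reports the highest-order component at
which two versions differ.  Field names are never repurposed —
corrections happen by adding fields and deprecating old ones — which
is why the catalogue is configuration, not code.

### Reading, writing, and splittable access

`read_rearrangements()` accepts any column order, types declared
columns, carries unknown columns through untyped as custom fields, and
(in lenient mode) reports problems as structured issues instead of
failing.  `write_rearrangements()` always emits canonical order —
declared fields in schema order, then custom fields — with `\n` line
endings and canonical `T`/`F` booleans, so identical input produces
identical bytes.  Writes are atomic (temp file + rename).

Because values may not contain tabs or newlines, a reader dropped at
any byte offset can skip to the next newline and be sure it is at a
record boundary.  `read_from_offset()` implements this for plain text
and for BGZF (blocked gzip), where it first resynchronises at the next
BGZF block boundary.  The set of records returned from offset *b* is
always a suffix of the set returned from any *a < b*, so the records
"owned" by a byte segment `[a, b)` are the difference of two suffix
reads — which makes partitioned reading exactly lossless, a property
the test suite checks against whole-file reads.  Standard gzip cannot
support this (decoding mid-stream needs the full history), so it is
detected by magic bytes and refused with a classed error; bzip2 is
block-structured in principle but its bit-aligned block boundaries are
not implemented here, and it is likewise refused for offset reads
while remaining fully supported for sequential ones.

Multiple files form one logical dataset via `concat_datasets()`: the
record stream is the in-order concatenation, the column set is the
union with null fill.  The standard requires only a "compatible
schema" for this; we read that as *identical required-column sets*,
letting optional and custom columns differ, since requiring identical
optional columns would make datasets fragile against harmless
per-tool extras.  A TSV may carry a companion YAML metadata document
(same basename); it is treated as an opaque, well-formedness-checked
structure because the metadata schema is standardized elsewhere.

## Validation

`validate_record()` / `validate_file()` apply a registry of
identified rules (`validation_rules()`), each with a fixed severity.
Design choices worth stating:

* **Cross-field rules fire only when all participants are non-null.**
  Nullability is universal, so absence is never an error beyond
  header requiredness.
* **Rules are hierarchical.**  A consistency rule whose premise is
  itself broken is skipped: if `v_sequence_start > v_sequence_end`,
  INTERVAL owns the defect and CIGAR_SPAN (whose expected span is
  undefined) stays silent.  One defect, one rule.  This is also what
  makes targeted corruption testing exact.
* **CIGAR spans are compared clip-free.**  Per-gene CIGARs may carry
  `S` (soft-clip) operations for the query outside the aligned
  segment and `N` for skipped germline stretches; the
  `*_start`/`*_end` interval describes the *aligned* region, so the
  CIGAR_SPAN rule excludes `S`/`N` from the consumption count
  (`cigar_spans(ops, clipped = FALSE)`), mirroring how SAM positions
  exclude clips.
* **Context-dependent fields are not over-validated.**  `_score`,
  `_identity`, `_support` definitions legitimately vary between
  annotation tools, so they are checked for numeric parseability
  only; identity additionally warns (not errors) outside both
  `[0, 1]` and `[0, 100]`.  `productive` is validated as a boolean
  only — frame/stop-codon semantics differ between tools.
* Sequence alphabets warn, not error, outside IUPAC nucleotide codes
  (plus `.`/`-` in gapped fields) and the 20 amino acids plus `X`/`*`.

The JUNC_LEN rule checks only internal consistency
(`junction_length == nchar(junction)`), not anchor semantics: whether
a junction includes both conserved anchor codons is a region
*definition*, delegated to germline metadata, not a property a record
can be checked against in isolation.

## Alignment encodings

`parse_cigar()`, `cigar_spans()`, `reconstruct_alignment()`,
`build_cigar_from_gapped()`, and `btop_to_cigar()` form a small
algebra with two deliberate conventions:

* `M`-style CIGAR (match and mismatch merged) is the default emission
  mode for maximal tool compatibility; `=X`-style is available
  everywhere and is the mode in which build/reconstruct are exact
  inverses (in `M` mode the inverse holds up to `=`/`X` collapse).
* `S` and `N` consume sequence without emitting alignment columns, so
  reconstructed rows contain only the aligned region and reported
  intervals cover exactly the column-emitting span.
* `"."` is accepted as a gap synonym on read (an IMGT habit) and
  normalized to `"-"`.

The BTOP tests use an independent oracle: each BTOP string is expanded
column by column into an aligned placeholder pair, the CIGAR is
derived from the pair by naive run-length encoding, and the two routes
must agree.  The package supports `=`/`X` on read regardless of
whether historical schema versions emitted them, and emits `M`-style
by default.

## Legacy conversion

Conversion from Change-O-like and IgBLAST/IMGT-like tabular dialects
is driven by *mapping profiles* — YAML documents, not code, because
field correspondences get revised and corrections should be
configuration-only.  Each mapping is (source column, target field,
transform); transforms cover renaming, boolean normalization,
start+length → closed-interval conversion, 0→1-based shifts, and
BTOP → CIGAR.  Conversion never invents values: unmapped targets are
null, and declared dialect null tokens (`None`, `NA`, …) become null
before any transform.  The exact legacy null-token vocabulary is a
profile option rather than a hard-coded list, since it varies between
tool versions.

Profiles built only from invertible transforms support
`export_legacy()`, which applies every mapping backwards; the bundled
`changeo-like` profile is invertible by construction, and the
conversion round trip (export 1,000 simulated records, convert back,
compare every mapped field) is part of the acceptance suite.  Joining
multi-file IMGT output is out of scope: only a single summary-style
table is supported per invocation.

## The simulator

`simulate_dataset()` exists so that every other module can be tested
against records whose ground truth is known.  Per record it draws V,
(D,) J genes uniformly from a bundled toy germline set, trims the
joining ends, inserts untemplated (np) nucleotides, concatenates,
applies point mutations, and derives *every* schema field from that
construction — junction and its translation, per-gene CIGARs and
coordinates, alignment rows (np insertions masked as `N` on the
germline side), region sequences and positions, junction lengths —
plus a hidden truth ledger (alleles, trims, insertions, mutated
positions) from which conservation laws can be checked exactly.

Parameters and defaults (chosen once as plausible for a repertoire
with moderate somatic hypermutation, and fixed):

| parameter | default | meaning |
|---|---|---|
| `trim_prob` | 0.3 | geometric success probability for trim lengths (mean ≈ 2 nt) |
| `max_trim` | v3/j5: 8, d5/d3: 4 | truncation caps; chosen so the junction anchors and ≥ 1 D nucleotide always survive |
| `np_lambda` | 4, 4 | Poisson means of np1/np2 insertion lengths |
| `mu` | 0.01 | per-base point mutation probability |
| `dup_lambda`, `cons_lambda` | 2, 3 | Poisson parts of duplicate/consensus counts |

Trim lengths are *truncated* geometric (renormalized over `0..max`),
and the tests check goodness of fit against exactly that truncated
distribution — the cap is part of the model, not an afterthought.
The junction convention is explicit data: it spans from the V gene's
conserved-Cys codon through the J gene's conserved-Trp codon
inclusive, with both anchors recorded in the germline sidecar, so the
convention can be changed without touching code.  The toy germline
set uses a `TOY` locus prefix, precisely so its alleles cannot be
mistaken for real ones; a light-chain set without D genes exercises
the nullability paths (`d_*`, `np2_*` all null).

What the simulator does *not* emulate — and therefore what passing
tests do not show about real data: biologically realistic
recombination statistics (no gene-usage bias, no inference-grade trim
models), clonal lineage structure, indel-containing alignments (all
simulated alignments are ungapped, so validator behaviour on `I`/`D`
operations is covered by the algebra tests, not the simulator),
sequencing error beyond point substitution, and real germline
databases.  It is a correctness fixture, not a biological model.

`simulate_dataset(n, seed = s)` runs on a private RNG state (the
caller's stream is untouched) and is byte-deterministic for a given
seed.  Under `mu = 0` productivity reduces exactly to "junction in
frame and stop-free", and with trims, insertions, and mutations all
disabled the record is pure germline concatenation — both degenerate
cases are tested.

## Numerical and edge-case choices

* Numbers render with R's full `as.character()` precision, so
  write→read round trips are value-exact; simulator scores are
  emitted with limited decimals so they are also *byte*-stable.
* Blank lines in a TSV body are ignored; CRLF is tolerated on read;
  output always uses `\n`.
* A row whose cell count disagrees with the header is an error in
  strict mode and a reported-and-skipped issue in lenient mode.
* `rearrangement_reader()` yields fixed-size chunks so validation of
  arbitrarily large files runs in constant memory.
* The acceptance-scale checks use 1,000-record round trips, 100
  corruptions per rule, 10,000 randomized alignments and BTOP
  strings, 50 random partitions of a 10,000-record file, and a
  5,000-record simulation for the statistical self-consistency
  checks (mutation fraction within 3 binomial SE; trim/insertion
  histograms at a χ² significance floor of 0.01).

## Known limitations

* Offset reads for bzip2 are unimplemented (sequential reads work).
* The validator does not resolve allele names against a germline
  database; biological plausibility is out of scope.
* The experimental multi-hit alignment table and repository/API
  layers of the broader standard are out of scope here.
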
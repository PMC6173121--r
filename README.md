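# airrkit

Schema-driven tools for **AIRR Rearrangement TSV** data — the tab-
delimited community standard for annotated immune-receptor (IG/TR)
repertoire sequencing records.

An *annotated rearrangement* is one recombined V(D)J receptor chain
read plus its annotations: gene calls (`v_call`, `d_call`, `j_call`),
the junction across the joining region and its translation, per-gene
alignments encoded as CIGAR strings with 1-based closed
`*_start`/`*_end` intervals, framework/CDR region coordinates, and
copy-number fields.  Every field is nullable (null = empty string);
"required" fields must merely be present in the header.  The format is
deliberately plain — no quoting, no escaping — so that a newline is
always a record boundary and files stay *splittable* for parallel
ingestion.

`airrkit` is for tool builders and analysts who need to produce,
check, or consume such files:

* **Schema as data** — the versioned column catalogue loads from YAML
  (`load_schema()`, `default_schema()`), with suffix-mandated value
  kinds (`_aa`, `_start`/`_end`, `_cigar`, …) enforced at load time.
* **Typed I/O** — `read_rearrangements()` / `write_rearrangements()`
  with strict/lenient modes, canonical column order, custom-column
  passthrough, byte-stable output, and streaming chunked access.
* **Splittable access** — `read_from_offset()` starts reading at any
  byte offset of a plain or BGZF file and recovers record boundaries;
  partitioned reads are exactly lossless.  Standard gzip is detected
  and refused (it is not splittable).
* **Validation** — `validate_file()` applies a registry of identified
  rules (interval ordering, junction-length consistency, CIGAR span
  vs coordinates, region bounds, alignment-row lengths, …) with
  machine-readable issues and severities.
* **Alignment algebra** — CIGAR parsing/building, gapped-alignment
  reconstruction, BLAST BTOP → CIGAR conversion, and the
  1-based-closed ↔ 0-based-half-open and end ↔ length coordinate
  bijections.
* **Legacy conversion** — mapping profiles (YAML, not code) convert
  Change-O-like and IgBLAST-like dialects; invertible profiles also
  export (`export_legacy()`), giving exact round trips.
* **Simulation** — `simulate_dataset()` generates fully consistent,
  validator-clean synthetic rearrangements (toy `TOY*` germline set,
  geometric trims, Poisson np insertions, point mutations) plus a
  truth ledger, and `corrupt_record()` produces minimal single-rule
  violations for sensitivity testing.

A thin CLI wraps it all: `exec/airr-repkit {validate, convert, merge,
simulate, stats}` with stable exit codes (0 ok, 1 validation failure,
2 usage/I-O error).

## Worked example

```r
library(airrkit)

sim <- simulate_dataset(500, seed = 42)
sim$records[1:3, c("sequence_id", "v_call", "j_call",
                   "junction_aa", "productive", "v_cigar")]
#>   sequence_id     v_call     j_call    junction_aa productive v_cigar
#> 1  sim_000001 TOYV1-1*01 TOYJ1-1*01           <NA>      FALSE  74M50S
#> 2  sim_000002 TOYV1-2*01 TOYJ1-3*01           <NA>      FALSE  79M51S
#> 3  sim_000003 TOYV1-4*01 TOYJ1-2*01 CKA*DLSATSLT*W      FALSE  89M49S

f <- file.path(tempdir(), "repertoire.tsv")
write_rearrangements(sim$records, f)
validate_file(f)
#> <airr_validation_report> PASS: 500 record(s), 0 error(s), 0 warning(s)
```

Record 1 is out of frame (`junction_aa` null, unproductive); record 3
is in frame but carries stop codons (`*`), so it is unproductive too.
`74M50S` says the first 74 query bases align to the V gene and the
remaining 50 are outside it (soft-clipped).  Now break one record on
purpose and watch exactly one rule fire:

```r
df <- sim$records
df[7, ] <- corrupt_record(df[7, , drop = FALSE], "CIGAR_SPAN")$record
validate_rearrangements(df)
#> <airr_validation_report> FAIL: 500 record(s), 2 error(s), 0 warning(s)
#>   CIGAR_SPAN       2
```

(Two issues, one rule: the inflated CIGAR disagrees with the interval
on both the query and the germline side.)  The alignment utilities
work standalone:

```r
cigar_string(btop_to_cigar("7AG38"))   # BLAST traceback -> CIGAR
#> [1] "46M"
reconstruct_alignment("ACGGT", "ACT", "2M2I1M")
#> qry [1-5] ACGGT
#> ref [1-3] AC--T
```

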
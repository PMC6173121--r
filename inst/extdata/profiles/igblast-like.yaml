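# IgBLAST-flavoured hit-table dialect: BTOP alignment encoding,
# 0-based start coordinates, Yes/No productivity flags.  Not
# invertible (BTOP discards the residue letters on conversion).
name: igblast-like
version: 1
dialect:
  delimiter: "\t"
  null_tokens: ["", "N/A"]
mappings:
  - {source: query_id, target: sequence_id}
  - {source: query_seq, target: sequence}
  - {source: v_gene, target: v_call}
  - {source: d_gene, target: d_call}
  - {source: j_gene, target: j_call}
  - source: is_productive
    target: productive
    transform: bool_norm
    true_tokens: ["Yes"]
    false_tokens: ["No"]
  - source: v_btop
    target: v_cigar
    transform: btop_to_cigar
  - source: v_start_0based
    target: v_sequence_start
    transform: shift_base
    offset: 1
  - {source: v_end, target: v_sequence_end}
  - {source: cdr3_seq, target: cdr3}
  - {source: internal_notes, transform: drop}
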
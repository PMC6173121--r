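# Change-O-like dialect: uppercase column names, start+length interval
# encoding, T/F booleans.  Every transform here is invertible, so this
# profile supports round-trip export via export_legacy().
name: changeo-like
version: 1
dialect:
  delimiter: "\t"
  null_tokens: ["", "None", "NA"]
mappings:
  - {source: SEQUENCE_ID, target: sequence_id}
  - {source: SEQUENCE_INPUT, target: sequence}
  - {source: LOCUS, target: locus}
  - {source: V_CALL, target: v_call}
  - {source: D_CALL, target: d_call}
  - {source: J_CALL, target: j_call}
  - {source: C_CALL, target: c_call}
  - source: REV_COMP
    target: rev_comp
    transform: bool_norm
  - source: FUNCTIONAL
    target: productive
    transform: bool_norm
  - {source: JUNCTION, target: junction}
  - {source: JUNCTION_AA, target: junction_aa}
  - {source: DUPCOUNT, target: duplicate_count}
  - {source: CONSCOUNT, target: consensus_count}
  - {source: SEQUENCE_IMGT, target: sequence_alignment}
  - {source: GERMLINE_IMGT, target: germline_alignment}
  - {source: V_SEQ_START, target: v_sequence_start}
  - source: V_SEQ_LENGTH
    target: v_sequence_end
    transform: end_from_length
    start_source: V_SEQ_START
  - {source: V_GERM_START, target: v_germline_start}
  - source: V_GERM_LENGTH
    target: v_germline_end
    transform: end_from_length
    start_source: V_GERM_START
  - {source: D_SEQ_START, target: d_sequence_start}
  - source: D_SEQ_LENGTH
    target: d_sequence_end
    transform: end_from_length
    start_source: D_SEQ_START
  - {source: D_GERM_START, target: d_germline_start}
  - source: D_GERM_LENGTH
    target: d_germline_end
    transform: end_from_length
    start_source: D_GERM_START
  - {source: J_SEQ_START, target: j_sequence_start}
  - source: J_SEQ_LENGTH
    target: j_sequence_end
    transform: end_from_length
    start_source: J_SEQ_START
  - {source: J_GERM_START, target: j_germline_start}
  - source: J_GERM_LENGTH
    target: j_germline_end
    transform: end_from_length
    start_source: J_GERM_START
  - {source: JUNCTION_LENGTH, target: junction_length}
  - {source: NP1_LENGTH, target: np1_length}
  - {source: NP2_LENGTH, target: np2_length}
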
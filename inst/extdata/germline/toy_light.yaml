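# Synthetic light-chain germline annotations for the TOYL locus (no D
# segment; exercises the nullability paths of d_* and np2_* fields).
locus: TOYL
genes:
  "TOYLV1-1*01":
    segment: V
    junction_start: 61
    regions:
      fwr1: [1, 18]
      cdr1: [19, 30]
      fwr2: [31, 42]
      cdr2: [43, 48]
      fwr3: [49, 60]
  "TOYLV1-2*01":
    segment: V
    junction_start: 67
    regions:
      fwr1: [1, 18]
      cdr1: [19, 30]
      fwr2: [31, 45]
      cdr2: [46, 54]
      fwr3: [55, 66]
  "TOYLJ1-1*01":
    segment: J
    junction_end: 12
  "TOYLJ1-2*01":
    segment: J
    junction_end: 15
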
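# Synthetic heavy-chain germline annotations for the TOYH locus.
# junction_start: 1-based, codon-aligned offset of the conserved Cys
# codon in each V gene; junction_end: last base of the conserved Trp
# codon in each J gene.  V region intervals tile [1, junction_start-1].
locus: TOYH
genes:
  "TOYV1-1*01":
    segment: V
    junction_start: 64
    regions:
      fwr1: [1, 18]
      cdr1: [19, 30]
      fwr2: [31, 42]
      cdr2: [43, 51]
      fwr3: [52, 63]
  "TOYV1-2*01":
    segment: V
    junction_start: 67
    regions:
      fwr1: [1, 18]
      cdr1: [19, 30]
      fwr2: [31, 45]
      cdr2: [46, 54]
      fwr3: [55, 66]
  "TOYV1-3*01":
    segment: V
    junction_start: 70
    regions:
      fwr1: [1, 21]
      cdr1: [22, 33]
      fwr2: [34, 45]
      cdr2: [46, 57]
      fwr3: [58, 69]
  "TOYV1-4*01":
    segment: V
    junction_start: 76
    regions:
      fwr1: [1, 24]
      cdr1: [25, 36]
      fwr2: [37, 48]
      cdr2: [49, 60]
      fwr3: [61, 75]
  "TOYD1-1*01":
    segment: D
  "TOYD1-2*01":
    segment: D
  "TOYD1-3*01":
    segment: D
  "TOYJ1-1*01":
    segment: J
    junction_end: 12
  "TOYJ1-2*01":
    segment: J
    junction_end: 15
  "TOYJ1-3*01":
    segment: J
    junction_end: 12
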
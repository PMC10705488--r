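# Integrated-construct specifications: lengths in bp (promoters and
# terminators included in component lengths), copies per genome, and the
# retained end-point clone counts per strain.
D:
  name: D
  length_bp: 7999
  components:
    gRNA: 388
    Cas9: 4890
  copies: 2
  n_clones: 67
C:
  name: C
  length_bp: 7601
  components:
    Cas9: 4890
  copies: 2
  n_clones: 83
W:
  name: W
  length_bp: 2770
  copies: 2
  n_clones: 79
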
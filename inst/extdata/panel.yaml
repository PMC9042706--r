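candidate_genes: [BTLA, SOX11, BCL2]
housekeeping_candidates: [ACTB, GAPDH]
refined_markers:
  CLL/SLL: [BTLA]
  cMCL: [SOX11]
  FL: [BCL2]
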
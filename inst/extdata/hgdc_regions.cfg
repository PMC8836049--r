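motif2_beta3 = 61-64 : motif 2 beta3-strand (G61~A64)
motif1_beta3 = 33-38 : motif 1 beta3-strand (C33~V38)
motif2_beta2 = 55-58 : motif 2 beta2-strand (Q55~L58)
motif3_loop = 109-118 : motif 3 loop (C109~F118)
denovo_strand = 116-119 : de novo strand-forming region (F116~N119)
aggregation_stretch = 54-58 : aggregation-prone stretch (L54~L58)
motif4_b2b3 = 138-162 : motif 4 beta2/beta3 strands (N138~A162)
N_td = 2-83 : N-terminal domain
C_td = 88-174 : C-terminal domain
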
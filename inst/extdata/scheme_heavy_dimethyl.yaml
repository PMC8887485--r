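# Heavy-isotopic reductive dimethylation (13CD2O + NaBD3CN) of lysines on
# the intact protein, then trypsin digestion (Arg-C-like, lysines blocked)
# and N-terminal propionylation of the peptides. Deltas are net monoisotopic
# additions in Da.
heavy_methyl_delta: 18.03783515   # 13CD3 replacing one amine H
light_methyl_delta: 14.01565006   # endogenous CH2
acetyl_delta: 42.01056468         # C2H2O
propionyl_delta: 56.02621474      # C3H4O
installed:                        # heavy methyls installed per endogenous state
  un: 2
  me1: 1
  me2: 0
  me3: 0
  ac: 0
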
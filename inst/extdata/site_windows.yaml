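# Default consensus membrane-binding site windows, 1-based inclusive alignment
# columns. These are a reconstruction of the three docking elements of the PX
# superfamily alignment (beta1-beta2 membrane-insertion loop; beta3 strand into
# alpha1 with the RRY motif; PRE-containing loop into alpha2). The exact column
# bounds the original analysis used were never published, so recomputed stop
# scores are validated on synthetic alignments, not against curated tables.
sites:
  site1: [30, 48]
  site2: [62, 80]
  site3: [95, 120]
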
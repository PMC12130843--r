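# SYNTHETIC illustrative sigma anchor table (NOT optimized force-field
# values). Anchors sit on the 0.05 grid of scaling factors; sigma shrinks
# as the charge is scaled down so the first solvation-shell radius stays
# at its unscaled-force-field value. Epsilon is constant per ion and is
# never interpolated.
ion,q_anchor,sigma,epsilon
K,1.00,0.31426,0.36401
K,0.95,0.30950,0.36401
K,0.90,0.30430,0.36401
K,0.85,0.29860,0.36401
K,0.80,0.29230,0.36401
K,0.75,0.28530,0.36401
K,0.70,0.27750,0.36401
K,0.65,0.26880,0.36401
NA,1.00,0.24300,0.19623
NA,0.95,0.23890,0.19623
NA,0.90,0.23440,0.19623
NA,0.85,0.22950,0.19623
NA,0.80,0.22410,0.19623
NA,0.75,0.21810,0.19623
NA,0.70,0.21140,0.19623
NA,0.65,0.20390,0.19623
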
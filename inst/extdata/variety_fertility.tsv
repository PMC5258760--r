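# Reference spikelet fertility means (percent; mean of 10 plants per group)
# for the heat-sensitive recurrent parent (HJX), the heat-tolerant donor
# (GXN) and the tolerant check landrace (N22) after flowering-stage heat
# stress, used to compute the heat tolerance index HI = heat SFP / control SFP.
variety	control_sfp	heat_sfp
HJX	76.6	15.3
GXN	66.4	55.8
N22	68.7	58.67
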
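# Example helix definition table for the ERa ligand-binding domain
# (approximate canonical ranges; adjust to your numbering before use).
segment_name	chain_id	start	end
H3	A	342	363
H4	A	368	380
H5	A	381	392
H6	A	402	411
H7	A	420	430
H8	A	438	453
H9	A	470	485
H10	A	487	496
H11	A	497	528
H12	A	536	544
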
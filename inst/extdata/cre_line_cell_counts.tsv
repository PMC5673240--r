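mouse_line	n_cells_scrnaseq	n_cells_ephys
Ctgf	13	12
Cux2	122	55
Gad2	69	11
Htr3a	123	81
Nr5a1	48	62
Ntsr1	90	37
Pvalb	88	141
Rbp4	173	61
Rorb	51	106
Scnn1a.Tg2	19	28
Scnn1a.Tg3	99	52
Sst	105	107
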
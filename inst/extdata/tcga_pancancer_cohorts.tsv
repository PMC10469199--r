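cancer_type	n_patients
ACC	92
BLCA	411
BRCA	1084
CESC	297
CHOL	36
CRC	594
DLBC	48
ESCA	182
GBM	585
HNSC	523
KICH	65
KIRC	512
KIRP	283
LAML	165
LGG	514
LIHC	372
LUAD	566
LUSC	487
MESO	87
OV	585
PAAD	184
PCPG	178
PRAD	494
SARC	255
SKCM	442
STAD	440
TGCT	149
THCA	499
THYM	123
UCEC	529
UCS	57
UVM	80
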
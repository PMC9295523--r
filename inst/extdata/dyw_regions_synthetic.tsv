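# SYNTHETIC alignment blocks for the three conserved regions of the DYW
# deaminase domain (PG box, active site, C-terminal), used to build the
# packaged region PWMs and by the synthetic cohort generator. These are
# constructed stand-ins, not curated biological alignments: each block embeds
# the field's hallmark residues (the PG dipeptide in the PG box, the
# H..E / C..C cytidine-deaminase signature in the active site, the terminal
# D-Y-W tripeptide) at the region widths 24 / 32 / 25 with light variation.
region	seq_id	sequence
PG_box	pg1	AEWVEVKNKVHTFSAGDQSHPGAE
PG_box	pg2	AEWVEVKNRVHTFSAGDQSHPGAE
PG_box	pg3	AEWIEVKNKVHTFSAGDQSHPGAE
PG_box	pg4	AEWVEVKNKVHEFSAGDQSHPGAE
PG_box	pg5	SEWVEVKNKVHTFSAGDKSHPGAE
PG_box	pg6	AEWVEVRNKVHTFSVGDQSHPGAE
PG_box	pg7	AEWVEVKNKVHTFSAGDQSHPGAD
PG_box	pg8	AEWVELKNKVHTFSAGDQSHPGSE
active_site	as1	DVYHAEKLAIAFALINTAPGTPIRIVKNCRSC
active_site	as2	DVYHAEKLAIAFGLINTAPGTPIRIVKNCRSC
active_site	as3	DIYHAEKLAIAFALINTAPGTPIRIVKNCRSC
active_site	as4	DVYHSEKLAIAFALINTAPGTPIRIVKNCRSC
active_site	as5	DVYHAEKLALAFALINTAPGTPLRIVKNCRSC
active_site	as6	DVYHAEKMAIAFALINTAEGTPIRIVKNCRSC
active_site	as7	DVYHAERLAIAFALINTAPGSPIRIVKNCRSC
active_site	as8	DVYHAEKLAIAFALVNTAPGTPIRIMKNCRSC
C_terminal	ct1	GYVPDTSRLEALRGHSERLAIADYW
C_terminal	ct2	GYVPDTSRLEALKGHSERLAIADYW
C_terminal	ct3	GYVPDTARLEALRGHSERLAIADYW
C_terminal	ct4	GYVPDTSRLESLRGHSERLAIADYW
C_terminal	ct5	GYLPDTSRLEALRGHSERLAVADYW
C_terminal	ct6	GYVPDSSRLEALRGHTERLAIADYW
C_terminal	ct7	GYVPDTSRMEALRGHSERLAIADYW
C_terminal	ct8	GYVPDTSRLEALRGHSEKLAIADYW
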
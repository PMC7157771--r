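id	role	family	superfamily	subgroup	notes	hmm_profile
tnpA_Tn3	transposase	NA	NA	Tn3	synthetic exemplar	NA
tnpA_Tn21	transposase	NA	NA	Tn21	synthetic exemplar	NA
tnpA_Tn163	transposase	NA	NA	Tn163	synthetic exemplar	NA
tnpA_IS1071	transposase	NA	NA	IS1071	synthetic exemplar	NA
tnpA_IS3000	transposase	NA	NA	IS3000	synthetic exemplar	NA
tnpA_Tn4430	transposase	NA	NA	Tn4430	synthetic exemplar	NA
tnpA_Tn4651	transposase	NA	NA	Tn4651	synthetic exemplar	NA
tnpA_Tn3000	transposase	NA	NA	Tn3000	synthetic exemplar	NA
tnpR_1	resolvase_S	NA	NA	NA	synthetic exemplar	NA
tnpR_2	resolvase_S	NA	NA	NA	synthetic exemplar	NA
tnpI_1	resolvase_Y	NA	NA	NA	synthetic exemplar	NA
tnpS_1	resolvase_Y_het	NA	NA	NA	synthetic exemplar	NA
tnpT_1	helper	NA	NA	NA	synthetic exemplar	NA
ParE_1	toxin	ParE	RelE/ParE	NA	synthetic exemplar	NA
ParE_2	toxin	ParE	RelE/ParE	NA	synthetic exemplar	NA
Gp49_1	toxin	Gp49	RelE/ParE	NA	synthetic exemplar	NA
PIN_3_1	toxin	PIN_3	PIN	NA	synthetic exemplar	NA
PIN_1	toxin	PIN	PIN	NA	synthetic exemplar	NA
HEPN_1	toxin	HEPN	HEPN	NA	synthetic exemplar	NA
ParD_1	antitoxin	ParD	RelB/ParD	NA	synthetic exemplar	NA
ParD_2	antitoxin	ParD	RelB/ParD	NA	synthetic exemplar	NA
RHH_6_1	antitoxin	RHH_6	VapB	NA	synthetic exemplar	NA
HTH_37_1	antitoxin	HTH_37	HigA	NA	synthetic exemplar	NA
PhdYeFM_1	antitoxin	Phd/YeFM	Phd/YeFM	NA	synthetic exemplar	NA
AbrB_1	antitoxin	AbrB	AbrB/MazE	NA	synthetic exemplar	NA
MNT_1	antitoxin	Mnt	Mnt	NA	synthetic exemplar	NA
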
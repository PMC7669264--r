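region	study	x	y	z	set	note
FFG	synth_meta_A	-44	-58	-16	alphabetic_dyslexia	
FFG	synth_meta_B	-46	-54	-12	alphabetic_dyslexia	
FFG	synth_meta_C	-42	-60	-18	alphabetic_dyslexia	
FFG	synth_meta_D	-48	-56	-14	alphabetic_dyslexia	
IOG	synth_meta_A	-42	-78	-10	alphabetic_dyslexia	
IOG	synth_meta_B	-44	-74	-14	alphabetic_dyslexia	
IOG	synth_meta_C	-40	-80	-8	alphabetic_dyslexia	
MTG	synth_meta_A	-52	-40	2	alphabetic_dyslexia	
MTG	synth_meta_B	-50	-44	4	alphabetic_dyslexia	
MTG	synth_meta_D	-54	-42	0	alphabetic_dyslexia	
STS	synth_meta_A	-56	-28	2	alphabetic_dyslexia	
STS	synth_meta_B	-58	-32	4	alphabetic_dyslexia	
STS	synth_meta_C	-57	-30	0	alphabetic_dyslexia	
pSTG	synth_meta_A	-52	-40	12	alphabetic_dyslexia	
pSTG	synth_meta_C	-56	-44	14	alphabetic_dyslexia	
pSTG	synth_meta_D	-54	-42	16	alphabetic_dyslexia	
SMG	synth_meta_B	-50	-38	28	alphabetic_dyslexia	
SMG	synth_meta_D	-54	-42	32	alphabetic_dyslexia	
SPL	synth_meta_A	-28	-58	48	alphabetic_dyslexia	
SPL	synth_meta_C	-32	-62	52	alphabetic_dyslexia	
PCG	synth_meta_A	-48	2	34	alphabetic_dyslexia	
PCG	synth_meta_B	-52	6	30	alphabetic_dyslexia	
PCG	synth_meta_D	-50	4	38	alphabetic_dyslexia	
IFG	synth_meta_B	-46	14	18	alphabetic_dyslexia	
IFG	synth_meta_C	-50	18	22	alphabetic_dyslexia	
R_pSTG	synth_meta_A	56	-30	4	alphabetic_dyslexia	
R_pSTG	synth_meta_C	58	-34	2	alphabetic_dyslexia	
MFG	synth_meta_E	-44	16	26	chinese_reading	
MFG	synth_meta_F	-48	22	28	chinese_reading	
MFG	synth_meta_G	-46	20	24	chinese_reading	
MFG	synth_meta_H	-42	18	30	chinese_reading	
R_IOG	synth_meta_E	40	-80	-8	chinese_reading	
R_IOG	synth_meta_F	44	-76	-12	chinese_reading	
R_FFG	synth_meta_F	44	-54	-16	chinese_reading	could equally be assigned to a ventral occipito-temporal label
R_FFG	synth_meta_G	46	-58	-14	chinese_reading	
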
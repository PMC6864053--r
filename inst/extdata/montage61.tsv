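label	x	y
Fp1	-2.556	4
Fpz	0	4
Fp2	2.556	4
AF7	-3.267	3
AF3	-1.634	3
AFz	0	3
AF4	1.634	3
AF8	3.267	3
F7	-3.692	2
F5	-2.769	2
F3	-1.846	2
F1	-0.923	2
Fz	0	2
F2	0.923	2
F4	1.846	2
F6	2.769	2
F8	3.692	2
FT7	-3.925	1
FC5	-2.944	1
FC3	-1.963	1
FC1	-0.981	1
FCz	0	1
FC2	0.981	1
FC4	1.963	1
FC6	2.944	1
FT8	3.925	1
T7	-4	0
C5	-3	0
C3	-2	0
C1	-1	0
Cz	0	0
C2	1	0
C4	2	0
C6	3	0
T8	4	0
TP7	-3.925	-1
CP5	-2.944	-1
CP3	-1.963	-1
CP1	-0.981	-1
CPz	0	-1
CP2	0.981	-1
CP4	1.963	-1
CP6	2.944	-1
TP8	3.925	-1
P7	-3.692	-2
P5	-2.769	-2
P3	-1.846	-2
P1	-0.923	-2
Pz	0	-2
P2	0.923	-2
P4	1.846	-2
P6	2.769	-2
P8	3.692	-2
PO7	-3.267	-3
PO3	-1.634	-3
POz	0	-3
PO4	1.634	-3
PO8	3.267	-3
O1	-2.556	-4
Oz	0	-4
O2	2.556	-4
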
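channel	x	y	z
Fp1	-0.024981	0.076883	0.026266
Fp2	0.024981	0.076883	0.026266
AF7	-0.047516	0.065401	0.026266
AF3	-0.025015	0.070632	0.04013
AF4	0.025015	0.070632	0.04013
AF8	0.047516	0.065401	0.026266
F7	-0.065401	0.047516	0.026266
F5	-0.052592	0.052679	0.041036
F3	-0.036807	0.05486	0.053484
F1	-0.01894	0.053937	0.062905
Fz	0	0.049962	0.068766
F2	0.01894	0.053937	0.062905
F4	0.036807	0.05486	0.053484
F6	0.052592	0.052679	0.041036
F8	0.065401	0.047516	0.026266
FT9	-0.08084	0.026266	0
FT7	-0.076883	0.024981	0.026266
FC5	-0.0643	0.029138	0.047345
FC3	-0.046199	0.030795	0.064361
FC1	-0.024135	0.029809	0.075854
FC2	0.024135	0.029809	0.075854
FC4	0.046199	0.030795	0.064361
FC6	0.0643	0.029138	0.047345
FT8	0.076883	0.024981	0.026266
FT10	0.08084	0.026266	0
T7	-0.08084	0	0.026266
C5	-0.068766	0	0.049962
C3	-0.049962	0	0.068766
C1	-0.026266	0	0.08084
Cz	0	0	0.085
C2	0.026266	0	0.08084
C4	0.049962	0	0.068766
C6	0.068766	0	0.049962
T8	0.08084	0	0.026266
TP9	-0.08084	-0.026266	0
TP7	-0.076883	-0.024981	0.026266
CP5	-0.0643	-0.029138	0.047345
CP3	-0.046199	-0.030795	0.064361
CP1	-0.024135	-0.029809	0.075854
CPz	0	-0.026266	0.08084
CP2	0.024135	-0.029809	0.075854
CP4	0.046199	-0.030795	0.064361
CP6	0.0643	-0.029138	0.047345
TP8	0.076883	-0.024981	0.026266
TP10	0.08084	-0.026266	0
P7	-0.065401	-0.047516	0.026266
P5	-0.052592	-0.052679	0.041036
P3	-0.036807	-0.05486	0.053484
P1	-0.01894	-0.053937	0.062905
Pz	0	-0.049962	0.068766
P2	0.01894	-0.053937	0.062905
P4	0.036807	-0.05486	0.053484
P6	0.052592	-0.052679	0.041036
P8	0.065401	-0.047516	0.026266
PO9	-0.049962	-0.068766	0
PO7	-0.047516	-0.065401	0.026266
PO3	-0.025015	-0.070632	0.04013
POz	0	-0.068766	0.049962
PO4	0.025015	-0.070632	0.04013
PO8	0.047516	-0.065401	0.026266
PO10	0.049962	-0.068766	0
O1	-0.024981	-0.076883	0.026266
Oz	0	-0.08084	0.026266
O2	0.024981	-0.076883	0.026266
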
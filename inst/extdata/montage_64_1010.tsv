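label	x_cm	y_cm	z_cm
Fpz	8.5595	0	2.7812
Fp2	8.1406	-2.645	2.7812
Fp1	8.1406	2.645	2.7812
AF4	7.4787	-2.6486	4.2491
AF3	7.4787	2.6486	4.2491
AFz	7.2812	0	5.2901
AF8	6.9248	-5.0312	2.7812
AF7	6.9248	5.0312	2.7812
F4	5.8087	-3.8972	5.663
F3	5.8087	3.8972	5.663
F2	5.711	-2.0054	6.6606
F1	5.711	2.0054	6.6606
F6	5.5778	-5.5686	4.345
F5	5.5778	5.5686	4.345
Fz	5.2901	0	7.2812
F8	5.0312	-6.9248	2.7812
F7	5.0312	6.9248	2.7812
FC4	3.2606	-4.8917	6.8147
FC3	3.2606	4.8917	6.8147
FC2	3.1563	-2.5555	8.0316
FC1	3.1563	2.5555	8.0316
FC6	3.0852	-6.8082	5.013
FC5	3.0852	6.8082	5.013
FT10	2.7812	-8.5595	0
FCz	2.7812	0	8.5595
FT9	2.7812	8.5595	0
FT8	2.645	-8.1406	2.7812
FT7	2.645	8.1406	2.7812
T8	0	-8.5595	2.7812
C6	0	-7.2812	5.2901
C4	0	-5.2901	7.2812
C2	0	-2.7812	8.5595
Cz	0	0	9
C1	0	2.7812	8.5595
C3	0	5.2901	7.2812
C5	0	7.2812	5.2901
T7	0	8.5595	2.7812
TP8	-2.645	-8.1406	2.7812
TP7	-2.645	8.1406	2.7812
CPz	-2.7812	0	8.5595
CP6	-3.0852	-6.8082	5.013
CP5	-3.0852	6.8082	5.013
CP2	-3.1563	-2.5555	8.0316
CP1	-3.1563	2.5555	8.0316
CP4	-3.2606	-4.8917	6.8147
CP3	-3.2606	4.8917	6.8147
P8	-5.0312	-6.9248	2.7812
P7	-5.0312	6.9248	2.7812
Pz	-5.2901	0	7.2812
P6	-5.5778	-5.5686	4.345
P5	-5.5778	5.5686	4.345
P2	-5.711	-2.0054	6.6606
P1	-5.711	2.0054	6.6606
P4	-5.8087	-3.8972	5.663
P3	-5.8087	3.8972	5.663
PO8	-6.9248	-5.0312	2.7812
PO7	-6.9248	5.0312	2.7812
POz	-7.2812	0	5.2901
PO4	-7.4787	-2.6486	4.2491
PO3	-7.4787	2.6486	4.2491
O2	-8.1406	-2.645	2.7812
O1	-8.1406	2.645	2.7812
Oz	-8.5595	0	2.7812
Iz	-9	0	0
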
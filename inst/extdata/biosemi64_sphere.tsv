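label	x	y	z
Fp1	-0.30882875	0.950477158	-0.0348994967
AF7	-0.587427189	0.808524163	-0.0348994967
AF3	-0.406246747	0.87119896	0.275637356
F1	-0.286965299	0.71026404	0.64278761
F3	-0.545007446	0.673028145	0.5
F5	-0.728993475	0.63370436	0.258819045
F7	-0.808524163	0.587427189	-0.0348994967
FT7	-0.950477158	0.30882875	-0.0348994967
FC5	-0.887887748	0.340828174	0.309016994
FC3	-0.676377097	0.359636082	0.64278761
FC1	-0.374709505	0.374709505	0.848048096
C1	-0.390731128	-0	0.920504853
C3	-0.7193398	-0	0.69465837
C5	-0.933580426	-0	0.35836795
T7	-0.999390827	-0	-0.0348994967
TP7	-0.950477158	-0.30882875	-0.0348994967
CP5	-0.887887748	-0.340828174	0.309016994
CP3	-0.676377097	-0.359636082	0.64278761
CP1	-0.374709505	-0.374709505	0.848048096
P1	-0.286965299	-0.71026404	0.64278761
P3	-0.545007446	-0.673028145	0.5
P5	-0.728993475	-0.63370436	0.258819045
P7	-0.808524163	-0.587427189	-0.0348994967
P9	-0.733218402	-0.532714351	-0.422618262
PO7	-0.587427189	-0.808524163	-0.0348994967
PO3	-0.406246747	-0.87119896	0.275637356
O1	-0.30882875	-0.950477158	-0.0348994967
Iz	5.54953465e-17	-0.906307787	-0.422618262
Oz	6.11950389e-17	-0.999390827	-0.0348994967
POz	5.71653141e-17	-0.933580426	0.35836795
Pz	4.40468592e-17	-0.7193398	0.69465837
CPz	2.39253813e-17	-0.390731128	0.920504853
Fpz	6.11950389e-17	0.999390827	-0.0348994967
Fp2	0.30882875	0.950477158	-0.0348994967
AF8	0.587427189	0.808524163	-0.0348994967
AF4	0.406246747	0.87119896	0.275637356
AFz	5.71653141e-17	0.933580426	0.35836795
Fz	4.40468592e-17	0.7193398	0.69465837
F2	0.286965299	0.71026404	0.64278761
F4	0.545007446	0.673028145	0.5
F6	0.728993475	0.63370436	0.258819045
F8	0.808524163	0.587427189	-0.0348994967
FT8	0.950477158	0.30882875	-0.0348994967
FC6	0.887887748	0.340828174	0.309016994
FC4	0.676377097	0.359636082	0.64278761
FC2	0.374709505	0.374709505	0.848048096
FCz	2.39253813e-17	0.390731128	0.920504853
Cz	0	0	1
C2	0.390731128	0	0.920504853
C4	0.7193398	0	0.69465837
C6	0.933580426	0	0.35836795
T8	0.999390827	0	-0.0348994967
TP8	0.950477158	-0.30882875	-0.0348994967
CP6	0.887887748	-0.340828174	0.309016994
CP4	0.676377097	-0.359636082	0.64278761
CP2	0.374709505	-0.374709505	0.848048096
P2	0.286965299	-0.71026404	0.64278761
P4	0.545007446	-0.673028145	0.5
P6	0.728993475	-0.63370436	0.258819045
P8	0.808524163	-0.587427189	-0.0348994967
P10	0.733218402	-0.532714351	-0.422618262
PO8	0.587427189	-0.808524163	-0.0348994967
PO4	0.406246747	-0.87119896	0.275637356
O2	0.30882875	-0.950477158	-0.0348994967
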
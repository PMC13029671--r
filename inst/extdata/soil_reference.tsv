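variable	group	mean	se
pH	KC	8.81	0.04
pH	NT	8.47	0.05
pH	RS	8.29	0.06
SWC	KC	27.76	1.08
SWC	NT	21.92	0.86
SWC	RS	19.76	0.2
Na	KC	5728.9	451.97
Na	NT	1384.43	122.46
Na	RS	580.15	35.26
K	KC	58.16	4.47
K	NT	34.49	1.85
K	RS	28.28	1.9
TC	KC	6.91	0.6
TC	NT	10.77	0.77
TC	RS	13.34	0.27
TOC	KC	2.93	0.21
TOC	NT	5.49	0.44
TOC	RS	6.37	0.62
TN	KC	0.25	0.01
TN	NT	0.49	0.1
TN	RS	0.35	0.03
TP	KC	0.34	0.02
TP	NT	0.37	0.03
TP	RS	0.29	0.02
AN	KC	6.1	0.3
AN	NT	9.26	0.42
AN	RS	11.52	0.58
OP	KC	0.91	0.03
OP	NT	0.6	0.05
OP	RS	0.54	0.03
MBC	KC	38.92	1.69
MBC	NT	45.72	0.76
MBC	RS	51.16	2.23
MBN	KC	2.56	0.08
MBN	NT	2.74	0.06
MBN	RS	3.22	0.24
MBP	KC	0.72	0.02
MBP	NT	0.87	0.02
MBP	RS	0.91	0.03
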
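symbol	direction	recurrence
SMOC1	up	12
CHI3L1	up	9
PKM	down	8
ALDOA	down	7
NPTX2	down	10
VGF	down	9
YWHAZ	up	6
GAPDH	down	6
ENO1	down	5
GFAP	up	11
NPTXR	down	4
SOD1	up	3
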
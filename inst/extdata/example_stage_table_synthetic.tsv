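symbol	first_change_years	direction
SMOC1	-29	up
SPON1	-27	up
YWHAZ	-25	up
ALDOA	-18	up
ENO1	-15	up
LDHB	-14	up
PGAM1	-12	up
PKM	-10	up
YWHAB	-9	up
YWHAG	-7	up
NPTX2	-3	down
NPTXR	0	down
VGF	2	down
ENO2	-4	up
GAPDH	1	up
MDH1	4	up
ITGB2	8	up
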
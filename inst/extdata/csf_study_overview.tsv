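study_id	author	doi	year	sub_cohort	platform	ms_flavor	n_case	n_control	n_measured	n_significant	fc_included
spellman2015	Spellman et al.	10.1002/prca.201400178	2015		MS	MRM	66	85	142	0	yes
dayon2018	Dayon et al.	10.1186/s13195-018-0397-4	2018		MS	TMT	72	48	790	22	no
sathe2019	Sathe et al.	10.1002/prca.201800105	2019		MS	TMT	5	5	2327	139	yes
bader2020_swe	Bader et al.	10.15252/msb.20199356	2020	Sweden	MS	DIA	29	31	1484	540	yes
bader2020_mk	Bader et al.	10.15252/msb.20199356	2020	Magdeburg-Kiel	MS	DIA	26	12	1484	453	yes
higginbotham2020	Higginbotham et al.	10.1126/sciadv.aaz9360	2020		MS	TMT	20	20	2875	528	yes
bai2020	Bai et al.	10.1016/j.neuron.2019.12.015	2020		MS	TMT	8	5	5940	9	yes
johnson2020	Johnson et al.	10.1038/s41591-020-0815-6	2020		MS	TMT	147	150	532	59	yes
park2020	Park et al.	10.1038/s41598-020-64461-y	2020		MS	SWATH	42	39	274	21	yes
degeus2023	De Geus et al.	10.1038/s41598-023-49440-3	2023		MS	DIA	72	68	636	101	yes
haque2023	Haque et al.	10.1126/scitranslmed.adg4122	2023		MS	SRM	110	376	48	22	yes
liu2023	Liu et al.	10.3390/ijms241814225	2023		MS	DDA	12	10	1308	68	no
modeste2023_cau	Modeste et al.	10.1186/s13024-023-00638-z	2023	Caucasian	MS	TMT	53	47	1840	257	yes
modeste2023_aa	Modeste et al.	10.1186/s13024-023-00638-z	2023	African American	MS	TMT	52	51	1840	313	yes
watson2023	Watson et al.	10.1038/s41597-023-02158-3	2023		MS	SRM	130	130	51	30	yes
delcampo2023	Del Campo et al.	10.1038/s41467-023-41122-y	2023		Olink		235	190	665	14	no
kamalian2023	Kamalian et al.	10.3390/biom13071094	2023		Olink		38	48	2936	117	no
tijms2024	Tijms et al.	10.1038/s43587-023-00550-7	2024		MS	TMT	419	187	1309	419	no
pichetbinette2024	Pichet Binette et al.	10.1038/s41593-024-01737-w	2024		Olink		184	352	1331	51	no
guo2024_bio	Guo et al.	10.1038/s41562-024-01924-6	2024	Biologically defined	SomaScan		269	85	6361	279	no
guo2024_clin	Guo et al.	10.1038/s41562-024-01924-6	2024	Clinically defined	SomaScan		138	166	6361	50	no
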
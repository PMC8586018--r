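id	name	lon	lat	size	survey_year	trips_male	trips_female	trips_total	ind_male	ind_female	ind_total
BLM	Blomstrand	12.11	78.99	908	2011	8	17	25	2	3	5
FGL	Fuglehuken	10.47	78.89	4286	2011	11	7	18	8	5	13
KRY	Krykkjefjellet	12.18	78.89	318	2016	13	23	36	4	5	9
OBS	Observasjonsholmen	12.28	78.93	141	2017	35	48	83	6	7	13
OSS	Ossian Sarsfjellet	12.44	78.92	1936	2011	26	17	43	5	3	8
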
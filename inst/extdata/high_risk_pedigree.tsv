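id	father_id	mother_id	sex	birth_year	birth_place	affected
C01	S01	P01	M	1880	in_state	1
C01w	0	0	F	1882	in_state	0
C02	S01	P01	F	1882	in_state	0
C02h	0	0	M	1879	in_state	0
C03	S01	P02	M	1886	in_state	0
C03w	0	0	F	1887	out_of_state	0
C04	T01h	T01	M	1881	in_state	0
C04w	0	0	F	1883	in_state	0
C05	T01h	T01	F	1884	in_state	0
C05h	0	0	M	1881	in_state	0
D01	C01	C01w	M	1905	in_state	1
D01w	0	0	F	1906	in_state	0
D02	C01	C01w	F	1907	in_state	0
D03	C02h	C02	M	1906	in_state	1
D03w	0	0	F	1908	in_state	0
D04	C02h	C02	F	1909	in_state	0
D05	C03	C03w	M	1910	in_state	1
D06	C03	C03w	F	1912	in_state	0
D07	C04	C04w	M	1907	in_state	0
D07w	0	0	F	1909	in_state	0
D08	C04	C04w	F	1910	in_state	0
D09	C05h	C05	M	1908	in_state	0
E01	D01	D01w	M	1931	in_state	0
E02	D01	D01w	F	1933	in_state	0
E03	D03	D03w	M	1932	in_state	0
E04	D07	D07w	M	1933	in_state	0
E05	D07	D07w	F	1936	in_state	0
F01	0	0	M	1830	in_state	0
F02	0	0	F	1832	in_state	0
P01	0	0	F	1858	in_state	0
P02	0	0	F	1861	out_of_state	0
S01	F01	F02	M	1856	in_state	0
T01	F01	F02	F	1858	in_state	0
T01h	0	0	M	1855	in_state	0
U01	0	0	M	1855	in_state	0
U02	0	0	F	1857	in_state	0
U03	U01	U02	M	1881	in_state	0
U04	U01	U02	F	1883	in_state	0
U05w	0	0	F	1884	in_state	0
U06	U03	U05w	M	1908	in_state	0
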
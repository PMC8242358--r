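chr1	1000	5000	peak_1	680	.	1000	5000	0	2	1500,1200,	0,2800,	14.25	3.1	2.4
chr1	8000	9200	peak_2	320	.	8000	9200	0	1	1200,	0,	6.5	2.2	1.8
chr2	100	2600	peak_3	910	.	100	2600	0	3	500,800,400,	0,900,2100,	22.75	5.6	4.9
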
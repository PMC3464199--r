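tetrad_id	grain	red	yellow	cyan
gc01	1	0	1	1
gc01	2	1	1	0
gc01	3	1	1	1
gc01	4	0	0	0
gc02	1	0	1	1
gc02	2	1	1	1
gc02	3	0	0	0
gc02	4	1	1	0
gc03	1	0	1	1
gc03	2	0	0	0
gc03	3	1	1	1
gc03	4	1	1	0
gc04	1	1	1	0
gc04	2	1	1	1
gc04	3	0	0	0
gc04	4	0	1	1
gc05	1	1	1	1
gc05	2	0	0	0
gc05	3	0	1	1
gc05	4	1	1	0
gc06	1	0	1	1
gc06	2	1	1	0
gc06	3	0	0	0
gc06	4	1	1	1
gc07	1	1	1	1
gc07	2	0	0	0
gc07	3	1	1	0
gc07	4	0	1	1
gc08	1	0	0	0
gc08	2	0	1	1
gc08	3	1	1	1
gc08	4	1	1	0
gc09	1	1	1	1
gc09	2	0	1	1
gc09	3	0	0	0
gc09	4	1	1	0
gc10	1	0	1	1
gc10	2	1	1	1
gc10	3	0	0	0
gc10	4	1	1	0
gc11	1	0	0	0
gc11	2	1	1	1
gc11	3	0	1	1
gc11	4	1	1	0
gc12	1	1	1	1
gc12	2	0	0	0
gc12	3	1	1	1
gc12	4	0	1	0
gc13	1	1	1	1
gc13	2	0	1	NA
gc13	3	1	1	0
gc13	4	0	0	0
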
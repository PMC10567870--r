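marker	target	truth	n	fired	source
NB21	nasal	nasal	23	14	both
NB21	nasal	peripheral_blood	22	0	both
NB21	nasal	menstrual_blood	9	0	both
NB21	nasal	saliva	22	0	both
NB21	nasal	vaginal_secretion	15	0	both
NB21	nasal	sperm_secretion	10	0	both
B7	peripheral_blood	nasal	22	0	both
B7	peripheral_blood	peripheral_blood	21	17	both
B7	peripheral_blood	menstrual_blood	13	0	both
B7	peripheral_blood	saliva	21	0	both
B7	peripheral_blood	vaginal_secretion	11	0	both
B7	peripheral_blood	sperm_secretion	8	0	both
MB4	menstrual_blood	nasal	22	0	both
MB4	menstrual_blood	peripheral_blood	23	0	both
MB4	menstrual_blood	menstrual_blood	11	9	both
MB4	menstrual_blood	saliva	22	0	both
MB4	menstrual_blood	vaginal_secretion	12	0	both
MB4	menstrual_blood	sperm_secretion	9	0	both
SA4	saliva	nasal	23	0	both
SA4	saliva	peripheral_blood	23	0	both
SA4	saliva	menstrual_blood	9	0	both
SA4	saliva	saliva	23	23	both
SA4	saliva	vaginal_secretion	9	0	both
SA4	saliva	sperm_secretion	8	0	both
V2	vaginal_secretion	nasal	22	0	both
V2	vaginal_secretion	peripheral_blood	22	0	both
V2	vaginal_secretion	menstrual_blood	9	0	both
V2	vaginal_secretion	saliva	21	0	both
V2	vaginal_secretion	vaginal_secretion	10	9	prose
V2	vaginal_secretion	vaginal_secretion	10	10	table2
V2	vaginal_secretion	sperm_secretion	9	0	both
N27SE	nasal	nasal	27	23	both
N27SE	nasal	peripheral_blood	23	0	both
N27SE	nasal	menstrual_blood	10	0	both
N27SE	nasal	saliva	21	0	both
N27SE	nasal	vaginal_secretion	10	0	both
N27SE	sperm_secretion	peripheral_blood	23	0	both
N27SE	sperm_secretion	menstrual_blood	10	0	both
N27SE	sperm_secretion	saliva	21	0	both
N27SE	sperm_secretion	vaginal_secretion	10	0	both
N27SE	sperm_secretion	sperm_secretion	8	8	both
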
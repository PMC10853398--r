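feature_id	kind	units
age	demographic	au
sex	demographic	au
BMI	demographic	au
HbA1c	clinical	au
glucose	clinical	au
insulin	clinical	au
HOMA_IR	clinical	au
eGFR	clinical	au
clin_0001	clinical	au
prot_A	protein	au
prot_B	protein	au
met_bad	metabolite	au
met_A	metabolite	au
met_B	metabolite	au
met_C	metabolite	au
met_D	metabolite	au
met_E	metabolite	au
met_F	metabolite	au
met_G	metabolite	au
met_H	metabolite	au
met_I	metabolite	au
met_J	metabolite	au
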
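target	baseline	followup	expected_label
HbA1c	5.0	5.5	1
HbA1c	5.0	5.2	0
HbA1c	5.5	5.0	0
glucose	90	93	0
glucose	100	105	1
glucose	100	90	0
insulin	10	10.6	1
insulin	20	19	0
HOMA_IR	2.0	2.2	1
HOMA_IR	2.0	2.05	0
eGFR	100	94	1
eGFR	100	106	0
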
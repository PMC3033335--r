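# background	0.25	0.25	0.25	0.25
# pseudo	0.0001
# feature	BP_core
base	1	2	3	4	5
A	0.15	0.10	0.55	0.92	0.10
C	0.45	0.10	0.10	0.03	0.50
G	0.10	0.05	0.25	0.03	0.10
T	0.30	0.75	0.10	0.02	0.30
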
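fraction	target	tech_rep	ct
IP	SlDML2	1	24.84
input	SlDML2	1	23.81
IP	ACTIN	1	20.11
input	ACTIN	1	19.99
IP	SlDML2	2	24.75
input	SlDML2	2	23.7
IP	ACTIN	2	20.04
input	ACTIN	2	19.92
IP	SlDML2	3	24.81
input	SlDML2	3	23.86
IP	ACTIN	3	20.07
input	ACTIN	3	19.94
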
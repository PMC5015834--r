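Neuron 1	Neuron 2	Type	Nbr
ADAL	ADAR	EJ	2
ADAR	ADAL	EJ	2
ADAL	AIBL	S	2
AIBL	ADAL	R	2
ADAL	AIBR	Sp	1
AIBR	ADAL	Rp	1
AVAL	ADAL	S	3
ADAL	AVAL	R	3
ADAL	MUSCLE	NMJ	5
AVAR	AVAL	EJ	1
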
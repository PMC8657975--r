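TF_A	synthetic toy set	g0001	g0002	g0003	g0004	g0005
TF_B	synthetic toy set	g0006	g0007	g0008	g0009
TF_C	synthetic toy set	g0003	g0010	g0011
MIR_X	synthetic toy set	g0002	g0007	g0012
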
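protein	CDK4
protein	CCND1
protein	RB1
protein	E2F1
protein	CCNE1
protein	INH1
complex	CDK4_CCND1
family	E2F
abstract-process	g1_s_transition
CDK4	CDK4_CCND1	component>
CCND1	CDK4_CCND1	component>
CDK4_CCND1	RB1	-a|
RB1	E2F1	-a|
E2F1	E2F	member>
E2F	CCNE1	-t>
INH1	CDK4	-a|
E2F	g1_s_transition	-a>
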
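# Ground-truth causal graph of the simulated HIV-like system.
# Age (X0), immune status (X2) and comorbidity (X4) confound treatment and
# outcome; geography (X8) drives the instrument Z; the viral-load-like
# mediator M lies on the treatment -> outcome path.
X0	T
X2	T
X4	T
Z	T
X8	Z
X0	Y
X2	Y
X4	Y
T	M
X3	M
M	Y
T	Y
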
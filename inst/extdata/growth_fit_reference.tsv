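model	kingdom	alpha	beta	gamma	lnL_model	lnL_null	p
rrn_eq1	Bacillati	9.000380	0.011936	NA	-19.5164	-25.8209	0.000384
rrn_eq1	Pseudomonadati	8.863043	0.010691	NA	-18.9248	-26.0992	0.000152
trna_eq2	Bacillati	51.377406	0.018713	45.392728	-36.4670	-151.0943	0.000000
trna_eq2	Pseudomonadati	157.323365	0.056354	40.954750	-131.4144	-475.6256	0.000000
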
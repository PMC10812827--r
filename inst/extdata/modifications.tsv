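#oxwave-modlist-v1 rows=11
name	delta_mass	allowed_residues	is_artifact	is_combination
Unmodified	0.0	*	FALSE	FALSE
Oxidation	15.994915	M,W,C,K,F,N,D,P,R,Y,H	FALSE	FALSE
Dioxidation	31.989829	C,W,M,F	FALSE	FALSE
Trioxidation	47.984744	C,W	FALSE	FALSE
Carbamidomethyl	57.021464	C	TRUE	FALSE
Methylthio	45.987721	C	TRUE	FALSE
Acetyl	42.010565	K,N-term	FALSE	FALSE
Deamidated	0.984016	N,Q	FALSE	FALSE
Isotope+1	1.003355	*	TRUE	FALSE
Isotope+2	2.006710	*	TRUE	FALSE
Oxidation+Acetyl	58.005480	K	FALSE	TRUE
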
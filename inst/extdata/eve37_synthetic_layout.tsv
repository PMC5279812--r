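# SYNTHETIC illustrative layout of an eve 3/7-like enhancer (binding-site
# coordinates are invented for demonstration; real site coordinates are a
# user-supplied input).  Columns: position_bp, name, role, occupied.
position_bp	name	role	occupied
120	dStat	activator	TRUE
165	Knirps	repressor	TRUE
210	Zld	activator	TRUE
255	Knirps	repressor	TRUE
300	dStat	activator	TRUE
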
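# synthetic species free energies (kcal/mol);
# magnitudes encode qualitative orderings only
species	energy	charge	spin
reactant-pair-E	0	0	diradical
reactant-pair-D	0	0	diradical
reactant-pair-K	0	0	diradical
reactant-pair-S	0	0	diradical
t4-dha-E	-12	0	closed-shell
t4-dha-D	-10.5	0	closed-shell
t4-dha-K	-9	0	closed-shell
t4-dha-S	-7.5	0	closed-shell
dit-deprotonation-by-E374	4	0	closed-shell
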
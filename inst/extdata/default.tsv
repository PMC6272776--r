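# Element-level lipophilic constants f_i for heavy atoms, hydrogens folded
# into their heavy-atom contribution. Magnitudes follow published atomic
# fragmental systems (Broto; Ghose-Crippen lineage). Positive = hydrophobic,
# negative = polar. Absolute logP back-calculation additionally requires a
# calibration of the linear weights; see calibrate_logp().
C	0.36
N	-0.60
O	-0.40
F	0.22
P	-0.45
S	0.41
Cl	0.94
Br	1.10
I	1.35
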
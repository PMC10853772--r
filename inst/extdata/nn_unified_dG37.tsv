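step	dG_kcal_per_mol	source
AA/TT	-1.00	unified_NN_1998
AT/TA	-0.88	unified_NN_1998
TA/AT	-0.58	unified_NN_1998
CA/GT	-1.45	unified_NN_1998
GT/CA	-1.44	unified_NN_1998
CT/GA	-1.28	unified_NN_1998
GA/CT	-1.30	unified_NN_1998
CG/GC	-2.17	unified_NN_1998
GC/CG	-2.24	unified_NN_1998
GG/CC	-1.84	unified_NN_1998
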
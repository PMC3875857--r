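dinucleotide	propeller_twist	stacking_energy
AA	-18.66	-5.37
AC	-13.10	-10.51
AG	-14.00	-6.78
AT	-15.01	-6.57
CA	-9.45	-6.57
CC	-8.11	-8.26
CG	-10.03	-9.69
CT	-14.00	-6.78
GA	-13.48	-9.81
GC	-11.08	-14.59
GG	-8.11	-8.26
GT	-13.10	-10.51
TA	-11.85	-3.82
TC	-13.48	-9.81
TG	-9.45	-6.57
TT	-18.66	-5.37
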
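# Nearest-neighbor free energies for DNA/DNA stacks at 37 C, 1 M NaCl (kcal/mol).
# context is 5'XY3'/3'WZ5' (top strand/bottom strand); kind 'wc' entries are the
# SantaLucia (1998) unified Watson-Crick parameters; kind 'mm' entries are internal
# single-mismatch contexts from Allawi & SantaLucia (1997, 1998a-c) and Peyret et
# al. (1999), as dG37 = dH - 310.15*dS/1000 from the published dH/dS tables.
# Contexts not listed (e.g. tandem mismatches) are inadmissible in the duplex grammar.
context	kind	dG37
AA/AT	mm	0.6991
AA/CT	mm	1.3350
AA/GT	mm	0.7049
AA/TA	mm	0.6727
AA/TC	mm	0.8733
AA/TG	mm	0.1133
AA/TT	wc	-1.0147
AC/AG	mm	0.1395
AC/CG	mm	0.4786
AC/GG	mm	-0.4925
AC/TA	mm	0.7718
AC/TC	mm	1.3647
AC/TG	wc	-1.4526
AC/TT	mm	0.6380
AG/AC	mm	0.4026
AG/CC	mm	0.7861
AG/GC	mm	0.0940
AG/TA	mm	0.0133
AG/TC	wc	-1.2869
AG/TG	mm	-0.1536
AG/TT	mm	0.7209
AT/AA	mm	0.6727
AT/CA	mm	0.7718
AT/GA	mm	0.0133
AT/TA	wc	-0.8729
AT/TC	mm	0.7229
AT/TG	mm	0.0742
AT/TT	mm	0.6496
CA/AT	mm	0.9188
CA/CT	mm	1.0135
CA/GA	mm	0.4026
CA/GC	mm	0.7524
CA/GG	mm	0.0133
CA/GT	wc	-1.4596
CA/TT	mm	0.7829
CC/AG	mm	0.7959
CC/CG	mm	0.8397
CC/GA	mm	0.7861
CC/GC	mm	0.7331
CC/GG	wc	-1.8280
CC/GT	mm	0.5957
CC/TG	mm	1.0130
CG/AC	mm	0.7524
CG/CC	mm	0.7331
CG/GA	mm	0.0940
CG/GC	wc	-2.1639
CG/GG	mm	-0.1547
CG/GT	mm	-0.4712
CG/TC	mm	0.3919
CT/AA	mm	0.8733
CT/CA	mm	1.3647
CT/GA	wc	-1.2869
CT/GC	mm	0.3919
CT/GG	mm	-0.3188
CT/GT	mm	-0.0996
CT/TA	mm	0.7229
GA/AT	mm	0.4829
GA/CA	mm	0.1395
GA/CC	mm	0.7959
GA/CG	mm	-0.2898
GA/CT	wc	-1.3147
GA/GT	mm	0.4835
GA/TT	mm	0.3438
GC/AG	mm	-0.2898
GC/CA	mm	0.4786
GC/CC	mm	0.8397
GC/CG	wc	-2.2323
GC/CT	mm	0.6252
GC/GG	mm	-1.0996
GC/TG	mm	-0.5852
GG/AC	mm	0.0133
GG/CA	mm	-0.4925
GG/CC	wc	-1.8280
GG/CG	mm	-1.0996
GG/CT	mm	0.0744
GG/GC	mm	-0.1547
GG/TC	mm	-0.3188
GT/AA	mm	0.1133
GT/CA	wc	-1.4526
GT/CC	mm	1.0130
GT/CG	mm	-0.5852
GT/CT	mm	0.4053
GT/GA	mm	-0.1536
GT/TA	mm	0.0742
TA/AA	mm	0.6991
TA/AC	mm	0.9188
TA/AG	mm	0.4829
TA/AT	wc	-0.5938
TA/CT	mm	0.9829
TA/GT	mm	0.4273
TA/TT	mm	0.6652
TC/AA	mm	1.3350
TC/AC	mm	1.0135
TC/AG	wc	-1.3147
TC/AT	mm	0.9829
TC/CG	mm	0.6252
TC/GG	mm	0.0744
TC/TG	mm	0.4053
TG/AA	mm	0.7049
TG/AC	wc	-1.4596
TG/AG	mm	0.4835
TG/AT	mm	0.4273
TG/CC	mm	0.5957
TG/GC	mm	-0.4712
TG/TC	mm	-0.0996
TT/AA	wc	-1.0147
TT/AC	mm	0.7829
TT/AG	mm	0.3438
TT/AT	mm	0.6652
TT/CA	mm	0.6380
TT/GA	mm	0.7209
TT/TA	mm	0.6496
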
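# SYBYL-atom-typed van der Waals radii for Tripos Mol2 input (Angstrom).
# Fine-grained typing after Tsai et al. (1999), as used by UCSF Chimera.
# Key: SYBYL atom type; '=EL' element fallback; '*' global fallback.
# version 1
C.3	1.88
C.2	1.76
C.1	1.78
C.ar	1.77
C.cat	1.76
N.3	1.64
N.2	1.64
N.1	1.64
N.ar	1.64
N.am	1.64
N.pl3	1.64
N.4	1.64
O.3	1.46
O.2	1.42
O.co2	1.42
O.spc	1.46
O.t3p	1.46
S.3	1.78
S.2	1.77
S.o	1.77
S.o2	1.77
P.3	1.87
H	1.00
H.spc	1.00
H.t3p	1.00
F	1.56
Cl	1.74
Br	1.98
I	2.09
Li	1.82
Na	2.27
K	2.75
Ca	1.74
Mg	1.73
Mn	1.61
Fe	1.47
Zn	1.39
Cu	1.40
Se	1.90
Si	2.10
=C	1.80
=N	1.64
=O	1.46
=S	1.78
=P	1.87
=H	1.00
*	1.70
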
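# United-atom van der Waals radii for PDB input (Angstrom).
# Heavy-atom radii following Chothia (1976) as used by NACCESS:
# trigonal/aromatic C 1.76, tetrahedral C 1.87, N 1.65, O 1.40, S 1.85.
# Key: 'RESNAME ATOMNAME'; '=EL' element fallback; '*' global fallback.
# version 1
ALA N	1.65
ALA CA	1.87
ALA C	1.76
ALA O	1.40
ALA OXT	1.40
ALA CB	1.87
ARG N	1.65
ARG CA	1.87
ARG C	1.76
ARG O	1.40
ARG OXT	1.40
ARG CB	1.87
ARG CG	1.87
ARG CD	1.87
ARG NE	1.65
ARG CZ	1.76
ARG NH1	1.65
ARG NH2	1.65
ASN N	1.65
ASN CA	1.87
ASN C	1.76
ASN O	1.40
ASN OXT	1.40
ASN CB	1.87
ASN CG	1.76
ASN OD1	1.40
ASN ND2	1.65
ASP N	1.65
ASP CA	1.87
ASP C	1.76
ASP O	1.40
ASP OXT	1.40
ASP CB	1.87
ASP CG	1.76
ASP OD1	1.40
ASP OD2	1.40
CYS N	1.65
CYS CA	1.87
CYS C	1.76
CYS O	1.40
CYS OXT	1.40
CYS CB	1.87
CYS SG	1.85
GLN N	1.65
GLN CA	1.87
GLN C	1.76
GLN O	1.40
GLN OXT	1.40
GLN CB	1.87
GLN CG	1.87
GLN CD	1.76
GLN OE1	1.40
GLN NE2	1.65
GLU N	1.65
GLU CA	1.87
GLU C	1.76
GLU O	1.40
GLU OXT	1.40
GLU CB	1.87
GLU CG	1.87
GLU CD	1.76
GLU OE1	1.40
GLU OE2	1.40
GLY N	1.65
GLY CA	1.87
GLY C	1.76
GLY O	1.40
GLY OXT	1.40
HIS N	1.65
HIS CA	1.87
HIS C	1.76
HIS O	1.40
HIS OXT	1.40
HIS CB	1.87
HIS CG	1.76
HIS ND1	1.65
HIS CD2	1.76
HIS CE1	1.76
HIS NE2	1.65
ILE N	1.65
ILE CA	1.87
ILE C	1.76
ILE O	1.40
ILE OXT	1.40
ILE CB	1.87
ILE CG1	1.87
ILE CG2	1.87
ILE CD1	1.87
LEU N	1.65
LEU CA	1.87
LEU C	1.76
LEU O	1.40
LEU OXT	1.40
LEU CB	1.87
LEU CG	1.87
LEU CD1	1.87
LEU CD2	1.87
LYS N	1.65
LYS CA	1.87
LYS C	1.76
LYS O	1.40
LYS OXT	1.40
LYS CB	1.87
LYS CG	1.87
LYS CD	1.87
LYS CE	1.87
LYS NZ	1.50
MET N	1.65
MET CA	1.87
MET C	1.76
MET O	1.40
MET OXT	1.40
MET CB	1.87
MET CG	1.87
MET SD	1.85
MET CE	1.87
PHE N	1.65
PHE CA	1.87
PHE C	1.76
PHE O	1.40
PHE OXT	1.40
PHE CB	1.87
PHE CG	1.76
PHE CD1	1.76
PHE CD2	1.76
PHE CE1	1.76
PHE CE2	1.76
PHE CZ	1.76
PRO N	1.65
PRO CA	1.87
PRO C	1.76
PRO O	1.40
PRO OXT	1.40
PRO CB	1.87
PRO CG	1.87
PRO CD	1.87
SER N	1.65
SER CA	1.87
SER C	1.76
SER O	1.40
SER OXT	1.40
SER CB	1.87
SER OG	1.40
THR N	1.65
THR CA	1.87
THR C	1.76
THR O	1.40
THR OXT	1.40
THR CB	1.87
THR OG1	1.40
THR CG2	1.87
TRP N	1.65
TRP CA	1.87
TRP C	1.76
TRP O	1.40
TRP OXT	1.40
TRP CB	1.87
TRP CG	1.76
TRP CD1	1.76
TRP CD2	1.76
TRP NE1	1.65
TRP CE2	1.76
TRP CE3	1.76
TRP CZ2	1.76
TRP CZ3	1.76
TRP CH2	1.76
TYR N	1.65
TYR CA	1.87
TYR C	1.76
TYR O	1.40
TYR OXT	1.40
TYR CB	1.87
TYR CG	1.76
TYR CD1	1.76
TYR CD2	1.76
TYR CE1	1.76
TYR CE2	1.76
TYR CZ	1.76
TYR OH	1.40
VAL N	1.65
VAL CA	1.87
VAL C	1.76
VAL O	1.40
VAL OXT	1.40
VAL CB	1.87
VAL CG1	1.87
VAL CG2	1.87
A P	1.90
A OP1	1.40
A OP2	1.40
A OP3	1.40
A O1P	1.40
A O2P	1.40
A O3P	1.40
A O5'	1.40
A C5'	1.87
A C4'	1.87
A O4'	1.40
A C3'	1.87
A O3'	1.40
A C2'	1.87
A O2'	1.40
A C1'	1.87
A N9	1.65
A C8	1.76
A N7	1.65
A C5	1.76
A C6	1.76
A N6	1.65
A N1	1.65
A C2	1.76
A N3	1.65
A C4	1.76
DA P	1.90
DA OP1	1.40
DA OP2	1.40
DA OP3	1.40
DA O1P	1.40
DA O2P	1.40
DA O3P	1.40
DA O5'	1.40
DA C5'	1.87
DA C4'	1.87
DA O4'	1.40
DA C3'	1.87
DA O3'	1.40
DA C2'	1.87
DA O2'	1.40
DA C1'	1.87
DA N9	1.65
DA C8	1.76
DA N7	1.65
DA C5	1.76
DA C6	1.76
DA N6	1.65
DA N1	1.65
DA C2	1.76
DA N3	1.65
DA C4	1.76
G P	1.90
G OP1	1.40
G OP2	1.40
G OP3	1.40
G O1P	1.40
G O2P	1.40
G O3P	1.40
G O5'	1.40
G C5'	1.87
G C4'	1.87
G O4'	1.40
G C3'	1.87
G O3'	1.40
G C2'	1.87
G O2'	1.40
G C1'	1.87
G N9	1.65
G C8	1.76
G N7	1.65
G C5	1.76
G C6	1.76
G O6	1.40
G N1	1.65
G C2	1.76
G N2	1.65
G N3	1.65
G C4	1.76
DG P	1.90
DG OP1	1.40
DG OP2	1.40
DG OP3	1.40
DG O1P	1.40
DG O2P	1.40
DG O3P	1.40
DG O5'	1.40
DG C5'	1.87
DG C4'	1.87
DG O4'	1.40
DG C3'	1.87
DG O3'	1.40
DG C2'	1.87
DG O2'	1.40
DG C1'	1.87
DG N9	1.65
DG C8	1.76
DG N7	1.65
DG C5	1.76
DG C6	1.76
DG O6	1.40
DG N1	1.65
DG C2	1.76
DG N2	1.65
DG N3	1.65
DG C4	1.76
C P	1.90
C OP1	1.40
C OP2	1.40
C OP3	1.40
C O1P	1.40
C O2P	1.40
C O3P	1.40
C O5'	1.40
C C5'	1.87
C C4'	1.87
C O4'	1.40
C C3'	1.87
C O3'	1.40
C C2'	1.87
C O2'	1.40
C C1'	1.87
C N1	1.65
C C2	1.76
C O2	1.40
C N3	1.65
C C4	1.76
C N4	1.65
C C5	1.76
C C6	1.76
DC P	1.90
DC OP1	1.40
DC OP2	1.40
DC OP3	1.40
DC O1P	1.40
DC O2P	1.40
DC O3P	1.40
DC O5'	1.40
DC C5'	1.87
DC C4'	1.87
DC O4'	1.40
DC C3'	1.87
DC O3'	1.40
DC C2'	1.87
DC O2'	1.40
DC C1'	1.87
DC N1	1.65
DC C2	1.76
DC O2	1.40
DC N3	1.65
DC C4	1.76
DC N4	1.65
DC C5	1.76
DC C6	1.76
T P	1.90
T OP1	1.40
T OP2	1.40
T OP3	1.40
T O1P	1.40
T O2P	1.40
T O3P	1.40
T O5'	1.40
T C5'	1.87
T C4'	1.87
T O4'	1.40
T C3'	1.87
T O3'	1.40
T C2'	1.87
T O2'	1.40
T C1'	1.87
T N1	1.65
T C2	1.76
T O2	1.40
T N3	1.65
T C4	1.76
T O4	1.40
T C5	1.76
T C7	1.87
T C5M	1.87
T C6	1.76
DT P	1.90
DT OP1	1.40
DT OP2	1.40
DT OP3	1.40
DT O1P	1.40
DT O2P	1.40
DT O3P	1.40
DT O5'	1.40
DT C5'	1.87
DT C4'	1.87
DT O4'	1.40
DT C3'	1.87
DT O3'	1.40
DT C2'	1.87
DT O2'	1.40
DT C1'	1.87
DT N1	1.65
DT C2	1.76
DT O2	1.40
DT N3	1.65
DT C4	1.76
DT O4	1.40
DT C5	1.76
DT C7	1.87
DT C5M	1.87
DT C6	1.76
U P	1.90
U OP1	1.40
U OP2	1.40
U OP3	1.40
U O1P	1.40
U O2P	1.40
U O3P	1.40
U O5'	1.40
U C5'	1.87
U C4'	1.87
U O4'	1.40
U C3'	1.87
U O3'	1.40
U C2'	1.87
U O2'	1.40
U C1'	1.87
U N1	1.65
U C2	1.76
U O2	1.40
U N3	1.65
U C4	1.76
U O4	1.40
U C5	1.76
U C6	1.76
DU P	1.90
DU OP1	1.40
DU OP2	1.40
DU OP3	1.40
DU O1P	1.40
DU O2P	1.40
DU O3P	1.40
DU O5'	1.40
DU C5'	1.87
DU C4'	1.87
DU O4'	1.40
DU C3'	1.87
DU O3'	1.40
DU C2'	1.87
DU O2'	1.40
DU C1'	1.87
DU N1	1.65
DU C2	1.76
DU O2	1.40
DU N3	1.65
DU C4	1.76
DU O4	1.40
DU C5	1.76
DU C6	1.76
=C	1.80
=N	1.65
=O	1.40
=S	1.85
=P	1.90
=H	1.00
=D	1.00
=F	1.47
=CL	1.75
=BR	1.85
=I	1.98
=FE	1.47
=ZN	1.39
=MG	1.73
=CA	1.74
=NA	2.27
=K	2.75
=MN	1.61
=CU	1.40
*	1.70
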
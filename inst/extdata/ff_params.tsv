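resid	atom	type	charge
ALA	N	NH	-0.16
ALA	CA	CT	0.16
ALA	C	CO	0.51
ALA	O	OA	-0.51
ALA	CB	CT	0
ARG	N	NH	-0.16
ARG	CA	CT	0.16
ARG	C	CO	0.51
ARG	O	OA	-0.51
ARG	CB	CT	0
ARG	CG	CT	0
ARG	CD	CT	0.1
ARG	NE	NH	0.1
ARG	CZ	CR	0.5
ARG	NH1	NH	0.15
ARG	NH2	NH	0.15
ASN	N	NH	-0.16
ASN	CA	CT	0.16
ASN	C	CO	0.51
ASN	O	OA	-0.51
ASN	CB	CT	0
ASN	CG	CO	0.55
ASN	OD1	OA	-0.55
ASN	ND2	NH	0
ASP	N	NH	-0.16
ASP	CA	CT	0.16
ASP	C	CO	0.51
ASP	O	OA	-0.51
ASP	CB	CT	-0.16
ASP	CG	CO	0.62
ASP	OD1	OC	-0.73
ASP	OD2	OC	-0.73
CYS	N	NH	-0.16
CYS	CA	CT	0.16
CYS	C	CO	0.51
CYS	O	OA	-0.51
CYS	CB	CT	0.1
CYS	SG	SA	-0.1
GLN	N	NH	-0.16
GLN	CA	CT	0.16
GLN	C	CO	0.51
GLN	O	OA	-0.51
GLN	CB	CT	0
GLN	CG	CT	0
GLN	CD	CO	0.55
GLN	OE1	OA	-0.55
GLN	NE2	NH	0
GLU	N	NH	-0.16
GLU	CA	CT	0.16
GLU	C	CO	0.51
GLU	O	OA	-0.51
GLU	CB	CT	0
GLU	CG	CT	-0.16
GLU	CD	CO	0.62
GLU	OE1	OC	-0.73
GLU	OE2	OC	-0.73
GLY	N	NH	-0.16
GLY	CA	CT	0.16
GLY	C	CO	0.51
GLY	O	OA	-0.51
HIS	N	NH	-0.16
HIS	CA	CT	0.16
HIS	C	CO	0.51
HIS	O	OA	-0.51
HIS	CB	CT	0
HIS	CG	CR	0
HIS	ND1	NH	0
HIS	CD2	CR	0.1
HIS	CE1	CR	0.3
HIS	NE2	NH	-0.4
ILE	N	NH	-0.16
ILE	CA	CT	0.16
ILE	C	CO	0.51
ILE	O	OA	-0.51
ILE	CB	CT	0
ILE	CG1	CT	0
ILE	CG2	CT	0
ILE	CD1	CT	0
LEU	N	NH	-0.16
LEU	CA	CT	0.16
LEU	C	CO	0.51
LEU	O	OA	-0.51
LEU	CB	CT	0
LEU	CG	CT	0
LEU	CD1	CT	0
LEU	CD2	CT	0
LYS	N	NH	-0.16
LYS	CA	CT	0.16
LYS	C	CO	0.51
LYS	O	OA	-0.51
LYS	CB	CT	0
LYS	CG	CT	0
LYS	CD	CT	0
LYS	CE	CT	0.25
LYS	NZ	NH	0.75
MET	N	NH	-0.16
MET	CA	CT	0.16
MET	C	CO	0.51
MET	O	OA	-0.51
MET	CB	CT	0
MET	CG	CT	0.1
MET	SD	SA	-0.2
MET	CE	CT	0.1
PHE	N	NH	-0.16
PHE	CA	CT	0.16
PHE	C	CO	0.51
PHE	O	OA	-0.51
PHE	CB	CT	0
PHE	CG	CR	0
PHE	CD1	CR	0
PHE	CD2	CR	0
PHE	CE1	CR	0
PHE	CE2	CR	0
PHE	CZ	CR	0
PRO	N	NH	-0.16
PRO	CA	CT	0.16
PRO	C	CO	0.51
PRO	O	OA	-0.51
PRO	CB	CT	0
PRO	CG	CT	0
PRO	CD	CT	0
SER	N	NH	-0.16
SER	CA	CT	0.16
SER	C	CO	0.51
SER	O	OA	-0.51
SER	CB	CT	0.31
SER	OG	OH	-0.31
THR	N	NH	-0.16
THR	CA	CT	0.16
THR	C	CO	0.51
THR	O	OA	-0.51
THR	CB	CT	0.25
THR	OG1	OH	-0.25
THR	CG2	CT	0
TRP	N	NH	-0.16
TRP	CA	CT	0.16
TRP	C	CO	0.51
TRP	O	OA	-0.51
TRP	CB	CT	0
TRP	CG	CR	0
TRP	CD1	CR	0
TRP	CD2	CR	0
TRP	NE1	NH	0
TRP	CE2	CR	0
TRP	CE3	CR	0
TRP	CZ2	CR	0
TRP	CZ3	CR	0
TRP	CH2	CR	0
TYR	N	NH	-0.16
TYR	CA	CT	0.16
TYR	C	CO	0.51
TYR	O	OA	-0.51
TYR	CB	CT	0
TYR	CG	CR	0
TYR	CD1	CR	0
TYR	CD2	CR	0
TYR	CE1	CR	0
TYR	CE2	CR	0
TYR	CZ	CR	0.25
TYR	OH	OH	-0.25
VAL	N	NH	-0.16
VAL	CA	CT	0.16
VAL	C	CO	0.51
VAL	O	OA	-0.51
VAL	CB	CT	0
VAL	CG1	CT	0
VAL	CG2	CT	0
A	P	PA	1.2
A	OP1	OC	-0.8
A	OP2	OC	-0.8
A	O5'	OS	-0.3
A	O3'	OS	-0.3
A	C5'	CT	0
A	C4'	CT	0.15
A	O4'	OS	-0.3
A	C3'	CT	0.15
A	C2'	CT	0.35
A	O2'	OH	-0.35
A	C1'	CT	0
A	N9	NH	-0.05
A	C8	CR	0.25
A	N7	NH	-0.5
A	C5	CR	0.1
A	C6	CR	0.55
A	N6	NH	-0.1
A	N1	NH	-0.6
A	C2	CR	0.4
A	N3	NH	-0.55
A	C4	CR	0.5
G	P	PA	1.2
G	OP1	OC	-0.8
G	OP2	OC	-0.8
G	O5'	OS	-0.3
G	O3'	OS	-0.3
G	C5'	CT	0
G	C4'	CT	0.15
G	O4'	OS	-0.3
G	C3'	CT	0.15
G	C2'	CT	0.35
G	O2'	OH	-0.35
G	C1'	CT	0
G	N9	NH	-0.05
G	C8	CR	0.25
G	N7	NH	-0.5
G	C5	CR	0.1
G	C6	CO	0.55
G	O6	OA	-0.55
G	N1	NH	-0.1
G	C2	CR	0.6
G	N2	NH	-0.1
G	N3	NH	-0.6
G	C4	CR	0.4
C	P	PA	1.2
C	OP1	OC	-0.8
C	OP2	OC	-0.8
C	O5'	OS	-0.3
C	O3'	OS	-0.3
C	C5'	CT	0
C	C4'	CT	0.15
C	O4'	OS	-0.3
C	C3'	CT	0.15
C	C2'	CT	0.35
C	O2'	OH	-0.35
C	C1'	CT	0
C	N1	NH	-0.05
C	C2	CO	0.6
C	O2	OA	-0.55
C	N3	NH	-0.65
C	C4	CR	0.65
C	N4	NH	-0.1
C	C5	CR	-0.2
C	C6	CR	0.3
U	P	PA	1.2
U	OP1	OC	-0.8
U	OP2	OC	-0.8
U	O5'	OS	-0.3
U	O3'	OS	-0.3
U	C5'	CT	0
U	C4'	CT	0.15
U	O4'	OS	-0.3
U	C3'	CT	0.15
U	C2'	CT	0.35
U	O2'	OH	-0.35
U	C1'	CT	0
U	N1	NH	-0.05
U	C2	CO	0.55
U	O2	OA	-0.5
U	N3	NH	-0.1
U	C4	CO	0.55
U	O4	OA	-0.5
U	C5	CR	-0.2
U	C6	CR	0.25
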
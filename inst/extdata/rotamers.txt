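# Illustrative rotamer library: three chi1 wells per residue.
# residue chi1 chi2 chi3 chi4 probability ('.' = unused)
ARG 180.0 180.0 180.0 180.0 0.5
ARG -60.0 180.0 180.0 180.0 0.3
ARG 60.0 180.0 180.0 180.0 0.2
ASN 180.0 180.0 . . 0.5
ASN -60.0 180.0 . . 0.3
ASN 60.0 180.0 . . 0.2
ASP 180.0 180.0 . . 0.5
ASP -60.0 180.0 . . 0.3
ASP 60.0 180.0 . . 0.2
CYS 180.0 . . . 0.5
CYS -60.0 . . . 0.3
CYS 60.0 . . . 0.2
GLN 180.0 180.0 180.0 . 0.5
GLN -60.0 180.0 180.0 . 0.3
GLN 60.0 180.0 180.0 . 0.2
GLU 180.0 180.0 180.0 . 0.5
GLU -60.0 180.0 180.0 . 0.3
GLU 60.0 180.0 180.0 . 0.2
HIS 180.0 180.0 . . 0.5
HIS -60.0 180.0 . . 0.3
HIS 60.0 180.0 . . 0.2
ILE 180.0 180.0 . . 0.5
ILE -60.0 180.0 . . 0.3
ILE 60.0 180.0 . . 0.2
LEU 180.0 180.0 . . 0.5
LEU -60.0 180.0 . . 0.3
LEU 60.0 180.0 . . 0.2
LYS 180.0 180.0 180.0 180.0 0.5
LYS -60.0 180.0 180.0 180.0 0.3
LYS 60.0 180.0 180.0 180.0 0.2
MET 180.0 180.0 180.0 . 0.5
MET -60.0 180.0 180.0 . 0.3
MET 60.0 180.0 180.0 . 0.2
PHE 180.0 180.0 . . 0.5
PHE -60.0 180.0 . . 0.3
PHE 60.0 180.0 . . 0.2
TYR 180.0 180.0 . . 0.5
TYR -60.0 180.0 . . 0.3
TYR 60.0 180.0 . . 0.2
SER 180.0 . . . 0.5
SER -60.0 . . . 0.3
SER 60.0 . . . 0.2
THR 180.0 . . . 0.5
THR -60.0 . . . 0.3
THR 60.0 . . . 0.2
TRP 180.0 180.0 . . 0.5
TRP -60.0 180.0 . . 0.3
TRP 60.0 180.0 . . 0.2
VAL 180.0 . . . 0.5
VAL -60.0 . . . 0.3
VAL 60.0 . . . 0.2
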
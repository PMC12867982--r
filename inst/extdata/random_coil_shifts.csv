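restype,atom,shift_ppm
ALA,CA,52.5
ALA,CO,177.8
ARG,CA,56.0
ARG,CO,176.3
ASN,CA,52.8
ASN,CO,175.2
ASP,CA,53.1
ASP,CO,176.3
CYS,CA,58.2
CYS,CO,174.6
GLN,CA,55.7
GLN,CO,176.0
GLU,CA,56.6
GLU,CO,176.6
GLY,CA,45.1
GLY,CO,174.9
HIS,CA,55.0
HIS,CO,174.1
ILE,CA,61.1
ILE,CO,176.4
LEU,CA,55.1
LEU,CO,177.6
LYS,CA,56.2
LYS,CO,176.6
MET,CA,55.4
MET,CO,176.3
PHE,CA,57.7
PHE,CO,175.8
PRO,CA,63.3
PRO,CO,177.3
SER,CA,58.3
SER,CO,174.6
THR,CA,61.8
THR,CO,174.7
TRP,CA,57.5
TRP,CO,176.1
TYR,CA,57.9
TYR,CO,175.9
VAL,CA,62.2
VAL,CO,176.3
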
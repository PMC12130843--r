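# Illustrative charged-group memberships (Charmm-style atom names).
# Each residue's listed atoms must together carry the integer formal
# charge; scale_group_charges() verifies this before scaling, so edit this
# file to match your force field if the check fails.
residue,atom
ASP,CB
ASP,HB1
ASP,HB2
ASP,CG
ASP,OD1
ASP,OD2
GLU,CG
GLU,HG1
GLU,HG2
GLU,CD
GLU,OE1
GLU,OE2
LYS,CE
LYS,HE1
LYS,HE2
LYS,NZ
LYS,HZ1
LYS,HZ2
LYS,HZ3
ARG,CD
ARG,HD1
ARG,HD2
ARG,NE
ARG,HE
ARG,CZ
ARG,NH1
ARG,HH11
ARG,HH12
ARG,NH2
ARG,HH21
ARG,HH22
HSP,CB
HSP,HB1
HSP,HB2
HSP,CG
HSP,ND1
HSP,HD1
HSP,CD2
HSP,HD2
HSP,NE2
HSP,HE2
HSP,CE1
HSP,HE1
POT,POT
K,K
SOD,SOD
NA,NA
CLA,CLA
CL,CL
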
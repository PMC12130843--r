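; Minimal example topology (Charmm-style charges) for charge-scaling demos.
; One ASP (-1), one LYS (+1), a K+ / Cl- pair and one TIP3 water: net 0 e.
[ moleculetype ]
; name  nrexcl
DEMO    3

[ atoms ]
;   nr  type  resnr residue  atom   cgnr     charge       mass
     1   NH1      1    ASP      N      1      -0.47     14.007
     2     H      1    ASP     HN      1       0.31      1.008
     3   CT1      1    ASP     CA      1       0.07     12.011
     4   HB1      1    ASP     HA      1       0.09      1.008
     5   CT2      1    ASP     CB      2      -0.28     12.011
     6   HA2      1    ASP    HB1      2       0.09      1.008
     7   HA2      1    ASP    HB2      2       0.09      1.008
     8    CC      1    ASP     CG      2       0.62     12.011
     9    OC      1    ASP    OD1      2      -0.76     15.999
    10    OC      1    ASP    OD2      2      -0.76     15.999
    11     C      1    ASP      C      3       0.51     12.011
    12     O      1    ASP      O      3      -0.51     15.999
    13   NH1      2    LYS      N      4      -0.47     14.007
    14     H      2    LYS     HN      4       0.31      1.008
    15   CT1      2    LYS     CA      4       0.07     12.011
    16   HB1      2    LYS     HA      4       0.09      1.008
    17   CT2      2    LYS     CB      5      -0.18     12.011
    18   HA2      2    LYS    HB1      5       0.09      1.008
    19   HA2      2    LYS    HB2      5       0.09      1.008
    20   CT2      2    LYS     CG      5      -0.18     12.011
    21   HA2      2    LYS    HG1      5       0.09      1.008
    22   HA2      2    LYS    HG2      5       0.09      1.008
    23   CT2      2    LYS     CD      5      -0.18     12.011
    24   HA2      2    LYS    HD1      5       0.09      1.008
    25   HA2      2    LYS    HD2      5       0.09      1.008
    26   CT2      2    LYS     CE      6       0.21     12.011
    27   HA2      2    LYS    HE1      6       0.05      1.008
    28   HA2      2    LYS    HE2      6       0.05      1.008
    29   NH3      2    LYS     NZ      6      -0.30     14.007
    30    HC      2    LYS    HZ1      6       0.33      1.008
    31    HC      2    LYS    HZ2      6       0.33      1.008
    32    HC      2    LYS    HZ3      6       0.33      1.008
    33     C      2    LYS      C      7       0.51     12.011
    34     O      2    LYS      O      7      -0.51     15.999
    35   POT      3    POT    POT      8       1.00     39.098
    36   CLA      4    CLA    CLA      9      -1.00     35.450
    37   OT       5    SOL     OW     10      -0.834    15.999
    38   HT       5    SOL    HW1     10       0.417     1.008
    39   HT       5    SOL    HW2     10       0.417     1.008
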
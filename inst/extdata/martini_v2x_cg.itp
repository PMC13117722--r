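; Coarse-grained parameter subset in the MARTINI 2.x style:
; three phosphatidylcholine lipids (DPPC, DOPC, POPC) and 4-to-1 water.
; Pair interactions follow the published 2.x interaction-level scheme
; (epsilon levels O..IX, sigma 0.47 nm, super-repulsive pairs 0.62 nm).
; This file is data, not code: substitute a force-field revision by
; pointing the readers at another file with the same sections.

[ defaults ]
; nbfunc comb-rule
  1      2

[ atomtypes ]
; name  mass   charge  ptype
  Q0    72.0   0.000   A
  Qa    72.0   0.000   A
  Na    72.0   0.000   A
  C1    72.0   0.000   A
  C3    72.0   0.000   A
  P4    72.0   0.000   A

[ nonbond_params ]
; i   j   func  sigma(nm)  epsilon(kJ/mol)
  Q0  Q0  1     0.470      3.500
  Q0  Qa  1     0.470      4.500
  Q0  Na  1     0.470      4.500
  Q0  C1  1     0.620      2.000
  Q0  C3  1     0.470      2.700
  Q0  P4  1     0.470      5.600
  Qa  Qa  1     0.470      5.000
  Qa  Na  1     0.470      4.500
  Qa  C1  1     0.620      2.000
  Qa  C3  1     0.470      2.700
  Qa  P4  1     0.470      5.600
  Na  Na  1     0.470      4.000
  Na  C1  1     0.470      2.700
  Na  C3  1     0.470      2.700
  Na  P4  1     0.470      4.000
  C1  C1  1     0.470      3.500
  C1  C3  1     0.470      3.500
  C1  P4  1     0.470      2.000
  C3  C3  1     0.470      3.500
  C3  P4  1     0.470      2.700
  P4  P4  1     0.470      5.000

[ moleculetype ]
; name  nrexcl
DPPC    1

[ atoms ]
; id  type  resnr  residue  atom  cgnr  charge
  1   Q0    1      DPPC     NC3   1      1.0
  2   Qa    1      DPPC     PO4   2     -1.0
  3   Na    1      DPPC     GL1   3      0.0
  4   Na    1      DPPC     GL2   4      0.0
  5   C1    1      DPPC     C1A   5      0.0
  6   C1    1      DPPC     C2A   6      0.0
  7   C1    1      DPPC     C3A   7      0.0
  8   C1    1      DPPC     C4A   8      0.0
  9   C1    1      DPPC     C1B   9      0.0
  10  C1    1      DPPC     C2B   10     0.0
  11  C1    1      DPPC     C3B   11     0.0
  12  C1    1      DPPC     C4B   12     0.0

[ bonds ]
; i  j  func  b0(nm)  kb(kJ/mol/nm2)
  1  2  1     0.470   1250
  2  3  1     0.470   1250
  3  4  1     0.470   1250
  3  5  1     0.470   1250
  5  6  1     0.470   1250
  6  7  1     0.470   1250
  7  8  1     0.470   1250
  4  9  1     0.470   1250
  9  10 1     0.470   1250
  10 11 1     0.470   1250
  11 12 1     0.470   1250

[ angles ]
; i  j  k  func  theta0(deg)  ka(kJ/mol)
  1  2  3  2     180          25
  2  3  4  2     180          25
  2  3  5  2     180          25
  3  5  6  2     180          25
  5  6  7  2     180          25
  6  7  8  2     180          25
  3  4  9  2     180          25
  4  9  10 2     180          25
  9  10 11 2     180          25
  10 11 12 2     180          25

[ moleculetype ]
; name  nrexcl
DOPC    1

[ atoms ]
; id  type  resnr  residue  atom  cgnr  charge
  1   Q0    1      DOPC     NC3   1      1.0
  2   Qa    1      DOPC     PO4   2     -1.0
  3   Na    1      DOPC     GL1   3      0.0
  4   Na    1      DOPC     GL2   4      0.0
  5   C1    1      DOPC     C1A   5      0.0
  6   C1    1      DOPC     C2A   6      0.0
  7   C3    1      DOPC     D3A   7      0.0
  8   C1    1      DOPC     C4A   8      0.0
  9   C1    1      DOPC     C1B   9      0.0
  10  C1    1      DOPC     C2B   10     0.0
  11  C3    1      DOPC     D3B   11     0.0
  12  C1    1      DOPC     C4B   12     0.0

[ bonds ]
; i  j  func  b0(nm)  kb(kJ/mol/nm2)
  1  2  1     0.470   1250
  2  3  1     0.470   1250
  3  4  1     0.470   1250
  3  5  1     0.470   1250
  5  6  1     0.470   1250
  6  7  1     0.470   1250
  7  8  1     0.470   1250
  4  9  1     0.470   1250
  9  10 1     0.470   1250
  10 11 1     0.470   1250
  11 12 1     0.470   1250

[ angles ]
; i  j  k  func  theta0(deg)  ka(kJ/mol)
  1  2  3  2     180          25
  2  3  4  2     180          25
  2  3  5  2     180          25
  3  5  6  2     180          25
  5  6  7  2     180          25
  6  7  8  2     120          45
  3  4  9  2     180          25
  4  9  10 2     180          25
  9  10 11 2     180          25
  10 11 12 2     120          45

[ moleculetype ]
; name  nrexcl
POPC    1

[ atoms ]
; id  type  resnr  residue  atom  cgnr  charge
  1   Q0    1      POPC     NC3   1      1.0
  2   Qa    1      POPC     PO4   2     -1.0
  3   Na    1      POPC     GL1   3      0.0
  4   Na    1      POPC     GL2   4      0.0
  5   C1    1      POPC     C1A   5      0.0
  6   C1    1      POPC     C2A   6      0.0
  7   C1    1      POPC     C3A   7      0.0
  8   C1    1      POPC     C4A   8      0.0
  9   C1    1      POPC     C1B   9      0.0
  10  C1    1      POPC     C2B   10     0.0
  11  C3    1      POPC     D3B   11     0.0
  12  C1    1      POPC     C4B   12     0.0

[ bonds ]
; i  j  func  b0(nm)  kb(kJ/mol/nm2)
  1  2  1     0.470   1250
  2  3  1     0.470   1250
  3  4  1     0.470   1250
  3  5  1     0.470   1250
  5  6  1     0.470   1250
  6  7  1     0.470   1250
  7  8  1     0.470   1250
  4  9  1     0.470   1250
  9  10 1     0.470   1250
  10 11 1     0.470   1250
  11 12 1     0.470   1250

[ angles ]
; i  j  k  func  theta0(deg)  ka(kJ/mol)
  1  2  3  2     180          25
  2  3  4  2     180          25
  2  3  5  2     180          25
  3  5  6  2     180          25
  5  6  7  2     180          25
  6  7  8  2     180          25
  3  4  9  2     180          25
  4  9  10 2     180          25
  9  10 11 2     180          25
  10 11 12 2     120          45

[ moleculetype ]
; name  nrexcl
W       1

[ atoms ]
; id  type  resnr  residue  atom  cgnr  charge
  1   P4    1      W        W     1      0.0
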
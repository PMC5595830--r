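HETATM    1  C0  LIG A 900       0.000 -30.000   0.000  1.00  0.00           C  
HETATM    2  C1  LIG A 900      40.000   0.000   0.000  1.00  0.00           C  
ATOM      3  CD1 LEU A   1      44.400   0.000   0.000  1.00  0.00           C  
ATOM      4  CG  LEU A   1      45.200   1.200   0.000  1.00  0.00           C  
ATOM      5  CD2 LEU A   1      45.900   2.000   0.000  1.00  0.00           C  
ATOM      6  CB  LEU A   1      46.700  -1.000   0.000  1.00  0.00           C  
ATOM      7  CA  LEU A   1      47.400   0.000   0.000  1.00  0.00           C  
HETATM    8  N1  LIG A 900      80.000   0.000   0.000  1.00  0.00           N  
ATOM      9  OD1 ASP A   2      83.800   0.000   0.000  1.00  0.00           O  
ATOM     10  OD2 ASP A   2      84.800   1.000   0.000  1.00  0.00           O  
ATOM     11  CG  ASP A   2      84.600  -0.900   0.000  1.00  0.00           C  
ATOM     12  CB  ASP A   2      86.000  -0.900   0.000  1.00  0.00           C  
ATOM     13  CA  ASP A   2      87.500  -0.900   0.000  1.00  0.00           C  
END   
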
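ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  GLY A   1       1.200   0.850   0.200  1.00  0.00           C
ATOM      3  C   GLY A   1       2.500   0.100   0.100  1.00  0.00           C
ATOM      4  O   GLY A   1       2.800  -0.900   0.800  1.00  0.00           O
ATOM      5  N   ALA A   2       3.800   0.000   0.000  1.00  0.00           N
ATOM      6  CA  ALA A   2       5.000  -0.850   0.200  1.00  0.00           C
ATOM      7  C   ALA A   2       6.300  -0.100   0.100  1.00  0.00           C
ATOM      8  O   ALA A   2       6.600   0.900   0.800  1.00  0.00           O
ATOM      9  CB  ALA A   2       5.050  -1.750  -1.000  1.00  0.00           C
ATOM     10  N   SER A   3       7.600   0.000   0.000  1.00  0.00           N
ATOM     11  CA  SER A   3       8.800   0.850   0.200  1.00  0.00           C
ATOM     12  C   SER A   3      10.100   0.100   0.100  1.00  0.00           C
ATOM     13  O   SER A   3      10.400  -0.900   0.800  1.00  0.00           O
ATOM     14  CB  SER A   3       8.850   1.750  -1.000  1.00  0.00           C
ATOM     15  OG  SER A   3       8.900   2.900  -0.200  1.00  0.00           O
ATOM     16  N   VAL A   4      11.400   0.000   0.000  1.00  0.00           N
ATOM     17  CA  VAL A   4      12.600  -0.850   0.200  1.00  0.00           C
ATOM     18  C   VAL A   4      13.900  -0.100   0.100  1.00  0.00           C
ATOM     19  O   VAL A   4      14.200   0.900   0.800  1.00  0.00           O
ATOM     20  CB  VAL A   4      12.650  -1.750  -1.000  1.00  0.00           C
ATOM     21  CG1 VAL A   4      11.500  -2.400  -1.600  1.00  0.00           C
ATOM     22  CG2 VAL A   4      13.700  -2.500  -1.600  1.00  0.00           C
ATOM     23  N   LEU A   5      15.200   0.000   0.000  1.00  0.00           N
ATOM     24  CA  LEU A   5      16.400   0.850   0.200  1.00  0.00           C
ATOM     25  C   LEU A   5      17.700   0.100   0.100  1.00  0.00           C
ATOM     26  O   LEU A   5      18.000  -0.900   0.800  1.00  0.00           O
ATOM     27  CB  LEU A   5      16.450   1.750  -1.000  1.00  0.00           C
ATOM     28  CG  LEU A   5      16.500   2.900  -0.400  1.00  0.00           C
ATOM     29  CD1 LEU A   5      15.400   3.800  -0.900  1.00  0.00           C
ATOM     30  CD2 LEU A   5      17.800   3.600  -0.700  1.00  0.00           C
HETATM   31  O   HOH A 101      20.000  20.000  20.000  1.00  0.00           O
END
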
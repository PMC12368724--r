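ATOM      1  N   ASN A   1       0.300  -1.200   0.400  1.00  0.00           N
ATOM      2  CA  ASN A   1       1.100  -0.200   1.000  1.00  0.00           C
ATOM      3  C   ASN A   1       0.600   1.200   0.900  1.00  0.00           C
ATOM      4  O   ASN A   1       1.000   2.100   1.700  1.00  0.00           O
ATOM      5  CB  ASN A   1       2.600  -0.300   0.700  1.00  0.00           C
ATOM      6  CG  ASN A   1       3.200   0.900   0.100  1.00  0.00           C
ATOM      7  OD1 ASN A   1       3.000   2.050   0.450  1.00  0.00           O
ATOM      8  ND2 ASN A   1       3.400   0.900  -1.210  1.00  0.00           N
ATOM      9  N   GLY A   2      -0.700   1.500   0.200  1.00  0.00           N
ATOM     10  CA  GLY A   2      -1.500   2.600   0.500  1.00  0.00           C
ATOM     11  C   GLY A   2      -2.900   2.300   0.000  1.00  0.00           C
ATOM     12  O   GLY A   2      -3.300   1.200  -0.300  1.00  0.00           O
ATOM     13  N   ASN B   1       8.900  -1.200   0.400  1.00  0.00           N
ATOM     14  CA  ASN B   1       8.100  -0.200   1.000  1.00  0.00           C
ATOM     15  C   ASN B   1       8.600   1.200   0.900  1.00  0.00           C
ATOM     16  O   ASN B   1       8.200   2.100   1.700  1.00  0.00           O
ATOM     17  CB  ASN B   1       6.600  -0.300   0.700  1.00  0.00           C
ATOM     18  CG  ASN B   1       6.000   0.900   0.100  1.00  0.00           C
ATOM     19  OD1 ASN B   1       6.200   2.050   0.450  1.00  0.00           O
ATOM     20  ND2 ASN B   1       5.800   0.900  -1.210  1.00  0.00           N
ATOM     21  N   GLY B   2       9.900   1.500   0.200  1.00  0.00           N
ATOM     22  CA  GLY B   2      10.700   2.600   0.500  1.00  0.00           C
ATOM     23  C   GLY B   2      12.100   2.300   0.000  1.00  0.00           C
ATOM     24  O   GLY B   2      12.500   1.200  -0.300  1.00  0.00           O
END
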
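MODEL        1
ATOM      1  N   ALA A   1      -1.500   1.000   0.000  1.00  0.00              
ATOM      2  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00              
ATOM      3  C   ALA A   1       1.500   1.000   0.000  1.00  0.00              
ATOM      4  O   ALA A   1       1.500   2.500   0.000  1.00  0.00              
ATOM      5  CB  ALA A   1       0.000  -1.500   0.000  1.00  0.00              
ATOM      6  N   ALA A   2      28.500   1.000   0.000  1.00  0.00              
ATOM      7  CA  ALA A   2      30.000   0.000   0.000  1.00  0.00              
ATOM      8  C   ALA A   2      31.500   1.000   0.000  1.00  0.00              
ATOM      9  O   ALA A   2      31.500   2.500   0.000  1.00  0.00              
ATOM     10  CB  ALA A   2      30.000  -1.500   0.000  1.00  0.00              
ATOM     11  N   ALA A   3      58.500   1.000   0.000  1.00  0.00              
ATOM     12  CA  ALA A   3      60.000   0.000   0.000  1.00  0.00              
ATOM     13  C   ALA A   3      61.500   1.000   0.000  1.00  0.00              
ATOM     14  O   ALA A   3      61.500   2.500   0.000  1.00  0.00              
ATOM     15  CB  ALA A   3      60.000  -1.500   0.000  1.00  0.00              
ATOM     16  N   ALA B   1      -1.500  81.000   0.000  1.00  0.00              
ATOM     17  CA  ALA B   1       0.000  80.000   0.000  1.00  0.00              
ATOM     18  C   ALA B   1       1.500  81.000   0.000  1.00  0.00              
ATOM     19  O   ALA B   1       1.500  82.500   0.000  1.00  0.00              
ATOM     20  CB  ALA B   1       0.000  78.500   0.000  1.00  0.00              
ATOM     21  N   ALA B   2       3.000   1.000   0.000  1.00  0.00              
ATOM     22  CA  ALA B   2       4.500   0.000   0.000  1.00  0.00              
ATOM     23  C   ALA B   2       6.000   1.000   0.000  1.00  0.00              
ATOM     24  O   ALA B   2       6.000   2.500   0.000  1.00  0.00              
ATOM     25  CB  ALA B   2       4.500  -1.500   0.000  1.00  0.00              
ATOM     26  N   ALA B   3      58.500  81.000   0.000  1.00  0.00              
ATOM     27  CA  ALA B   3      60.000  80.000   0.000  1.00  0.00              
ATOM     28  C   ALA B   3      61.500  81.000   0.000  1.00  0.00              
ATOM     29  O   ALA B   3      61.500  82.500   0.000  1.00  0.00              
ATOM     30  CB  ALA B   3      60.000  78.500   0.000  1.00  0.00              
ENDMDL
MODEL        2
ATOM      1  N   ALA A   1      -1.500   1.000   0.000  1.00  0.00              
ATOM      2  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00              
ATOM      3  C   ALA A   1       1.500   1.000   0.000  1.00  0.00              
ATOM      4  O   ALA A   1       1.500   2.500   0.000  1.00  0.00              
ATOM      5  CB  ALA A   1       0.000  -1.500   0.000  1.00  0.00              
ATOM      6  N   ALA A   2      28.500   1.000   0.000  1.00  0.00              
ATOM      7  CA  ALA A   2      30.000   0.000   0.000  1.00  0.00              
ATOM      8  C   ALA A   2      31.500   1.000   0.000  1.00  0.00              
ATOM      9  O   ALA A   2      31.500   2.500   0.000  1.00  0.00              
ATOM     10  CB  ALA A   2      30.000  -1.500   0.000  1.00  0.00              
ATOM     11  N   ALA A   3      58.500   1.000   0.000  1.00  0.00              
ATOM     12  CA  ALA A   3      60.000   0.000   0.000  1.00  0.00              
ATOM     13  C   ALA A   3      61.500   1.000   0.000  1.00  0.00              
ATOM     14  O   ALA A   3      61.500   2.500   0.000  1.00  0.00              
ATOM     15  CB  ALA A   3      60.000  -1.500   0.000  1.00  0.00              
ATOM     16  N   ALA B   1      -1.500  81.000   0.000  1.00  0.00              
ATOM     17  CA  ALA B   1       0.000  80.000   0.000  1.00  0.00              
ATOM     18  C   ALA B   1       1.500  81.000   0.000  1.00  0.00              
ATOM     19  O   ALA B   1       1.500  82.500   0.000  1.00  0.00              
ATOM     20  CB  ALA B   1       0.000  78.500   0.000  1.00  0.00              
ATOM     21  N   ALA B   2       6.500   1.000   0.000  1.00  0.00              
ATOM     22  CA  ALA B   2       8.000   0.000   0.000  1.00  0.00              
ATOM     23  C   ALA B   2       9.500   1.000   0.000  1.00  0.00              
ATOM     24  O   ALA B   2       9.500   2.500   0.000  1.00  0.00              
ATOM     25  CB  ALA B   2       8.000  -1.500   0.000  1.00  0.00              
ATOM     26  N   ALA B   3      58.500  81.000   0.000  1.00  0.00              
ATOM     27  CA  ALA B   3      60.000  80.000   0.000  1.00  0.00              
ATOM     28  C   ALA B   3      61.500  81.000   0.000  1.00  0.00              
ATOM     29  O   ALA B   3      61.500  82.500   0.000  1.00  0.00              
ATOM     30  CB  ALA B   3      60.000  78.500   0.000  1.00  0.00              
ENDMDL
END   
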
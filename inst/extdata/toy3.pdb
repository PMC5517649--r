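ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00 10.00           N
ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00 10.00           C
ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00 10.00           C
ATOM      4  N   ASP A   2       3.332   1.536   0.000  1.00 10.00           N
ATOM      5  CA AASP A   2       4.100   2.750   0.100  0.60 10.00           C
ATOM      6  CA BASP A   2       4.200   2.850   0.200  0.40 10.00           C
ATOM      7  C   ASP A   2       5.570   2.500   0.300  1.00 10.00           C
ATOM      8  N   GLY A   3       6.340   3.570   0.350  1.00 10.00           N
ATOM      9  CA  GLY A   3       7.790   3.480   0.450  1.00 10.00           C
ATOM     10  C   GLY A   3       8.370   4.880   0.500  1.00 10.00           C
TER
HETATM   11  O   HOH A 101       9.000   9.000   9.000  1.00 20.00           O
END
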
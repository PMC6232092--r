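REMARK synthetic alpha-helix-like coordinates for I/O and gridding tests
REMARK not derived from any PDB entry
ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 20.00           N
ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 20.00           C
ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00 20.00           C
ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00 20.00           O
ATOM      5  N   ALA A   2       3.332   1.536   0.109  1.00 20.00           N
ATOM      6  CA  ALA A   2       3.988   2.835   0.255  1.00 20.00           C
ATOM      7  C   ALA A   2       3.671   3.778   1.413  1.00 20.00           C
ATOM      8  O   ALA A   2       3.914   3.445   2.577  1.00 20.00           O
ATOM      9  N   ALA A   3       3.134   4.958   1.099  1.00 20.00           N
ATOM     10  CA  ALA A   3       2.772   5.962   2.092  1.00 20.00           C
ATOM     11  C   ALA A   3       1.439   5.659   2.766  1.00 20.00           C
ATOM     12  O   ALA A   3       1.272   5.868   3.970  1.00 20.00           O
ATOM     13  N   ALA B   4       0.478   5.170   1.986  1.00 20.00           N
ATOM     14  CA  ALA B   4      -0.846   4.821   2.487  1.00 20.00           C
ATOM     15  C   ALA B   4      -0.791   3.695   3.513  1.00 20.00           C
ATOM     16  O   ALA B   4      -1.597   3.642   4.442  1.00 20.00           O
ATOM     17  CB  ALA B   4      -1.780   4.424   1.349  1.00 20.00           C
ATOM     18  N   ALA B   5       0.169   2.785   3.366  1.00 20.00           N
ATOM     19  CA  ALA B   5       0.332   1.663   4.287  1.00 20.00           C
ATOM     20  SD  MET B   5       1.726   0.744   3.919  1.00 20.00           S
END
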
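HETATM    1  F1  UNL     1      -2.243  -0.282   0.961  1.00  0.00           F  
HETATM    2  C1  UNL     1      -1.071   0.356   0.762  1.00  0.00           C  
HETATM    3  F2  UNL     1      -0.481   0.448   1.983  1.00  0.00           F  
HETATM    4  F3  UNL     1      -1.339   1.613   0.361  1.00  0.00           F  
HETATM    5  C2  UNL     1      -0.161  -0.388  -0.192  1.00  0.00           C  
HETATM    6  O1  UNL     1       1.107   0.263  -0.448  1.00  0.00           O  
HETATM    7  C3  UNL     1       1.923   0.400   0.704  1.00  0.00           C  
HETATM    8  F4  UNL     1       3.191   0.567   0.254  1.00  0.00           F  
HETATM    9  C4  UNL     1      -0.943  -0.542  -1.478  1.00  0.00           C  
HETATM   10  F5  UNL     1      -2.068  -1.270  -1.292  1.00  0.00           F  
HETATM   11  F6  UNL     1      -0.210  -1.208  -2.404  1.00  0.00           F  
HETATM   12  F7  UNL     1      -1.302   0.639  -2.021  1.00  0.00           F  
CONECT    1    2
CONECT    2    3    4    5
CONECT    5    6    9
CONECT    6    7
CONECT    7    8
CONECT    9   10   11   12
END
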
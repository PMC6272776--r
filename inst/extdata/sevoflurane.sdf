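
     RDKit          3D

 12 11  0  0  0  0  0  0  0  0999 V2000
   -2.2425   -0.2825    0.9607 F   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0711    0.3559    0.7623 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.4808    0.4479    1.9829 F   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3388    1.6135    0.3614 F   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1614   -0.3875   -0.1919 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.1071    0.2632   -0.4479 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.9231    0.3997    0.7043 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.1910    0.5670    0.2544 F   0  0  0  0  0  0  0  0  0  0  0  0
   -0.9432   -0.5420   -1.4777 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0677   -1.2696   -1.2921 F   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2104   -1.2080   -2.4039 F   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3019    0.6387   -2.0205 F   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  2  4  1  0
  2  5  1  0
  5  6  1  0
  6  7  1  0
  7  8  1  0
  5  9  1  0
  9 10  1  0
  9 11  1  0
  9 12  1  0
M  END
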
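12
sevoflurane heavy atoms (synthetic conformer)
F -2.2425 -0.2825 0.9607
C -1.0711 0.3559 0.7623
F -0.4808 0.4479 1.9829
F -1.3388 1.6135 0.3614
C -0.1614 -0.3875 -0.1919
O 1.1071 0.2632 -0.4479
C 1.9231 0.3997 0.7043
F 3.1910 0.5670 0.2544
C -0.9432 -0.5420 -1.4777
F -2.0677 -1.2696 -1.2921
F -0.2104 -1.2080 -2.4039
F -1.3019 0.6387 -2.0205
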
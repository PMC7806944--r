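89J idealized
  abfekit: heavy atoms, idealized planar geometry

 16 17  0  0  0  0  0  0  0  0999 V2000
    0.0000    1.4000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2124    0.7000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2124   -0.7000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.2950   -1.3250    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0000   -1.4000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2124   -0.7000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2124    0.7000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4682    1.4250    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.4249   -1.4000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0
    3.7874   -0.9041    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.4942    1.4400    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.7066    0.7400    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.9190    1.4400    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.9190    2.8400    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.7066    3.5400    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.4942    2.8400    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  3  5  1  0
  5  6  2  0
  6  7  1  0
  7  1  2  0
  3  4  2  0
  2  8  1  0
  6  9  1  0
  9 10  1  0
  7 11  1  0
 11 12  2  0
 12 13  1  0
 13 14  2  0
 14 15  1  0
 15 16  2  0
 16 11  1  0
M  END
$$$$
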
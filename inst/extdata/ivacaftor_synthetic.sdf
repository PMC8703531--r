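ivacaftor_synthetic_idealized
     RDKit          3D

 29 31  0  0  0  0  0  0  0  0999 V2000
    0.3000   -1.8589    2.0435 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.0683   -2.3139    0.8197 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0959   -2.7657   -0.2506 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.8660   -3.5380    1.2326 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.9405   -1.1916    0.2984 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.3325   -1.3823    0.2500 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.2318   -0.4144   -0.2126 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.7131   -0.6988   -0.2320 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.0542   -2.0836    0.2851 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.2453   -0.6044   -1.6474 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.4487    0.2994    0.6388 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.6839    0.7950   -0.6419 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.3128    1.0253   -0.6110 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.4347    0.0453   -0.1455 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0493    0.2823   -0.1160 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6131    1.4230   -0.5080 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0911    2.4415   -0.9571 O   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0856    1.3418   -0.3449 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.7726    2.4307   -0.7142 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.1367    2.6139   -0.6653 N   0  0  0  0  0  0  0  0  0  0  0  0
   -4.9293    1.5528   -0.1753 C   0  0  0  0  0  0  0  0  0  0  0  0
   -6.3159    1.6916   -0.1069 C   0  0  0  0  0  0  0  0  0  0  0  0
   -7.1030    0.6473    0.3759 C   0  0  0  0  0  0  0  0  0  0  0  0
   -6.5095   -0.5424    0.7935 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.1270   -0.6931    0.7300 C   0  0  0  0  0  0  0  0  0  0  0  0
   -4.3425    0.3533    0.2466 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.8712    0.1955    0.1781 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.3586   -0.8529    0.5469 O   0  0  0  0  0  0  0  0  0  0  0  0
    4.4789    1.8014   -1.1105 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  2  4  1  0
  2  5  1  0
  5  6  2  0
  6  7  1  0
  7  8  1  0
  8  9  1  0
  8 10  1  0
  8 11  1  0
  7 12  2  0
 12 13  1  0
 13 14  2  0
 14 15  1  0
 15 16  1  0
 16 17  2  0
 16 18  1  0
 18 19  2  0
 19 20  1  0
 20 21  1  0
 21 22  2  0
 22 23  1  0
 23 24  2  0
 24 25  1  0
 25 26  2  0
 26 27  1  0
 27 28  2  0
 12 29  1  0
 14  5  1  0
 27 18  1  0
 26 21  1  0
M  END
$$$$
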
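# Minimal AMBER-functional-form parameter set covering the bundled
# amino-acid + water templates. Self-authored; r0/theta0 derive from
# the template geometries, force constants from element-class rules.

[options]
scee 1.2
scnb 2.0
coulomb 332.0637
cutoff 12.0

[types]
# name rmin2(A) eps(kcal/mol) mass(amu)
CT  1.9080 0.1094  12.011
C   1.9080 0.0860  12.011
CA  1.9080 0.0860  12.011
N   1.8240 0.1700  14.007
N2  1.8240 0.1700  14.007
N3  1.8750 0.1700  14.007
NA  1.8240 0.1700  14.007
NB  1.8240 0.1700  14.007
O   1.6612 0.2100  15.999
O2  1.6612 0.2100  15.999
OH  1.7210 0.2104  15.999
OW  1.7683 0.1520  15.999
S   2.0000 0.2500  32.060
SH  2.0000 0.2500  32.060
H   0.6000 0.0157   1.008
HC  1.4870 0.0157   1.008
HA  1.4590 0.0150   1.008
HO  0.2000 0.0001   1.008
HS  0.6000 0.0157   1.008
HW  0.2000 0.0001   1.008

[stretch]
# t1 t2 k(kcal/mol/A^2) r0(A)
C   CT  317.0 1.5229
C   N   480.0 1.3295
C   O   570.0 1.2308
C   O2  570.0 1.2500
CA  CA  469.0 1.3985
CA  CT  317.0 1.5050
CA  HA  340.0 1.0800
CA  N2  480.0 1.3300
CA  NA  480.0 1.3700
CA  NB  480.0 1.3700
CA  OH  320.0 1.3640
CT  CT  317.0 1.5263
CT  HC  340.0 1.0900
CT  N   337.0 1.4586
CT  N2  337.0 1.4630
CT  N3  337.0 1.4591
CT  OH  320.0 1.4100
CT  S   232.0 1.8000
CT  SH  232.0 1.8100
H   N   434.0 1.0100
H   N2  434.0 1.0100
H   N3  434.0 1.0100
H   NA  434.0 1.0100
HO  OH  553.0 0.9600
HS  SH  274.0 1.3400
HW  OW  553.0 0.9600

[bend]
# t1 t2 t3 k(kcal/mol/rad^2) theta0(deg)
C   CT  CT  63.0 110.247
C   CT  HC  50.0 109.032
C   CT  N   63.0 111.200
C   CT  N3  63.0 111.200
C   N   CT  63.0 121.833
C   N   H   50.0 119.336
CA  CA  CA  63.0 119.401
CA  CA  CT  63.0 122.786
CA  CA  HA  50.0 120.509
CA  CA  NA  63.0 113.710
CA  CA  NB  63.0 108.000
CA  CA  OH  63.0 120.000
CA  CT  CT  63.0 113.550
CA  CT  HC  50.0 108.550
CA  N2  CT  63.0 124.000
CA  N2  H   50.0 119.600
CA  NA  CA  63.0 108.500
CA  NA  H   50.0 125.750
CA  NB  CA  63.0 108.000
CA  OH  HO  50.0 109.000
CT  C   N   63.0 116.609
CT  C   O   63.0 120.491
CT  C   O2  63.0 118.591
CT  CA  NA  63.0 126.000
CT  CT  CT  63.0 110.371
CT  CT  HC  50.0 109.523
CT  CT  N   63.0 109.558
CT  CT  N2  63.0 111.500
CT  CT  N3  63.0 109.689
CT  CT  OH  63.0 109.396
CT  CT  S   63.0 112.700
CT  CT  SH  63.0 108.500
CT  N   CT  63.0 116.631
CT  N   H   50.0 118.900
CT  N2  H   50.0 118.000
CT  N3  CT  63.0 116.631
CT  N3  H   50.0 109.441
CT  OH  HO  50.0 109.000
CT  S   CT  63.0 100.200
CT  SH  HS  50.0  96.000
H   N   H   35.0 120.000
H   N2  H   35.0 120.000
H   N3  H   35.0 109.442
HA  CA  NA  50.0 125.000
HA  CA  NB  50.0 126.000
HC  CT  HC  35.0 108.642
HC  CT  N   50.0 108.701
HC  CT  N2  50.0 109.628
HC  CT  N3  50.0 108.772
HC  CT  OH  50.0 110.084
HC  CT  S   50.0 109.300
HC  CT  SH  50.0 111.171
HW  OW  HW  35.0 104.520
N   C   O   63.0 122.900
N2  CA  N2  63.0 120.000
NA  CA  NB  63.0 108.000
O2  C   O2  63.0 122.818

[torsion]
# t1 t2 t3 t4 Vn/2(kcal/mol) n gamma(deg); X = wildcard
X  CT  CT  X  0.1556 3   0.0
X  C   CT  X  0.0000 2   0.0
X  CA  CT  X  0.0000 2   0.0
X  CT  N   X  0.0000 2   0.0
X  CT  N3  X  0.1556 3   0.0
X  CT  N2  X  0.0000 3   0.0
X  CT  OH  X  0.1667 3   0.0
X  CT  S   X  0.3333 3   0.0
X  CT  SH  X  0.2500 3   0.0
X  C   N   X  2.5000 2 180.0
X  C   OH  X  1.8000 2 180.0
X  C   O2  X  1.4000 2 180.0
X  CA  CA  X  3.6250 2 180.0
X  CA  N2  X  2.4000 2 180.0
X  CA  NA  X  1.5000 2 180.0
X  CA  NB  X  2.4000 2 180.0
X  CA  OH  X  0.9000 2 180.0
X  C   CA  X  1.0000 2 180.0
X  CA  N   X  1.0000 2 180.0

[charges-in-fragment-db]
# partial charges live in fragments.txt
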
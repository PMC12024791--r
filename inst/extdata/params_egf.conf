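ligand = EGF
dusp_hill_squared = false
total_R = 1
total_Ras = 1
total_Raf = 1
total_MEK = 1
total_ERK = 1
total_NFB = 1
total_PFB = 1
k1R = 0.0083333333333333332
kd1R = 0.0083333333333333332
PtaseR = 1
k6R = 0.66666666666666663
K6 = 1
kd6 = 0.125
D6 = 1
GAP = 1
k5 = 0.16666666666666666
K5 = 1
kd5 = 0.0625
D5 = 1
KNFB = 0.050000000000000003
PtaseRaf = 1
kPFB = 0
KPFB = 0.01
k4 = 0.033333333333333333
K4 = 1
kd4 = 0.0083333333333333332
D4 = 1
PtaseMEK = 1
k2 = 0.033333333333333333
K2 = 1
kd2 = 0.0041666666666666666
D2 = 0.10000000000000001
k3F = 0.00047666666666666669
K3 = 0.01
K3R = 0.84999999999999998
kd3 = 9.5000000000000005e-05
D3 = 0.5
PtaseNFB = 1
k7 = 0.0016666666666666668
K7 = 0.10000000000000001
kd7 = 8.3333333333333331e-05
D7 = 0.10000000000000001
PtasePFB = 1
duspbasal = 1
duspind = 6
Kdusp = 0.10000000000000001
Tdusp = 5400
TDUSP = 5400
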
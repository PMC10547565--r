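instrument,sum_score,eap,se
OKS,0,-3.40,0.53
OKS,1,-3.01,0.49
OKS,2,-2.68,0.45
OKS,3,-2.39,0.42
OKS,4,-2.14,0.40
OKS,5,-1.93,0.39
OKS,6,-1.74,0.38
OKS,7,-1.56,0.37
OKS,8,-1.40,0.36
OKS,9,-1.24,0.36
OKS,10,-1.10,0.35
OKS,11,-0.96,0.35
OKS,12,-0.82,0.34
OKS,13,-0.69,0.34
OKS,14,-0.57,0.34
OKS,15,-0.44,0.34
OKS,16,-0.32,0.33
OKS,17,-0.20,0.33
OKS,18,-0.09,0.33
OKS,19,0.03,0.33
OKS,20,0.14,0.33
OKS,21,0.26,0.33
OKS,22,0.37,0.33
OKS,23,0.48,0.33
OKS,24,0.59,0.33
OKS,25,0.70,0.33
OKS,26,0.81,0.33
OKS,27,0.92,0.33
OKS,28,1.03,0.33
OKS,29,1.15,0.33
OKS,30,1.26,0.33
OKS,31,1.37,0.33
OKS,32,1.48,0.33
OKS,33,1.60,0.33
OKS,34,1.72,0.33
OKS,35,1.83,0.34
OKS,36,1.95,0.34
OKS,37,2.08,0.34
OKS,38,2.20,0.34
OKS,39,2.33,0.35
OKS,40,2.47,0.35
OKS,41,2.61,0.36
OKS,42,2.76,0.37
OKS,43,2.92,0.38
OKS,44,3.08,0.40
OKS,45,3.26,0.31
OKS,46,3.46,0.43
OKS,47,3.67,0.46
OKS,48,3.90,0.50
HAAS,0,-3.13,1.17
HAAS,1,-1.95,1.16
HAAS,2,-0.96,1.10
HAAS,3,-0.18,1.00
HAAS,4,0.47,1.00
HAAS,5,1.08,0.99
HAAS,6,1.60,0.97
HAAS,7,2.15,0.95
HAAS,8,2.65,0.94
HAAS,9,3.12,0.93
HAAS,10,3.60,0.91
HAAS,11,4.11,0.87
HAAS,12,4.62,0.81
HAAS,13,5.03,0.72
HAAS,14,5.28,0.63
HAAS,15,5.36,0.60
HAAS,16,5.49,0.51
HAAS,17,5.57,0.46
HAAS,18,5.63,0.42
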
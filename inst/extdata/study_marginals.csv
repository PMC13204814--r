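variable,mean,sd,min,max
ATR-L,0.445,0.087,0.331,0.601
ATR-R,0.480,0.087,0.365,0.654
CGC-L,0.417,0.067,0.305,0.517
CGC-R,0.404,0.060,0.319,0.530
CGH-L,0.355,0.082,0.228,0.456
CGH-R,0.335,0.081,0.219,0.491
CST-L,0.553,0.081,0.431,0.674
CST-R,0.586,0.107,0.386,0.747
Fmj,0.522,0.067,0.422,0.621
Fmn,0.457,0.074,0.367,0.575
IFOF-L,0.479,0.091,0.360,0.593
IFOF-R,0.447,0.069,0.352,0.531
ILF-L,0.467,0.090,0.346,0.607
ILF-R,0.464,0.105,0.351,0.792
SLF-L,0.465,0.091,0.336,0.596
SLF-R,0.463,0.089,0.338,0.621
UNC-L,0.379,0.080,0.257,0.487
UNC-R,0.369,0.073,0.275,0.481
IAF,10.303,0.718,8.594,11.328
age,29.54,8.5,20,43
education,14,3,9,19
SRT,463.54,35.49,408,518
CRT,433.37,47.14,357,555
SDSRT,78.58,17.59,44.04,114.78
SDCRT,85.81,22.75,45.24,138.71
SKWSRT,1.08,0.59,-0.36,2.10
SKWCRT,1.41,0.55,-0.41,2.41
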
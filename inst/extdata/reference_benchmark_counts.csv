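dataset,method,mode,n_gt,n_gti,n_s,n_tp,n_fn,n_fp,r_tp,r_tpi,r_tpb,r_fp,default_failure,note
A,F,D,155,56,1344,153,2,1191,0.99,1.00,0.98,0.89,TRUE,
A,F,M,155,56,138,133,22,5,0.86,0.93,0.82,0.04,FALSE,
A,3DMLS,D,155,56,219,117,38,102,0.76,0.73,0.77,0.47,FALSE,printed r_tp inconsistent with counts (117/155 -> 0.75)
A,3DMLS,M,155,56,130,114,41,16,0.74,0.66,0.78,0.12,FALSE,
A,ImageJ,M,155,56,91,54,101,37,0.35,0.34,0.35,0.41,FALSE,
A,ImageJ,S,155,56,96,54,95,36,0.39,0.36,0.40,0.38,FALSE,printed counts violate identities (54+95=149; 54+36=90); printed rates imply n_tp=60
B,F,D,246,162,298,204,42,94,0.83,0.83,0.82,0.32,FALSE,
B,3DMLS,D,246,162,202,167,79,35,0.68,0.69,0.67,0.17,FALSE,
B,3DMLS,M,246,162,162,130,116,32,0.53,0.57,0.45,0.20,FALSE,
B,ImageJ,M,246,162,313,159,87,154,0.65,0.69,0.57,0.49,FALSE,
B,ImageJ,S,246,162,122,60,186,62,0.24,0.17,0.38,0.51,FALSE,
C,F,D,60,34,2349,59,1,2290,0.98,1.00,0.96,0.98,TRUE,printed r_fp inconsistent with counts (2290/2349 -> 0.97)
C,F,M,60,34,69,56,4,13,0.93,0.97,0.89,0.19,FALSE,
C,3DMLS,D,60,34,51,30,30,21,0.50,0.50,0.50,0.41,FALSE,
C,3DMLS,M,60,34,53,30,30,23,0.50,0.50,0.50,0.43,FALSE,
C,ImageJ,M,60,34,52,40,20,12,0.67,0.59,0.77,0.23,FALSE,
C,ImageJ,S,60,34,59,35,25,24,0.58,0.50,0.69,0.41,FALSE,
D,F,D,58,35,567,32,26,535,0.55,0.54,0.57,0.94,TRUE,
D,F,M,58,35,120,22,36,98,0.38,0.43,0.30,0.82,FALSE,
D,F,R,58,35,76,33,25,43,0.57,0.54,0.61,0.57,FALSE,
D,ImageJ,M,58,35,41,27,31,14,0.47,0.31,0.70,0.34,FALSE,
D,ImageJ,S,58,35,37,29,29,8,0.50,0.40,0.65,0.22,FALSE,
D,ImageJ,R,58,35,39,28,30,11,0.48,0.34,0.70,0.28,FALSE,
D,ImageJ,R-S,58,35,37,29,29,8,0.50,0.37,0.70,0.22,FALSE,
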
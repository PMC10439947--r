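object_id,X1,X2,X3,X4,X5,X6,X7,X8,X9,X10,X11,X12,X13,X14,X15
1,39.82,17.15,33.87,2.27,30.51,5,1.46,0.65,9.87,38.58,8.67,100.25,2.6,4,3
2,50.26,15.25,34.26,2.58,86.36,3,2.86,0.95,16.54,50.21,18.52,130.25,2.06,2,2
3,54.36,21.36,28.35,2.32,90.28,2,2.36,0.83,22.57,58.57,20.06,132.52,2.12,2,3
4,58.79,29.86,11.56,3.08,97.27,2,2.83,0.95,29.85,68.56,26.58,186.52,1.32,1,2
5,35.28,19.82,22.58,2.39,35.06,5,1.55,0.7,10.24,35.67,13.65,90.42,2.65,3,4
6,49.85,14.26,29.65,2.06,48.36,4,1.64,0.68,12.34,45.62,10.15,88.67,2.31,3,3
7,75.66,26.87,17.26,3.26,95.55,2,2.68,0.86,26.57,63.27,23.56,176.53,1.38,1,2
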
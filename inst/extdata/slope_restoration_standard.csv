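index_id,name,kind,units,g1_lo,g1_hi,g2_lo,g2_hi,g3_lo,g3_hi,g4_lo,g4_hi,g5_lo,g5_hi
X1,Shearing strength of root-soil composite,quantitative,kPa,60,100,50,60,40,50,30,40,0,30
X2,Permeability,quantitative,mm h-1,30,40,20,30,10,20,5,10,0,5
X3,Soil erosion intensity,quantitative,g cm-3 a-1,0,5,5,15,15,25,25,35,35,45
X4,Root weight density,quantitative,kg m-3,3.5,4.5,2.5,3.5,1.5,2.5,0.5,1.5,0,0.5
X5,Vegetation coverage,quantitative,%,95,100,80,95,65,80,40,65,0,40
X6,Drought resistance of vegetation,qualitative,,1,,2,,3,,4,,5,
X7,Shannon-Wiener diversity index,quantitative,,3.0,3.5,2.5,3.0,2.0,2.5,1.5,2.0,0,1.5
X8,Pielou evenness index,quantitative,,1.0,1.2,0.8,1.0,0.6,0.8,0.4,0.6,0,0.4
X9,Organic matter,quantitative,g kg-1,30,40,20,30,10,20,5,10,0,5
X10,Available N,quantitative,mg kg-1,75,100,55,75,35,55,15,35,0,15
X11,Available P,quantitative,mg kg-1,30,40,20,30,10,20,5,10,0,5
X12,Available K,quantitative,mg kg-1,205,260,150,205,95,150,40,95,0,40
X13,Soil bulk density,quantitative,g cm-3,0,1.5,1.5,2.0,2.0,2.5,2.5,3.0,3.0,3.5
X14,Landscape coordination,qualitative,,1,,2,,3,,4,,5,
X15,Landscape capacity for visitors,qualitative,,1,,2,,3,,4,,5,
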
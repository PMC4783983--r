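label,scope,static_mean,static_sd,dynamic,mean_persistency,class1,class1_count,class1_persistency,class2,class2_count,class2_persistency,class3,class3_count,class3_persistency
P180/S180,intra-protein,239.2,5.3,540,44.3,M-M,217,66.7,M-S,215,25.7,S-S,108,36.1
P300/S180,intra-protein,232.9,6.1,712,30.7,M-M,262,49.3,M-S,294,17.7,S-S,156,23.9
P180/S300,intra-protein,229.0,6.8,1121,18.8,M-M,297,42.0,M-S,515,10.1,S-S,309,11.2
P300/S300,intra-protein,215.6,7.8,1987,9.4,M-M,469,23.5,M-S,979,4.5,S-S,539,5.8
P180/S180,protein-solvent,391.3,11.7,8475,4.62,M-solv,627,8.34,S-solv,7848,4.32,,,
P300/S180,protein-solvent,377.2,11.7,17960,2.10,M-solv,1435,3.34,S-solv,16525,1.99,,,
P180/S300,protein-solvent,363.8,14.3,743864,0.05,M-solv,74319,0.07,S-solv,669545,0.05,,,
P300/S300,protein-solvent,330.4,14.8,1034810,0.03,M-solv,120772,0.03,S-solv,914038,0.03,,,
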
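label,rmsd,rmsd_sd,sasa,sasa_sd,nnc,nnc_sd,rg,rg_sd,sse_helix,sse_helix_sd,sse_sheet,sse_sheet_sd,sse_turn,sse_turn_sd
P180/S180,0.62,0.03,10574,96,137766,474,16.6,0.3,69.9,1.6,62.0,2.4,42.7,3.5
P300/S180,0.68,0.04,10679,136,136887,620,16.6,0.3,69.6,1.6,61.4,2.7,40.0,3.6
P180/S300,0.90,0.08,10767,162,136502,756,16.7,0.5,69.7,1.7,59.2,3.7,40.0,4.7
P300/S300,1.24,0.18,10972,192,134821,947,16.7,0.5,69.6,1.9,57.7,5.1,32.4,5.0
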
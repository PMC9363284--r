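device,protocol,ctdi_mgy,uniformity_hu,cnr,cnrd,lcv,air_hu,ptfe_hu,pmma_hu,pvc_hu,air_err_pct,ptfe_err_pct,pmma_err_pct,pvc_err_pct,mtf10,mtf50
dental_cbct,ULD,0.5,67,7.2,10.2,0.78,-964.6,984.8,154.5,-88.7,3.5,0.6,28.7,26.1,1.33,0.65
extremity_cbct,ULD,0.6,125,4.5,5.8,0.48,-971.3,1429.5,29.9,9.6,2.9,44.4,75.1,108.0,0.93,0.46
mdct,ULD,0.5,7,19.1,25.3,1.14,-1022.9,1149.5,134.1,-123.6,2.3,16.1,11.8,2.6,0.52,0.27
dental_cbct,LD,1.3,56,18,15.9,1.43,-986.8,968.7,118.1,-114.2,1.3,2.2,1.6,4.9,1.34,0.66
extremity_cbct,LD,1.4,100,11.4,9.6,1.18,-959.2,1377.3,89.9,-129.8,4.1,39.1,25.0,8.1,0.89,0.48
mdct,LD,1.4,6,26.4,22,2.03,-1023.7,1155.4,138.7,-122.1,2.4,16.7,15.6,1.8,0.53,0.29
dental_cbct,DF,3.7,51,26,13.5,2.51,-999.3,940.6,93.7,-137.5,0.1,5.0,26.3,14.6,1.46,0.69
extremity_cbct,DF,3.9,88,12.2,9.8,1.20,-973.6,829.5,61.4,-155.3,2.6,16.2,48.8,29.4,1.00,0.40
mdct,DF,7,6,40.4,15.2,3.41,-1022.8,1113.9,151.7,-94.6,2.3,12.5,26.4,21.2,0.48,0.28
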
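fio2,pao2,paco2,f_r,q,v_tid,v_ds,chb,ph,t,fetco2
0.3,97.5,23.1,12,5.5,0.5,0.15,140,7.4,37,0.03
0.4,119.6,22.7,12,5.5,0.5,0.15,140,7.4,37,0.03
0.5,150.2,23.8,12,5.5,0.5,0.15,140,7.4,37,0.03
0.6,207.2,23.8,12,5.5,0.5,0.15,140,7.4,37,0.03
0.8,333.5,24.4,12,5.5,0.5,0.15,140,7.4,37,0.03
1,488.9,24.3,12,5.5,0.5,0.15,140,7.4,37,0.03
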
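model,image_set,dsc,mda_mm,hd95_mm,pvd_pct,sdsc,rapl_mm_per_cc
t1_model,T1,0.882,1.573,6.171,-8.516,0.844,12.18
multi_seq,T1,0.881,1.637,7.078,-8.373,0.846,11.2
t2_model,T2,0.860,2.128,8.542,-10.71,0.777,14.25
multi_seq,T2,0.867,1.942,7.777,-9.535,0.785,13.11
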
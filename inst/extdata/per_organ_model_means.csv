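organ,model,dsc,mda_mm,hd95_mm,pvd_pct,sdsc,rapl_mm_per_cc
aorta,t1_model,0.96,0.5,1.62,-2.15,0.99,0.13
aorta,t2_model,0.91,1.05,2.64,-8.95,0.89,5
aorta,multi_seq,0.94,0.75,2.11,-5.71,0.95,2.31
large_bowel,t1_model,0.85,3.8,18.97,0.27,0.73,9.54
large_bowel,t2_model,0.86,2.85,14.87,-4.51,0.77,7.9
large_bowel,multi_seq,0.85,3.85,23.68,1.73,0.76,7.54
small_bowel,t1_model,0.85,2.38,9.39,-7.77,0.74,11.54
small_bowel,t2_model,0.84,3.42,19.52,-6.06,0.68,10.92
small_bowel,multi_seq,0.84,2.81,14.51,-11.8,0.71,12.07
duodenum,t1_model,0.77,2.76,12.68,-18.8,0.72,22.34
duodenum,t2_model,0.73,3.01,12.69,-13.8,0.64,21.65
duodenum,multi_seq,0.75,2.92,12.68,-13.5,0.68,21.79
esophagus,t1_model,0.7,2.26,8.87,-36.3,0.7,56.79
esophagus,t2_model,0.66,4,13.63,-39.4,0.62,67.31
esophagus,multi_seq,0.71,2.8,10.02,-31.2,0.7,54.16
kidney_l,t1_model,0.97,0.51,1.62,-1.9,0.98,0.96
kidney_l,t2_model,0.95,0.9,2.92,-0.83,0.91,2.66
kidney_l,multi_seq,0.96,0.69,2.12,-2.91,0.95,1.75
kidney_r,t1_model,0.97,0.55,1.69,-0.06,0.97,1.35
kidney_r,t2_model,0.95,0.84,2.6,-2.95,0.92,2.45
kidney_r,multi_seq,0.96,0.71,2.1,-2.64,0.94,1.85
liver,t1_model,0.98,0.99,2.93,-1.64,0.91,0.139
liver,t2_model,0.96,1.63,5.64,-3.74,0.79,2.62
liver,multi_seq,0.97,1.24,3.92,-2.22,0.86,1.92
pancreas,t1_model,0.82,1.92,6.8,-16,0.73,19.3
pancreas,t2_model,0.77,3.97,16.61,-21.7,0.63,22.8
pancreas,multi_seq,0.81,2.01,6.57,-14.8,0.68,18.24
spinal_cord,t1_model,0.8,1.2,3.01,-12,0.87,16.54
spinal_cord,t2_model,0.8,1.23,3.03,-19.7,0.82,20.86
spinal_cord,multi_seq,0.8,1.21,3.18,-17.8,0.85,18.74
spleen,t1_model,0.98,0.57,1.8,-1.97,0.97,0.721
spleen,t2_model,0.96,1.01,3.17,-2.73,0.9,1.99
spleen,multi_seq,0.97,0.97,3.86,-1.22,0.93,1.26
stomach,t1_model,0.93,1.44,4.66,-3.95,0.81,5.45
stomach,t2_model,0.92,1.62,5.19,-4.21,0.76,4.85
stomach,multi_seq,0.93,1.5,4.66,-5.37,0.79,5.38
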
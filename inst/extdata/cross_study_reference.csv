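day,total_alveoli_millions_histology,total_alveoli_millions_tomography,alveolar_volume_1e5um3_histology,alveolar_volume_1e5um3_tomography,acini_per_lung_tomography,quintile_low_ul,quintile_high_ul
4,0.823,0.64,5.91,4.98,18260,0.0035,0.095
10,3.538,1.23,2.49,3.34,14359,0.0071,0.11
21,14.303,2.65,1.34,3.07,11203,0.018,0.26
60,19.297,3.01,2.93,8.12,4277,0.33,1.3
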
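condition_label,dose,batch,well_order,raman_percent,reference_percent
control,0,1,1,85,82
0.05 uM,0.05,1,2,81,78
0.1 uM,0.1,1,3,73,69
0.5 uM,0.5,1,4,64,59
1 uM,1,1,5,63,47
control (end),0,1,6,91,85
control,0,2,1,99,99
0.05 uM,0.05,2,2,78,70
0.1 uM,0.1,2,3,69,59
0.5 uM,0.5,2,4,36,32
1 uM,1,2,5,22,13
control (end),0,2,6,97,95
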
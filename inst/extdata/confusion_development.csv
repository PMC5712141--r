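# Development-group per-patient confusion counts (summed over trials)
patient_id,tp,fn,fp
1,4,2,1
4,1,0,0
5,1,0,0
7,2,1,1
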
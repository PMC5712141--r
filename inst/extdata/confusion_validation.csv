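# Validation-group per-patient confusion counts (summed over trials)
patient_id,tp,fn,fp
2,2,1,1
3,3,0,0
6,5,2,0
8,3,0,1
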
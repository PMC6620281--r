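comparison,threshold,tp,fp,tn,fn
F0 vs F1-F3,1.34,21,3,4,2
F0-1 vs F2&F3,1.43,11,6,12,1
F1 vs F2&F3,1.48,10,3,8,2
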
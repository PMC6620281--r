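group,steatosis,lobular_inflammation,ballooning
SS,1.3,1.0,1.3
NASH,2.5,2.4,1.5
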
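C1Oc2ccc(cc2O1)-c1cc(n[nH]1)-c1cccc(Br)c1	anle138b
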
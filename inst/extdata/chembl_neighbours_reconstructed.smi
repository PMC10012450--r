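Oc1ccccc1-c1cc([nH]n1)-c1ccc2OCCOc2c1	CHEMBL1567097_reconstructed
COc1cccc(-c2cc(n[nH]2)-c2cccc(Br)c2)c1O	CHEMBL1370387_reconstructed
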
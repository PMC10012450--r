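anle138b.smi
    SMILES of anle138b, 3-(1,3-benzodioxol-5-yl)-5-(3-bromophenyl)-1H-pyrazole.

chembl_neighbours_reconstructed.smi
    Reconstructed structures of the two experimental drugs most similar to
    anle138b in public bioactivity data. These were NOT downloaded from
    ChEMBL: they were transcribed from their published structural
    descriptions relative to anle138b (CHEMBL1567097: the meta-bromine
    replaced by an ortho-hydroxyl and the dioxole ring extended to a
    six-membered dioxine; CHEMBL1370387: the dioxole ring opened to an
    ortho-hydroxyl plus meta-methyl-ether). The reconstructions reproduce
    the published ECFP4/2048 Tanimoto similarities to anle138b (0.50 and
    0.45) under an independent fingerprint implementation.
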
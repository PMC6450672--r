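>tau187 truncated human 2N4R tau, residues 255-441, C291S single-cysteine variant
NVKSKIGSTENLKHQPGGGKVQIINKKLDLSNVQSKSGSKDNIKHVPGGGSVQIVYKPVD
LSKVTSKCGSLGNIHHKPGGGQVEVKSEKLDFKDRVQSKIGSLDNITHVPGGGNKKIETH
KLTFRENAKAKTDHGAEIVYKSPVVSGDTSPRHLSNVSSTGSIDMVDSPQLATLADEVSA
SLAKQGL
>tau187His tau187 with synthetic generic N-terminal His-tag (tag sequence is a placeholder consistent with the 207-residue construct length)
MGSSHHHHHHSSGLVPRGSHNVKSKIGSTENLKHQPGGGKVQIINKKLDLSNVQSKSGSK
DNIKHVPGGGSVQIVYKPVDLSKVTSKCGSLGNIHHKPGGGQVEVKSEKLDFKDRVQSKI
GSLDNITHVPGGGNKKIETHKLTFRENAKAKTDHGAEIVYKSPVVSGDTSPRHLSNVSST
GSIDMVDSPQLATLADEVSASLAKQGL
>tau114 truncated human 2N4R tau, residues 255-368, C291S variant
NVKSKIGSTENLKHQPGGGKVQIINKKLDLSNVQSKSGSKDNIKHVPGGGSVQIVYKPVD
LSKVTSKCGSLGNIHHKPGGGQVEVKSEKLDFKDRVQSKIGSLDNITHVPGGGN
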
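protein1,residue1,protein2,residue2
CSN4,200,RBX1,105
CSN2,157,CUL2,489
CSN2,263,CUL2,462
CSN2,225,CUL2,462
CSN2,64,CUL2,404
CUL2,382,WHB,720
CUL2,382,WHB,677
CUL2,433,WHB,677
CUL2,382,NEDD8,33
CUL2,433,NEDD8,6
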
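compound_id,smiles,library_tag
EX01,c1ccc2c(c1)ncnc2N,demo
EX02,Nc1ncnc2c1cccc2O,demo
EX03,c1ccc(cc1)-c1ccsc1,demo
EX04,NCCNCCO,demo
EX05,OCC1OC(O)C(O)C(O)C1O,demo
EX06,c1ccc2ccccc2c1,demo
EX07,CC(=O)Nc1ccc(O)cc1,demo
EX08,CCN(CC)CCNC(=O)c1ccc(N)cc1,demo
EX09,Cn1cnc2c1c(=O)n(C)c(=O)n2C,demo
EX10,OC(=O)c1ccccc1O,demo
EX11,NC(=O)c1ccc[nH]1,demo
EX12,C1CCNCC1,demo
EX13,c1ccc(cc1)S(=O)(=O)N,demo
EX14,CC(C)Cc1ccc(cc1)C(C)C(=O)O,demo
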
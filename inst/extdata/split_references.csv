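"id","smiles"
"ref1","CCc1ccccc1CCNC(CCCCC)CCc1ccccc1"
"ref2","CCCCCS(=O)(=O)Nc1ccc(cc1)C(=O)NCCc1ccsc1"
"ref3","COc1ccc(OCCCCC)cc1CCOCCOc1ccccc1"
"ref4","CCCCCC(=O)Nc1ccncc1CCNC(=O)c1ccccc1"
"ref5","CN1CCN(CC1)CCCCCCCNC(=O)c1ccncc1"
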
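"id","smiles","cluster"
"fix01","OC1COC(O)C1O","singleton"
"fix02","CCc1ccccc1CCNC(CCCC)CCc1ccccc1","arylamine"
"fix03","OCCOCCOCCO","singleton"
"fix04","CCc1ccccc1CCNC(C)CCc1ccccc1","arylamine"
"fix05","CC(=O)NCCOCCCN1CCOCC1","morpholine_hybrid"
"fix06","Clc1ccc(Cl)cc1CCNCCCCCc1ccc(F)cc1","dichloroaryl"
"fix07","CC(O)C(O)C(O)C","singleton"
"fix08","CCC(=O)Nc1ccncc1CCNC(=O)c1ccccc1","pyridyl_amide"
"fix09","CCCOC(=O)c1ccsc1CCOC(=O)CCc1ccccc1","thienyl_ester"
"fix10","FC(F)(F)C(F)(F)F","singleton"
"fix11","CS(=O)(=O)Nc1ccc(cc1)C(=O)NCCOCCCN1CCOCC1","morpholine_hybrid"
"fix12","Clc1ccc(Cl)cc1CCNCCCc1ccc(F)cc1","dichloroaryl"
"fix13","SCC(=O)NC","singleton"
"fix14","OC(=O)CCC(=O)O","singleton"
"fix15","CC#CC#CC","singleton"
"fix16","COc1ccc(OCC)cc1CCOCCOc1ccccc1","diaryl_ether"
"fix17","CCCS(=O)(=O)Nc1ccc(cc1)C(=O)NCCc1ccsc1","sulfonamide"
"fix18","COc1ccc(OC)cc1CCOCCOc1ccccc1","diaryl_ether"
"fix19","CCCC(=O)Nc1ccncc1CCNC(=O)c1ccccc1","pyridyl_amide"
"fix20","OC1CCOC1","singleton"
"fix21","NC(=O)C(N)CC(=O)O","singleton"
"fix22","NCCCCN","singleton"
"fix23","OC(=O)CC1CCCCC1CCCOCC1CCCCC1","cyclohexyl_acid"
"fix24","NC1CC1","singleton"
"fix25","O=S(=O)(O)CCO","singleton"
"fix26","CN(C)C(=O)N(C)C","singleton"
"fix27","CSCCSC","singleton"
"fix28","NC(=O)NCC(=O)N","singleton"
"fix29","CNC(=O)OC","singleton"
"fix30","CCCCCOC(=O)c1ccsc1CCOC(=O)CCc1ccccc1","thienyl_ester"
"fix31","CCc1ccccc1CCNC(CCC)CCc1ccccc1","arylamine"
"fix32","CCS(=O)(=O)Nc1ccc(cc1)C(=O)NCCc1ccsc1","sulfonamide"
"fix33","OCC1CO1","singleton"
"fix34","CN1CCN(CC1)CCCCNC(=O)c1ccncc1","piperazine"
"fix35","CN1CCN(CC1)CCCCCNC(=O)c1ccncc1","piperazine"
"fix36","CCC(=O)NCCOCCCN1CCOCC1","morpholine_hybrid"
"fix37","CNC(=O)NC(=O)NC","singleton"
"fix38","OC(=O)CCC1CCCCC1CCCOCC1CCCCC1","cyclohexyl_acid"
"fix39","COc1ccc(OCCCC)cc1CCOCCOc1ccccc1","diaryl_ether"
"fix40","OCc1coc(CO)c1","singleton"
"fix41","OC(=O)CCCCC1CCCCC1CCCOCC1CCCCC1","cyclohexyl_acid"
"fix42","CCCCS(=O)(=O)Nc1ccc(cc1)C(=O)NCCc1ccsc1","sulfonamide"
"fix43","Clc1ccc(Cl)cc1CCNCCCCCCc1ccc(F)cc1","dichloroaryl"
"fix44","Clc1ccc(Cl)cc1CCNCCCCc1ccc(F)cc1","dichloroaryl"
"fix45","C1CC1C1CC1","singleton"
"fix46","CN1CCN(CC1)CCCNC(=O)c1ccncc1","piperazine"
"fix47","CCCCOC(=O)c1ccsc1CCOC(=O)CCc1ccccc1","thienyl_ester"
"fix48","CC(C)(O)C(C)(C)O","singleton"
"fix49","NCCSCCN","singleton"
"fix50","CCc1ccccc1CCNC(CC)CCc1ccccc1","arylamine"
"fix51","CC(=O)Nc1ccncc1CCNC(=O)c1ccccc1","pyridyl_amide"
"fix52","CCCCC(=O)Nc1ccncc1CCNC(=O)c1ccccc1","pyridyl_amide"
"fix53","COc1ccc(OCCC)cc1CCOCCOc1ccccc1","diaryl_ether"
"fix54","CCOP(=O)(OCC)OCC","singleton"
"fix55","CN1CCN(CC1)CCCCCCNC(=O)c1ccncc1","piperazine"
"fix56","OC(=O)CCCC1CCCCC1CCCOCC1CCCCC1","cyclohexyl_acid"
"fix57","CCOC(=O)c1ccsc1CCOC(=O)CCc1ccccc1","thienyl_ester"
"fix58","NC(CO)CO","singleton"
"fix59","OCC(O)C(O)C(O)C(O)CO","singleton"
"fix60","OCC=CCO","singleton"
"fix61","COCOCOC","singleton"
"fix62","CS(=O)(=O)Nc1ccc(cc1)C(=O)NCCc1ccsc1","sulfonamide"
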
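"reaction_smiles","yield"
"CC(CN)COC.Nc1ccccc1Cl>>FC(c1cocc1)(F)F",56.5021810621914
"Oc1ncccc1C(F)(F)F.CCNC(=O)C>>ClC1CCCCC1",83.012647858715
"COC1CCCCC1.Brc1cccnc1F>>CCCC(F)(F)F",66.2165242586746
"Cc1ccccc1Br.CCOCB(O)O>>N#Cc1cccnc1Br",52.9258075212859
"CCC1COCC1.Oc1cccc(c1)Br.BrC1CCCCC1.CCOCB(O)O>>N#CC1CCCC1",65.796731580579
"CCC1CCCC1S.CCC1COCC1.CCC1CCCCC1>>NCc1ccccc1S",40.46649777087
"FC(c1cocc1)(F)F.CCOCBr.ClC1CCCCC1.Oc1ncccc1C(F)(F)F>>CCC1CCCC1C",75.7323805127715
"Nc1ccccc1Cl.c1ccccc1.CCOCB(O)O.CCC1CCCC1C>>OB(c1ccccc1)O",41.7343319054969
"Cc1ccccc1Br.Oc1ncccc1C(F)(F)F>>CCC1CCCC1C",73.9091554575547
"Oc1cccc(c1)Br.CCOCBr.FCC(B(O)O)C.C=CC1COCC1>>CC(Cl)C",45.3307029477601
"CCOCC#N.CCOCC.CCNC(=O)C(=O)O>>CCNC(=O)B(O)O",56.7896399225795
"COc1cccc(c1)N.CC(CN)COC.OC1CCCCC1>>OC1CCCCC1",68.2491366443665
"CCNC(=O)C(=O)O.OC(=O)N1CCCC1>>COc1cccc(c1)N",68.1173392907725
"COC1CCCCC1.Nc1ccccc1C(F)(F)F.NCc1ccccc1O>>CCCC(F)(F)F",60.7480911483703
"CCOCBr.BrC1COCC1>>BrC1COCC1",56.8998586475661
"ClC1CCCCC1.SN1CCCC1.OC1CCCCC1>>Cc1cscc1",26.9169921018328
"OB(C1CCCCC1)O.N#Cc1cocc1>>Cc1cscc1",49.683916688607
"Sc1ccccc1Br.NCc1cocc1.Nc1ccccc1Cl>>CCOCBr",64.9744000295385
"c1ccccc1.CCCC(F)(F)F.Oc1cccc(c1)Br.FC(C1CCCCC1)(F)F>>Cc1cscc1",34.2006627141156
"FC(C1CCCCC1)(F)F.CC(C(=O)O)CC=C.SN1CCCC1.CCOCC#N>>CCOCB(O)O",60.5834209363107
"Nc1ccccc1C(F)(F)F.NCc1cocc1>>NCc1cscc1",66.8320755380978
"Cc1cscc1.NCc1ccccc1S.FCC(B(O)O)C.CCC1CCCC1S>>CCOCC#N",58.2693084202333
"Nc1ccccc1C(F)(F)F.FC(c1cocc1)(F)F.CCNC(=O)B(O)O>>COc1cccnc1Br",81.5603570018931
"CCNC=O.CC(Cl)C.CCOCBr.Brc1cocc1>>NCc1cocc1",38.4502063789748
"OC(=O)c1cocc1.Cc1cscc1.FC(c1ccccc1)(F)F>>Nc1ccccc1Cl",53.3219052857735
"Oc1cocc1.Oc1ncccc1C(F)(F)F>>Oc1ncccc1C(F)(F)F",80.5739472154007
"N#CC1CCCC1.CCOCC.CCNC(=O)F.CCC1CCCC1S>>COC1CCCCC1",54.167649065624
"Brc1cccnc1F.BrC1COCC1.C=CC1COCC1>>ClC1CCCCC1",63.7331027439806
"CCOCC.FC(c1ccccc1)(F)F.SN1CCCC1>>CC(Cl)C",37.409645768172
"NCc1ccccc1O.OC(=O)N1CCCC1.Cc1ccccc1Br>>Nc1ccccc1Cl",47.4137708828891
"Oc1cocc1.Sc1ccccc1Br.CCC1CCCC1C>>Nc1ccccc1Cl",31.5324124877912
"OB(c1cocc1)O.N#Cc1cccnc1Br>>COc1cccc(c1)N",54.2655932540769
"NCc1ccccc1O.CC(C(=O)O)CC=C.N#Cc1cocc1>>Cc1ccccc1Br",43.3465439515807
"CCC1CCCCC1.CCOCB(O)O.FC(c1cocc1)(F)F.CC(C(=O)O)CC=C>>OB(c1ccccc1)O",52.7578031983478
"C=CC1COCC1.CCNC(=O)C(=O)O>>Fc1ccccn1",45.1888150808457
"OC(=O)N1CCCC1.CCNC(=O)B(O)O>>Fc1ccccn1",54.4281044479839
"C=CC1COCC1.N#Cc1cccnc1Br.Brc1cccnc1F.COC1CCCCC1>>Cc1cscc1",36.5019559730495
"CCC1CCCC1C.OB(c1cocc1)O.CCC1CCCC1S>>FC(c1cocc1)(F)F",51.67020228696
"COC1CCCCC1.CCNC=O.c1ccccc1>>Fc1ccccn1",24.7080615643046
"Brc1cocc1.CCCCl.BrC1COCC1.CCOCBr>>COc1cccnc1Br",27.0172051756592
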
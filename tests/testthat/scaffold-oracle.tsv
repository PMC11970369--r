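Cc1ccccc1	c1ccccc1	UHOVQNZJYSORNB
CC(=O)c1ccccc1	c1ccccc1	UHOVQNZJYSORNB
O=C1CCCC1	O=C1CCCC1	BGTOWKSIORTVQH
c1ccccc1C(=O)Nc1ccccc1	O=C(Nc1ccccc1)c1ccccc1	ZVSKZLHKADLHSD
CN1CCC[C@H]1c1cccnc1	c1cncc([C@@H]2CCCN2)c1	MYKUKUCHPMASKF
COc1cc2c(cc1O)CC1(O)c3cc4OCOc4cc3CC21	c1ccc2c(c1)CC1c3cc4c(cc3CC21)OCO4	JXGHNZNTKHGSOB
O=S(=O)(c1ccccc1)NCC	c1ccccc1	UHOVQNZJYSORNB
CC1=CC(=O)C=CC1=O	O=C1C=CC(=O)C=C1	AZQWKYJCGOJGHM
c1ccc2c(c1)ccc1ccccc21	c1ccc2c(c1)ccc1ccccc12	YNPNZTXNASCQKK
OC(=O)C1CCCN1	C1CCNC1	RWRDLPDLKQPQOW
C1CCCCC1=NC	N=C1CCCCC1	NNGAQKAUYDTUQR
c1ccccc1OCCN1CCOCC1	c1ccc(OCCN2CCOCC2)cc1	FDMDXNDAQKLGBA
CC(C)Cc1ccc(cc1)C(C)C(=O)O	c1ccccc1	UHOVQNZJYSORNB
OCC1OC(O)C(O)C(O)C1O	C1CCOCC1	DHXVGJBLRPWPCS
CC12CCC3c4ccc(O)cc4CCC3C1CCC2O	c1ccc2c(c1)CCC1C2CCC2CCCC21	GBGFUQOSVTZLFA
Oc1ccc(cc1)/C=C/c1cc(O)cc(O)c1	C(=C/c1ccccc1)\c1ccccc1	PJANXHGTPQOBST
CN1C=NC2=C1C(=O)N(C)C(=O)N2C	O=c1[nH]c(=O)c2[nH]cnc2[nH]1	LRFVTYWOQMYALW
c1ccc(-c2ccco2)cc1	c1ccc(-c2ccco2)cc1	GCXNJAXHHFZVIM
O=c1cc(-c2ccccc2)oc2ccccc12	O=c1cc(-c2ccccc2)oc2ccccc12	VHBFFQKBGNRLFZ
CC(=O)Oc1ccccc1C(=O)O	c1ccccc1	UHOVQNZJYSORNB
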
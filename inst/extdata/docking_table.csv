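receptor,ligand,formula,pubchem_cid,affinity_kcal_mol
CCL5,Ginsenoside Re,C48H82O18,441921,-10.0
CCL5,Asiaticoside,C48H78O19,24721205,-9.7
CCL5,Ergotamine,C33H35N5O5,8223,-9.6
CCL5,Neferine,C38H44N2O6,159654,-9.6
CCL5,Polyphyllin II,C44H70O16,46200821,-9.5
CCL5,Dioscin,C45H72O16,119245,-9.4
CCL5,Raddeanin A,C47H76O16,174742,-9.3
CCL5,Berbamine,C37H40N2O6,275182,-9.2
CCL5,Ginsenoside Rg1,C42H72O14,441923,-9.1
CCL5,Tubeimoside I,C63H98O29,51346132,-9.1
CXCL10,Alpha-Crocin,C44H64O24,5281233,-9.5
CXCL10,Polyphyllin II,C44H70O16,46200821,-9.2
CXCL10,Dioscin,C45H72O16,119245,-9.0
CXCL10,Digoxin,C41H64O14,2724385,-9.0
CXCL10,Ergotamine,C33H35N5O5,8223,-8.9
CXCL10,Saikosaponin A,C42H68O13,167928,-8.8
CXCL10,Raddeanin A,C47H76O16,174742,-8.8
CXCL10,Polyphyllin VI,C39H62O13,10417550,-8.7
CXCL10,Asiaticoside,C48H78O19,24721205,-8.6
CXCL10,Jujuboside A,C58H94O26,51346169,-8.6
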
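species	specimen	acc_18S	acc_28S	acc_16S	acc_COI
P_milaschewitchii	ZSM_Mol_20071381	-	JQ410926	JQ410925	JQ410897
P_milaschewitchii	ZSM_Mol_20080054	HQ168435	JF828043	HQ168422	-
P_milaschewitchii	ZSM_Mol_20080055	-	-	JQ410927	-
P_milaschewitchii	ZSM_Mol_20080925	-	-	JQ410928	HQ168459
P_milaschewitchii	ZSM_Mol_20080953	KC984282	-	JQ410929	JQ410898
P_brasilensis	SI-CBC2010KJ01-E03	KC984283	JQ410941	JQ410940	-
P_brasilensis	SI-CBC2010KJ01-B07	-	JQ410943	JQ410942	-
P_brasilensis	SI-CBC2010KJ01-D07	-	JQ410944	-	-
P_brasilensis	SI-CBC2010KJ01-B09	-	JQ410946	JQ410945	JQ410904
P_brasilensis	SI-CBC2010KJ01-C09	-	JQ410948	JQ410947	JQ410905
P_brasilensis	SI-CBC2010KJ01-A10	-	-	JQ410949	-
P_brasilensis	SI-CBC2010KJ02-E01	-	JQ410950	-	-
P_brasilensis	ZSM_Mol_20110723	KC984284	JQ410952	JQ410951	JQ410906
P_brasilensis	ZSM_Mol_20110722	KC984285	JQ410932	JQ410931	JQ410900
P_brasilensis	ZSM_Mol_20090198	KC984286	JQ410936	JQ410935	-
P_verrucosa	ZSM_Mol_20071820	KC984287	JQ410978	JQ410977	JQ410920
P_verrucosa	ZSM_Mol_20080176	-	JQ410980	JQ410979	JQ410921
P_verrucosa	ZSM_Mol_20071135	KC984288	JQ410971	JQ410970	JQ410914
P_verrucosa	ZSM_Mol_20100388	-	-	-	JQ410916
P_verrucosa	ZSM_Mol_20100389	-	JQ410974	-	JQ410917
P_verrucosa	ZSM_Mol_20100390	-	JQ410975	-	JQ410918
P_verrucosa	ZSM_Mol_20100391	KC984289	-	JQ410976	JQ410919
P_kepii	ZSM_Mol_20081013	KC984290	JQ410967	JQ410966	JQ410912
P_joni	ZSM_Mol_20090197	KC984291	JQ410934	JQ410933	JQ410901
P_joni	SI-CBC2010KJ01-D05	KC984292	-	JQ410937	JQ410902
P_joni	SI-CBC2010KJ01-C08	-	JQ410939	JQ410938	JQ410903
P_neridae	AM_C_476062.001	-	JQ410986	JQ410985	JQ410922
P_liliae	ZSM_Mol_20090471	KC984293	JQ410954	JQ410953	-
P_liliae	ZSM_Mol_20090472	-	JQ410956	JQ410955	-
P_wiggi	ZSM_Mol_20100595	-	JQ410960	JQ410959	JQ410908
P_wiggi	ZSM_Mol_20100596	-	-	JQ410961	JQ410909
P_wiggi	ZSM_Mol_20100597	-	JQ410963	JQ410962	JQ410910
P_wiggi	ZSM_Mol_20100603	-	JQ410965	JQ410964	JQ410911
P_wenzli	ZSM_Mol_20100592	KC984294	JQ410958	JQ410957	JQ410907
P_wenzli	AM_C_476051.001	KC984295	JQ410982	JQ410981	-
P_wenzli	ZSM_Mol_20081014	KC984296	JQ410969	JQ410968	JQ410913
P_wenzli	ZSM_Mol_20100379	KC984297	JQ410973	JQ410972	JQ410915
P_peteryalli	ZSM_Mol_20071133	KC984298	-	JQ410930	JQ410899
P_martynovi	AM_C_476054.001	-	JQ410984	JQ410983	-
P_yurihookeri	ZSM_Mol_20080565	KC984299	JQ410987	-	-
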
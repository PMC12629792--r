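classical_markers_synthetic	synthetic stand-in marker set (not a published signature)	CLA01	CLA02	CLA03	CLA04	CLA05	CLA06	CLA07	CLA08	CLA09	CLA10	CLA11	CLA12	CLA13	CLA14	CLA15	CLA16	CLA17	CLA18	CLA19	CLA20	CLA21	CLA22	CLA23	CLA24	CLA25
basal_markers_synthetic	synthetic stand-in marker set (not a published signature)	BAS01	BAS02	BAS03	BAS04	BAS05	BAS06	BAS07	BAS08	BAS09	BAS10	BAS11	BAS12	BAS13	BAS14	BAS15	BAS16	BAS17	BAS18	BAS19	BAS20	BAS21	BAS22	BAS23	BAS24	BAS25
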
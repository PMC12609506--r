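gene	degree	log2fc	weight	gene_score	drugs
LYN	48	-0.24	11.34	0.48	Dasatinib; Bosutinib; Ponatinib; Nintedanib; Fostamatinib
JAK1	21	--	0	0.47	Ruxolitinib; Tofacitinib; Momelotinib; Baricitinib; Fostamatinib; Fedratinib; Filgotinib; Abrocitinib; Upadacitinib; Pralsetinib
FCGR2A	4	0.68	2.71	0.46	Cetuximab; Etanercept; Human immunoglobulin G; Abciximab; Alemtuzumab; Bevacizumab; Catumaxomab; Sarilumab
TEC	10	0.25	2.47	0.46	Bosutinib; Fostamatinib; Ritlecitinib; Zanubrutinib
TUBA4A	1	-0.13	0.13	0.45	Vincristine; Podofilox
PTPN6	29	-0.09	2.73	0.45	Tiludronic acid
SYK	37	-0.1	3.84	0.45	Fostamatinib
ITGA5	5	--	0	0.45	Tauroursodeoxycholic acid
GRB2	37	--	0	0.45	Pegademase
JAK3	16	0.45	7.3	0.44	Ruxolitinib; Tofacitinib; Momelotinib; Baricitinib; Fostamatinib; Ritlecitinib; Abrocitinib; Zanubrutinib
P2RY12	1	-0.49	0.49	0.44	Ticlopidine; Treprostinil; Clopidogrel; Promethazine; Epoprostenol; Prasugrel; Cangrelor; Ticagrelor
BTK	19	-0.271	5.08	0.44	Dasatinib; Ibrutinib; Acalabrutinib; Fostamatinib; Ritlecitinib; Zanubrutinib; Pirtobrutinib
PPIA	1	--	0	0.44	Cyclosporine; Copper; Artenimol
PIK3CB	1	0.13	0.13	0.44	Caffeine; Copanlisib
CSK	18	0.11	1.95	0.44	Dasatinib; Fostamatinib
PTK2B	37	0.18	6.76	0.44	Leflunomide; Fostamatinib
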
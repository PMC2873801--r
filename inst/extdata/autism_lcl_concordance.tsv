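pair_id	mirna_id	gene_id	mirna_log2	gene_log2
A361/C360	miR-219	PLK2	-1.447	0.414
A809/C810	miR-219	PLK2	-1.089	0.147
A809/C813	miR-219	PLK2	-2.330	NA
A2369/C2368	miR-219	PLK2	-2.390	NA
A2369/C2357	miR-219	PLK2	-0.175	NA
A366/C365	miR-219	PLK2	0.398	0.314
A2769/C2772	miR-219	PLK2	-1.176	0.456
A361/C360	miR-29b	ID3	0.585	-0.406
A809/C810	miR-29b	ID3	1.720	-0.187
A809/C813	miR-29b	ID3	1.287	-0.574
A2369/C2368	miR-29b	ID3	0.395	-0.603
A2369/C2357	miR-29b	ID3	1.315	0.070
A366/C365	miR-29b	ID3	2.939	-0.152
A2769/C2772	miR-29b	ID3	0.061	-0.233
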
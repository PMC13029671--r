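parameter	KC	NT	RS
bacterial_nodes	424	273	574
fungal_nodes	6	95	59
edges	2392	2996	3300
positive_edges	2330	2934	3154
negative_edges	62	62	146
modularity	0.69	0.40	0.64
n_modules	21	28	18
avg_path_length	6.57	4.72	5.84
diameter	16.82	16.01	15.93
density	0.02	0.04	0.02
clustering_coefficient	0.56	0.59	0.51
betweenness_centralization	0.15	0.05	0.04
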
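class,type,n_nodes,pct_female,density_gt,density_bt,assortativity_gt,assortativity_bt,centralization_degree_gt,centralization_degree_bt,centralization_closeness_gt,centralization_closeness_bt
A,directed,15,53,0.50,0.63,0.37,0.15,0.23,0.24,0.38,0.15
A,undirected,15,53,0.68,0.68,0.25,0.08,0.36,0.20,0.50,0.24
B,directed,20,35,0.45,0.67,0.46,0.03,0.25,0.23,0.38,0.15
B,undirected,20,35,0.60,0.80,0.31,-0.04,0.44,0.16,0.59,0.21
C,directed,19,26,0.56,0.74,0.12,-0.08,0.23,0.15,0.32,0.10
C,undirected,19,26,0.77,0.77,0.02,-0.07,0.26,0.13,0.38,0.15
D,directed,13,46,0.46,0.48,0.20,-0.08,0.31,0.28,0.41,0.18
D,undirected,13,46,0.64,0.40,0.12,-0.10,0.42,0.32,0.56,0.39
E,directed,13,69,0.70,0.68,0.17,-0.16,0.15,0.26,0.24,0.18
E,undirected,13,69,0.85,0.73,0.03,-0.13,0.18,0.22,0.27,0.27
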
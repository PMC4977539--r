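# Published per-dataset contamination-index summaries (bovine-specific /
# human-specific read-count ratio) for public exRNA-seq datasets:
# group means +/- SEM, printed fold change, and group sizes.
# SEM is blank where the group holds a single sample.
dataset	cell_type	cellular_mean	cellular_sem	exosomal_mean	exosomal_sem	fc_printed	n_cellular	n_exosomal
GSE38916	HEK293T	0.029	0.010	0.095	0.026	3.26	2	2
GSE71901	MCF7	0.0004	0.0004	0.082	0.004	195.4	2	3
SRP046046	HB	0.063	0.012	0.146	0.040	2.32	3	6
SRP031761	LIM1863	0.166	NA	0.473	0.169	2.85	1	2
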
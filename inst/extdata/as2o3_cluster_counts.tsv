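cluster	sensitive	resistant
Cluster 1	6	17
Cluster 2	0	7
Cluster 3	18	5
Cluster 4	5	0
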
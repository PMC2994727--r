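file	md5
matrix.gct	074c56aeae1441e68e0b244eb874d840
studies.tsv	d6107cc5142bf41b1b60409ae37b468e
sets.gmt	9c074203e27d689876514108489b8698
groups.tsv	a2211d9252a2f59255640b23b0bbbd98
truth_modules.tsv	04b699ce656048356874dc1338688bab
normalized.tsv	2e787ed3f7d41a87325d8ccebf255626
gene_hits.tsv	aea1314783d8e92802debce7d63f2dc6
sample_enrichment.tsv	60fc9204b8c9d300609664b8167c57a4
sample_set_map.tsv	c721b4b5d8d4e30a9d7031ad9145a9eb
experimentset_map.tsv	25d031e6156f12ed54c8be52ba4243e7
experiment_hit_matrix.tsv	26dc9e60bcffd746ababdfab8b3ec48f
signature.gmt	48a7ca6597825962b132ec9681d1124f
prevalence.tsv	447a627aeacc29e436b48cc4bbf6d28d
dendrogram.newick	be9291b5ce35a8439ea0ebbfbbb04038
clustered.cdt	94943c9d73765c947f5202aa49aa234c
clustered.gtr	8345ace4a83298a5086119d58fc08a4e
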
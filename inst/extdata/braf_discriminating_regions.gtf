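# Discriminating regions for the two full-length BRAF transcript variants
# (GRCh38 coordinates; minus-strand intervals written 5'->3' as is
# conventional for this locus, i.e. in descending genomic order).
chr7	isoregion	discriminating_region	140725145	140719327	.	-	.	variant_id "BRAF-204";
chr7	isoregion	discriminating_region	140732564	140730665	.	-	.	variant_id "BRAF-220";
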
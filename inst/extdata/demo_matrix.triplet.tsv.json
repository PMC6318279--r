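{"chrom":"chrS","bin_size":50000,"haplotype":"demo","n_bins":30}
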
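# CpG islands at the CCDC163P-MMACHC bidirectional promoter (CpG:33) and the
# TESK2 promoter (CpG:51), GRCh37, BED (0-based half-open). CpG:33 bounds are
# the published interval chr1:45,965,587-45,966,049; CpG:51 bounds span the
# reported in-island probes (no published interval; not UCSC bounds).
chr1	45956423	45956882	CpG:51
chr1	45965586	45966049	CpG:33
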
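# Example run configuration for run_all(). Unset keys fall back to the
# documented defaults (thresholds as printed in the protocol: Phred 5 end
# trim, Q10 over 85%, 16-27 nt window, 1 mismatch, abundance filter 50 in
# >= 2 samples, padj < 0.05, |log2FC| > 0.6, 10 kb cluster gap).
mature_fasta: mature_synthetic.fa
loci_gff: loci_synthetic.gff3
contaminant_fasta: contaminants_synthetic.fa
simulate_reads: true
n_reads: 250
filter_threshold: 5   # shallow smoke-scale libraries; use 50 for deep data
seed: 1
outdir: mirtraj_out
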
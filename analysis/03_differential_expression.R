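#!/usr/bin/env Rscript
# Stage 3: normalization, abundance filtering, and the two developmental
# contrasts (NSC over hESC; DiffNSC over NSC) on the study-scale simulated
# count matrix.

suppressPackageStartupMessages(library(mirtraj))

tab <- read.delim("results/sim/counts_trajectory.tsv", check.names = FALSE)
counts <- as.matrix(tab[, -1]); rownames(counts) <- tab[[1]]
storage.mode(counts) <- "integer"
meta <- read.delim("results/sim/samples_trajectory.tsv",
                   stringsAsFactors = FALSE)

norm <- normalize_counts(counts, meta)
cat(sprintf("size factors span %.3f-%.3f (geometric mean 1 by construction)\n",
            min(norm$size_factors), max(norm$size_factors)))

retained <- abundance_filter(norm, threshold = 50, min_samples = 2)
cat(sprintf("abundance filter (>50 normalized counts in >=2 samples of one cell type): %d of %d miRNAs retained\n",
            length(retained), nrow(counts)))

cons <- run_contrasts(norm, mirnas = retained)
write_de_table(cons$de1, "results/de_NSC_vs_hESC.tsv")
write_de_table(cons$de2, "results/de_DiffNSC_vs_NSC.tsv")

for (k in 1:2) {
  de <- cons[[k]]
  cat(sprintf("%s: %d miRNAs at padj < 0.05 (%d up, %d down)\n",
              de$contrast[1], sum(de$padj < 0.05),
              sum(de$padj < 0.05 & de$log2fc > 0),
              sum(de$padj < 0.05 & de$log2fc < 0)))
  cat("  top upregulated:  ",
      paste(top_ranked(de, "up", 5), collapse = ", "), "\n")
  cat("  top downregulated:",
      paste(top_ranked(de, "down", 5), collapse = ", "), "\n")
}
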
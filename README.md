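# mirtraj

Small RNA-seq analysis of miRNA expression across a stem-cell
differentiation series: human embryonic stem cells (hESC) → self-renewing
neural stem cells (NSC) → differentiating NSCs (Diff.NSC). The package is
for computational biologists who want a fully testable, download-free
re-implementation of this analysis: every stage runs on synthetic data with
planted structure, so each algorithm can be verified against ground truth
and brute-force oracles.

## What it computes

* **Read filtering and counting** — 3' adapter trimming (≤1 mismatch,
  ≥6 nt overlap), end-trimming of bases with Phred < 5, an 85%-of-bases ≥
  Q10 rule, a 16–27 nt length window, and minimum-mismatch ungapped
  assignment to mature miRNAs with contaminant priority: reads matching
  rRNA/tRNA/snoRNA/snRNA/YRNA with *strictly fewer* mismatches than any
  miRNA are excluded. Multi-mapping reads split 1/k.
* **Differential expression** — median-of-ratios size factors
  (s_j = median_i K_ij / geomean_i), an abundance filter (normalized counts
  > 50 in ≥2 samples of one cell type), and a negative-binomial Wald test
  per contrast with variance μ + αμ², moment-based dispersion pooled across
  miRNAs and shrunk 50/50 toward the trend α(μ) = a0/μ + a1,
  log2FC = log2((μ̂_b + 0.5)/(μ̂_a + 0.5)), delta-method standard errors,
  and Benjamini–Hochberg adjustment within each contrast.
* **Trajectory groups** — each miRNA's pair of transition states (UP /
  DOWN / STABLE at padj < 0.05, |log2FC| > 0.6, strict) maps to groups
  G1–G8 (e.g. G1 = up in NSC then down again: NSC-specific).
* **Clusters and seed families** — genomic clusters by single-linkage
  grouping (same strand, gaps ≤ 10 kb), families by identical seed
  (nucleotides 2–8), per-cell-state contribution fractions of each
  cluster/family to the total normalized miRNA population, effective
  cluster numbers (exp of Shannon entropy), and cross-cluster seed
  similarity by longest common substring (7 = identical, ≥6 = similar).
* **Growth curves** — doubling time = 48·ln2 / ln(N_D4/N_D2) hours.
* **Synthetic data** — NB counts over a log-normal abundance spectrum with
  planted trajectory groups and planted cluster dominance, plus FASTQ
  simulation (75 nt reads, two-state qualities, contaminant/adapterless/
  low-quality read fractions) for the 3/8/6-replicate design.

The packaged reference (`inst/extdata/*_synthetic*`) carries the well-known
mature sequences of 26 human miRNAs spanning the miR-302–367, miR-17–92,
miR-106a–363, miR-106b–25 and miR-200c–141 clusters, with synthetic genomic
placements that preserve real cluster composition.

## Worked example

```r
library(mirtraj)

fa  <- system.file("extdata", "mature_synthetic.fa",  package = "mirtraj")
gff <- system.file("extdata", "loci_synthetic.gff3", package = "mirtraj")
ann <- load_mirna_reference(fa, gff)

# the hESC-enriched miR-367 seed is identical to the NSC-enriched miR-92a seed
seed_similarity(ann$seed[ann$mirna_id == "hsa-miR-367-3p"][1],
                ann$seed[ann$mirna_id == "hsa-miR-92a-3p"][1])
#> $category
#> [1] "identical"
#> $score
#> [1] 7

# simulate the study design (hESC n=3, NSC n=8, DiffNSC n=6) with 40 miRNAs
# planted per trajectory group, then run the full DE + classification chain
spec <- simulation_spec(n_mirnas = 400, baseline_mean = 500, dispersion = 0.05,
                        planted_groups = default_planted_groups(40, 2), seed = 1)
sim  <- simulate_counts(spec)
norm <- normalize_counts(sim$counts, sim$sample_meta)
kept <- abundance_filter(norm)                      # > 50 in >= 2 samples
cons <- run_contrasts(norm, mirnas = kept)          # NSC/hESC, DiffNSC/NSC
calls <- classify_trajectories(cons$de1, cons$de2)  # padj < 0.05, |lfc| > 0.6
table(calls$group)
#>   G1   G2   G3   G4   G5   G6   G7   G8 unclassified
#>   40   39   40   43   40   40   40   40           76

truth   <- sim$truth$groups
planted <- truth[truth$group != "stable", ]
got     <- calls$group[match(planted$mirna_id, calls$mirna_id)]
mean(!is.na(got) & got == planted$group)   # planted-group recovery
#> [1] 0.996875

doubling_time(100, 800)    # three doublings in 48 h
#> [1] 16
```

The 40/39/40/... group counts recover the 8 × 40 planted trajectory
miRNAs almost exactly (99.7% correct labels); the few misses are planted
miRNAs whose log-normal baseline fell below the abundance filter or a
stable miRNA drifting over a threshold.

## Analysis workflow

The numbered scripts under `analysis/` run the whole study emulation and
write tables under `results/`:

```sh
Rscript analysis/01_simulate_data.R            # reference + synthetic study
Rscript analysis/02_preprocess.R               # FASTQ -> counts + filter report
Rscript analysis/03_differential_expression.R  # size factors, filter, 2 contrasts
Rscript analysis/04_trajectory_groups.R        # G1-G8 calls + exports
Rscript analysis/05_cluster_contributions.R    # cluster/family fractions, seeds
```

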
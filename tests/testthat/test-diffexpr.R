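make_norm <- function(counts, cell_type) {
  meta <- data.frame(sample_id = colnames(counts), cell_type = cell_type,
                     replicate = ave(seq_along(cell_type), cell_type,
                                     FUN = seq_along),
                     stringsAsFactors = FALSE)
  normalize_counts(counts, meta)
}

test_that("median-of-ratios size factors match the hand-computed example and DESeq2", {
  counts <- cbind(s1 = c(10L, 20L, 30L), s2 = c(20L, 40L, 60L))
  rownames(counts) <- paste0("m", 1:3)
  norm <- make_norm(counts, c("A", "A"))
  expect_equal(unname(norm$size_factors), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # normalized counts are equal across the two samples
  expect_equal(norm$normalized[, 1], norm$normalized[, 2])

  # identical samples -> unit size factors
  eq <- cbind(s1 = c(5L, 7L, 9L), s2 = c(5L, 7L, 9L))
  rownames(eq) <- paste0("m", 1:3)
  expect_equal(unname(make_norm(eq, c("A", "A"))$size_factors), c(1, 1))

  # scaling one sample by 10 multiplies its size factor by 10 (up to the
  # global geometric-mean rescale) and shifts its normalized counts by the
  # same constant for every gene (scale equivariance)
  set.seed(2)
  base <- matrix(rnbinom(300, mu = 100, size = 10), nrow = 50,
                 dimnames = list(paste0("m", 1:50), paste0("s", 1:6)))
  sc <- base; sc[, 3] <- sc[, 3] * 10L
  n1 <- make_norm(base, rep("A", 6))
  n2 <- make_norm(sc, rep("A", 6))
  expect_equal(unname(n2$size_factors[3] / n1$size_factors[3]),
               10 * 10^(-1 / 6), tolerance = 1e-9)
  ratio <- n2$normalized[, 3] / n1$normalized[, 3]
  expect_equal(ratio, rep(10^(1 / 6), 50), tolerance = 1e-9,
               ignore_attr = TRUE)

  # agreement with DESeq2 (which medians log-ratios; identical up to the
  # even-count median interpolation)
  sf_ours <- n1$size_factors
  sf_deseq <- DESeq2::estimateSizeFactorsForMatrix(base)
  expect_equal(unname(sf_ours / exp(mean(log(sf_ours)))),
               unname(sf_deseq / exp(mean(log(sf_deseq)))), tolerance = 1e-3)

  # all-zero-containing genes only -> informative error
  z <- cbind(s1 = c(0L, 5L), s2 = c(5L, 0L))
  rownames(z) <- c("m1", "m2")
  expect_error(make_norm(z, c("A", "A")), "positive counts")
})

test_that("the abundance filter applies a strict >50 rule within cell types", {
  counts <- rbind(
    kept     = c(60, 55, 10, 10, 10, 10),
    boundary = c(50, 50, 50, 50, 50, 50),
    onehigh  = c(1000, 0, 0, 1000, 0, 0),
    low      = c(5, 5, 5, 5, 5, 5)
  )
  colnames(counts) <- paste0("s", 1:6)
  storage.mode(counts) <- "integer"
  meta <- data.frame(sample_id = colnames(counts),
                     cell_type = rep(c("A", "B"), each = 3),
                     replicate = rep(1:3, 2), stringsAsFactors = FALSE)
  norm <- normalize_counts(counts, meta)
  norm$normalized <- counts  # isolate the filter rule from normalization
  expect_equal(abundance_filter(norm), "kept")
  # a cell type with a single sample warns and cannot qualify
  meta2 <- meta; meta2$cell_type <- c("A", "A", "A", "B", "B", "C")
  norm2 <- normalize_counts(counts, meta2)
  norm2$normalized <- counts
  expect_warning(r <- abundance_filter(norm2), "cannot qualify")
  expect_equal(r, "kept")
})

test_that("BH adjustment equals the step-up oracle and p.adjust on random vectors", {
  set.seed(14)
  for (i in 1:25) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  expect_equal(bh_adjust(numeric(0)), numeric(0))
})

test_that("identical groups give log2fc 0 and p 1; zero rows are degenerate", {
  counts <- cbind(a1 = c(10L, 100L, 0L), a2 = c(20L, 150L, 0L),
                  b1 = c(10L, 100L, 0L), b2 = c(20L, 150L, 0L))
  rownames(counts) <- c("m1", "m2", "mzero")
  norm <- make_norm(counts, c("A", "A", "B", "B"))
  de <- nb_test(norm, "A", "B")
  expect_equal(de$log2fc, c(0, 0, 0))
  expect_equal(de$pvalue, c(1, 1, 1))
  expect_true(all(de$padj >= de$pvalue))
})

test_that("swapping the group order negates every log2 fold change", {
  spec <- simulation_spec(n_mirnas = 120, cell_types = c("A", "B"),
                          replicates = c(4, 4), seed = 6,
                          planted_groups = list(G = list(n = 30, lfc = 1.5)))
  sim <- simulate_counts(spec)
  norm <- normalize_counts(sim$counts, sim$sample_meta)
  ab <- nb_test(norm, "A", "B")
  ba <- nb_test(norm, "B", "A")
  expect_equal(ab$log2fc, -ba$log2fc, tolerance = 1e-12)
  expect_equal(ab$pvalue, ba$pvalue, tolerance = 1e-12)
})

test_that("planted fold changes are recovered without material bias", {
  # 40 planted genes at log2fc = 2, baseline 500, dispersion 0.05:
  # the median estimate across planted genes sits near 2 (planting is kept
  # to 10% of genes so median-of-ratios normalization stays valid)
  spec <- simulation_spec(n_mirnas = 400, cell_types = c("A", "B"),
                          replicates = c(3, 3), baseline_mean = 500,
                          baseline_sdlog = 0, dispersion = 0.05, seed = 19,
                          planted_groups = list(G = list(n = 40, lfc = 2)))
  sim <- simulate_counts(spec)
  norm <- normalize_counts(sim$counts, sim$sample_meta)
  de <- nb_test(norm, "A", "B")
  planted <- sim$truth$groups$mirna_id[sim$truth$groups$group == "G"]
  expect_equal(median(de$log2fc[de$mirna_id %in% planted]), 2,
               tolerance = 0.1)
})

test_that("power: planted |log2fc| = 2 at baseline >= 200 is recovered at padj < 0.05", {
  spec <- simulation_spec(n_mirnas = 300, baseline_mean = 500,
                          baseline_sdlog = 0.5, dispersion = 0.1, seed = 23,
                          planted_groups = default_planted_groups(30, 2))
  sim <- simulate_counts(spec)
  norm <- normalize_counts(sim$counts, sim$sample_meta)
  cons <- run_contrasts(norm)
  tg <- sim$truth$groups
  for (k in 1:2) {
    de <- cons[[k]]
    lfc_true <- tg[[paste0("lfc", k)]]
    changed <- tg$mirna_id[lfc_true != 0 &
                             rowMeans(sim$truth$cell_means)[tg$mirna_id] >= 200]
    hit <- de$padj[match(changed, de$mirna_id)] < 0.05
    expect_gte(mean(hit), 0.95)
  }
})

test_that("run_contrasts orients both transitions and validates the design", {
  spec <- simulation_spec(n_mirnas = 50, seed = 2,
                          planted_groups = list(G1 = list(n = 10, lfc = c(2, -2))))
  sim <- simulate_counts(spec)
  norm <- normalize_counts(sim$counts, sim$sample_meta)
  cons <- run_contrasts(norm)
  g1 <- sim$truth$groups$mirna_id[sim$truth$groups$group == "G1"]
  lfc1 <- cons$de1$log2fc[match(g1, cons$de1$mirna_id)]
  lfc2 <- cons$de2$log2fc[match(g1, cons$de2$mirna_id)]
  expect_true(all(lfc1 > 0.6))  # higher in NSC than hESC
  expect_true(all(lfc2 < -0.6)) # lower in DiffNSC than NSC
  expect_error(run_contrasts(norm, design = c("hESC", "NSC", "missing")),
               "absent")
})
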
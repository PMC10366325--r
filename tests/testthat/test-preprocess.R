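adapter <- "AGATCGGAAGAGCACACGTCT"
params <- filter_params(adapter)

test_that("adapter trimming keeps the insert and discards adapterless reads", {
  insert <- "TATTGCACTTGTCCCGGCCTGT"  # 22 nt
  read <- paste0(insert, adapter, "ACGT")
  q <- rep(34L, nchar(read))
  tr <- trim_adapter(read, q, params)
  expect_equal(tr$status, "trimmed")
  expect_equal(tr$bases, insert)
  expect_length(tr$quals, 22)

  # one mismatch inside the adapter match is tolerated
  adap_mm <- paste0("AGATCGGAAGAGCACACGTC", "A")
  tr2 <- trim_adapter(paste0(insert, adap_mm), rep(34L, 43), params)
  expect_equal(tr2$status, "trimmed")
  expect_equal(tr2$bases, insert)

  # partial adapter at the read end counts when the overlap is >= 6
  tr3 <- trim_adapter(paste0(insert, substr(adapter, 1, 7)),
                      rep(34L, 29), params)
  expect_equal(tr3$status, "trimmed")

  # no adapter anywhere
  tr4 <- trim_adapter("ACGTACGTACGTACGTACGTACGTACGT", rep(34L, 28), params)
  expect_equal(tr4$status, "no_adapter")

  # adapter at position 1 leaves an empty insert for the length filter
  tr5 <- trim_adapter(paste0(adapter, "ACGT"), rep(34L, 25), params)
  expect_equal(tr5$status, "trimmed")
  expect_equal(nchar(tr5$bases), 0L)
  expect_equal(quality_filter(tr5$bases, tr5$quals, params)$status,
               "length_fail")
})

test_that("quality filtering applies end-trim, the 85% rule, then the length window", {
  # clean 22-mer passes unchanged
  b <- paste(rep("A", 22), collapse = "")
  qf <- quality_filter(b, rep(30L, 22), params)
  expect_equal(qf$status, "pass")
  expect_equal(qf$bases, b)

  # low-quality ends are stripped before the other rules
  q <- c(2L, 2L, rep(30L, 20), 3L)
  qf2 <- quality_filter(paste(rep("C", 23), collapse = ""), q, params)
  expect_equal(qf2$status, "pass")
  expect_equal(nchar(qf2$bases), 20L)

  # 8 of 20 bases at Q6 -> only 60% reach Q10 -> quality_fail
  q3 <- c(rep(6L, 8), rep(30L, 12))
  expect_equal(quality_filter(paste(rep("G", 20), collapse = ""), q3, params)$status,
               "quality_fail")

  # high-quality but 30 nt -> length_fail
  expect_equal(quality_filter(paste(rep("T", 30), collapse = ""),
                              rep(35L, 30), params)$status, "length_fail")
  # 15 nt after end-trim -> length_fail
  expect_equal(quality_filter(paste(rep("T", 16), collapse = ""),
                              c(rep(30L, 15), 2L), params)$status, "length_fail")
})

test_that("contaminant exclusion is strict (fewer mismatches) and ties count as miRNA", {
  mir <- data.frame(mirna_id = c("mir-1", "mir-2"),
                    sequence = c("UAUUGCACUUGUCCCGGCCUGU",
                                 "UGAGGUAGUAGGUUGUAUAGUU"),
                    stringsAsFactors = FALSE)
  # contaminant contains mir-1's sequence with one substitution
  con <- data.frame(ref_id = "tRNA-x", ncrna_class = "tRNA",
                    sequence = paste0("GGGGG", "UAUUGCACUUGACCCGGCCUGU", "GGGGG"),
                    stringsAsFactors = FALSE)
  idx <- build_ref_index(mir, con)

  # read == mature exactly; contaminant needs 1 mismatch -> counted
  r1 <- assign_read("TATTGCACTTGTCCCGGCCTGT", idx, params)
  expect_equal(r1$status, "counted")
  expect_equal(r1$targets, "mir-1")

  # read == contaminant fragment exactly; best miRNA needs 1 -> excluded
  r2 <- assign_read("TATTGCACTTGACCCGGCCTGT", idx, params)
  expect_equal(r2$status, "contaminant_excluded")

  # equal mismatch count (tie) stays miRNA
  con2 <- data.frame(ref_id = "tRNA-y", ncrna_class = "tRNA",
                     sequence = "GGUAUUGCACUUGUCCCGGCCUGUGG",
                     stringsAsFactors = FALSE)
  idx2 <- build_ref_index(mir, con2)
  r3 <- assign_read("TATTGCACTTGTCCCGGCCTGT", idx2, params)
  expect_equal(r3$status, "counted")

  # no reference within one mismatch -> unmatched
  r4 <- assign_read("CCCCCCCCCCCCCCCCCCCCCC", idx, params)
  expect_equal(r4$status, "unmatched")
})

test_that("a read matching two matures exactly splits 0.5/0.5 (or first-best)", {
  mir <- data.frame(mirna_id = c("mir-a", "mir-b"),
                    sequence = c("UAAGUGCUUCCAUGUUUUGGUGA",
                                 "UAAGUGCUUCCAUGUUUUGGUGA"),
                    stringsAsFactors = FALSE)
  idx <- build_ref_index(mir)
  r <- assign_read("TAAGTGCTTCCATGTTTTGGTGA", idx, params)
  expect_equal(r$status, "counted")
  expect_equal(sort(r$targets), c("mir-a", "mir-b"))
  expect_equal(r$weights, c(0.5, 0.5))
  expect_equal(sum(r$weights), 1)
  pf <- filter_params(adapter, multimap = "first")
  r2 <- assign_read("TAAGTGCTTCCATGTTTTGGTGA", idx, pf)
  expect_equal(r2$targets, "mir-a")
})

test_that("the pipeline count matrix equals the exhaustive per-read oracle and conserves reads", {
  ann <- load_fixture_reference()
  con <- load_fixture_contaminants()
  spec <- simulation_spec(seed = 33, read_error_rate = 0.01,
                          contaminant_fraction = 0.1, lowq_fraction = 0.1,
                          end_low_fraction = 0.15, adapterless_fraction = 0.05)
  reads <- simulate_reads(spec, ann, con, n_reads = 600)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  sheet <- data.frame(sample_id = "s1", cell_type = "hESC", replicate = 1,
                      fastq = fq, stringsAsFactors = FALSE)
  res <- build_count_matrix(sheet, ann, con, params)

  # conservation: statuses sum to the number of input reads
  expect_equal(sum(res$report$n_reads), 600L)

  # exhaustive oracle over every read
  u <- unique(ann[, c("mirna_id", "sequence")])
  mir_seqs <- setNames(chartr("U", "T", u$sequence), u$mirna_id)
  con_seqs <- setNames(chartr("U", "T", con$sequence), con$ref_id)
  w <- setNames(numeric(length(mir_seqs)), names(mir_seqs))
  statuses <- character(length(reads$bases))
  for (i in seq_along(reads$bases)) {
    o <- oracle_process_read(reads$bases[i], reads$quals[[i]], adapter,
                             mir_seqs, con_seqs)
    statuses[i] <- o$status
    if (o$status == "counted") w[o$targets] <- w[o$targets] + o$weights
  }
  expect_equal(as.integer(res$counts[names(w), "s1"]),
               as.integer(round(w)))
  oracle_tab <- table(factor(statuses, levels = c(
    "counted", "no_adapter", "quality_fail", "length_fail",
    "contaminant_excluded", "unmatched")))
  expect_equal(res$report$n_reads, as.integer(oracle_tab))
})

test_that("FASTQ parsing reports malformed records and rejects Phred+64", {
  bad <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII",
               "@r2", "ACGTACGT", "+", "III"), bad)
  expect_error(read_fastq(bad), "record 2")

  p64 <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGTACGTACGTACGTACGT", "+",
               paste(rep("h", 20), collapse = "")), p64)
  expect_error(read_fastq(p64), "Phred\\+64")
})

test_that("the heuristic adapter scan finds a spiked adapter prefix", {
  ann <- load_fixture_reference()
  spec <- simulation_spec(seed = 8, contaminant_fraction = 0,
                          lowq_fraction = 0, adapterless_fraction = 0)
  reads <- simulate_reads(spec, ann, n_reads = 300)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  kmer <- scan_adapter(fq)
  expect_true(grepl(kmer, spec$adapter, fixed = TRUE))
})
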
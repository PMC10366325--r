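test_that("reference loading normalizes the alphabet, extracts seeds, and joins loci", {
  ann <- load_fixture_reference()
  # every seed equals positions 2-8 of the mature, by independent slicing
  expect_identical(ann$seed,
                   vapply(ann$sequence, function(s)
                     paste(strsplit(s, "")[[1]][2:8], collapse = ""),
                     character(1), USE.NAMES = FALSE))
  expect_equal(seed_of(ann, "hsa-miR-92a-3p"), "AUUGCAC")
  expect_true(all(grepl("^[ACGU]+$", ann$sequence)))
  expect_true(all(ann$start <= ann$end, na.rm = TRUE))
  # multi-locus matures appear once per locus
  expect_equal(sum(ann$mirna_id == "hsa-miR-19b-3p"), 2L)

  # DNA-alphabet FASTA is converted to RNA; out-of-window entries are dropped
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">mir-a", "TATTGCACTTGTCCCGGCCTGT",
               ">mir-short", "AAAAAAA",
               ">mir-long", paste(rep("A", 40), collapse = "")), fa)
  expect_warning(a2 <- load_mirna_reference(fa), "outside the 16-27")
  expect_equal(a2$mirna_id, "mir-a")
  expect_equal(a2$sequence, "UAUUGCACUUGUCCCGGCCUGU")
  expect_equal(a2$seed, "AUUGCAC")
})

test_that("a mature without a locus is retained with a warning; malformed GFF errors with its line", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">mir-a", "UAUUGCACUUGUCCCGGCCUGU",
               ">mir-b", "UGAGGUAGUAGGUUGUAUAGUU"), fa)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tmiRNA\t100\t121\t.\t+\t.\tID=loc-a;Name=mir-a"), gff)
  expect_warning(ann <- load_mirna_reference(fa, gff), "mir-b")
  expect_true(is.na(ann$chrom[ann$mirna_id == "mir-b"]))
  expect_true(is.na(ann$cluster_id[ann$mirna_id == "mir-b"]))

  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tmiRNA\t100\t121\t.\t+\t.\tID=a;Name=a",
               "chr1\tonly-three-fields\toops"), bad)
  expect_error(read_mirna_gff(bad), "line 3")
})

test_that("cluster derivation matches a brute-force single-linkage oracle", {
  ann <- load_fixture_reference()
  cl <- derive_clusters(ann)
  # fixture composition: the five-member miR-302-367 cluster and the
  # six-member miR-17-92 cluster are recovered
  m302 <- cl$mirna_id[cl$cluster_id == "cl-hsa-miR-302b-3p"]
  expect_setequal(m302, c("hsa-miR-302a-3p", "hsa-miR-302b-3p",
                          "hsa-miR-302c-3p", "hsa-miR-302d-3p",
                          "hsa-miR-367-3p"))
  expect_equal(sum(cl$cluster_id == "cl-hsa-miR-17-5p"), 6L)
  expect_false(anyDuplicated(cl$mirna_id) > 0)

  # randomized property check against the oracle on small locus sets
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:15, 1)
    loci <- data.frame(
      mirna_id = paste0("m", seq_len(n)),
      sequence = replicate(n, paste(sample(c("A", "C", "G", "U"), 20,
                                           replace = TRUE), collapse = "")),
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = sample.int(50000, n),
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    loci$end <- loci$start + 21L
    loci$seed <- substr(loci$sequence, 2, 8)
    loci$cluster_id <- NA_character_
    gap <- sample(c(500, 5000, 10000), 1)
    cl2 <- derive_clusters(loci, max_gap_bp = gap)
    comp <- oracle_single_linkage(loci, gap)
    oracle_sets <- unname(Filter(function(x) length(x) >= 2,
                                 split(loci$mirna_id, comp)))
    got_sets <- unname(split(cl2$mirna_id, cl2$cluster_id))
    expect_setequal(lapply(got_sets, sort), lapply(oracle_sets, sort))
  }

  # strand rule and gap boundary
  two <- data.frame(mirna_id = c("a", "b"), chrom = "chr1",
                    start = c(100, 5100), end = c(121, 5121),
                    strand = c("+", "-"), stringsAsFactors = FALSE)
  expect_equal(nrow(derive_clusters(two, 10000)), 0L)
  expect_equal(nrow(derive_clusters(two, 10000, same_strand = FALSE)), 2L)
  expect_equal(nrow(derive_clusters(data.frame())), 0L)
})

test_that("family assignment groups identical seeds and is order-invariant", {
  ann <- load_fixture_reference()
  fam <- assign_families(ann)
  f92 <- fam$family_id[fam$mirna_id == "hsa-miR-92a-3p"]
  expect_setequal(fam$mirna_id[fam$family_id == f92],
                  c("hsa-miR-367-3p", "hsa-miR-92a-3p", "hsa-miR-363-3p",
                    "hsa-miR-25-3p"))
  # family id is the lexicographically smallest member, prefixed
  expect_equal(f92, "seed:hsa-miR-25-3p")
  # permuting the input changes nothing
  set.seed(3)
  fam2 <- assign_families(ann[sample.int(nrow(ann)), ])
  expect_identical(fam, fam2)
  # differing at seed position 1 -> two families
  d <- data.frame(mirna_id = c("x", "y"),
                  seed = c("AUUGCAC", "GUUGCAC"), stringsAsFactors = FALSE)
  expect_equal(length(unique(assign_families(d)$family_id)), 2L)
  expect_equal(nrow(assign_families(data.frame(mirna_id = character(0),
                                               seed = character(0)))), 0L)
})

test_that("seed similarity scores by longest common substring with threshold 6", {
  ann <- load_fixture_reference()
  expect_equal(seed_similarity("AUUGCAC", "AUUGCAC"),
               list(category = "identical", score = 7L))
  s <- seed_similarity(seed_of(ann, "hsa-miR-302a-3p"),
                       seed_of(ann, "hsa-miR-17-5p"))
  expect_equal(s$category, "similar")
  expect_equal(s$score, 6L)
  expect_equal(seed_similarity("AAAAAAA", "CCCCCCC")$category, "dissimilar")
  expect_error(seed_similarity("AAA", "AAAAAAA"), "7 nt")

  # symmetry, self-score 7, and oracle agreement on random seeds
  set.seed(5)
  for (i in 1:50) {
    a <- paste(sample(c("A", "C", "G", "U"), 7, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), 7, replace = TRUE), collapse = "")
    expect_equal(seed_similarity(a, b)$score, seed_similarity(b, a)$score)
    expect_equal(seed_similarity(a, a)$score, 7L)
    expect_equal(seed_similarity(a, b)$score, oracle_lcs(a, b))
  }
})

test_that("contaminant loading enforces the five ncRNA classes", {
  con <- load_fixture_contaminants()
  expect_true(all(con$ncrna_class %in%
                    c("rRNA", "tRNA", "snoRNA", "snRNA", "YRNA")))
  expect_true(all(grepl("^[ACGU]+$", con$sequence)))
  bad <- tempfile(fileext = ".fa")
  writeLines(c(">x class=mRNA", "ACGUACGUACGU"), bad)
  expect_error(load_contaminants(bad), "unknown contaminant class")
})

test_that("cluster tables round-trip through TSV and reject duplicates", {
  ann <- load_fixture_reference()
  cl <- derive_clusters(ann)
  tf <- tempfile(fileext = ".tsv")
  write_cluster_table(cl, tf)
  back <- read_cluster_table(tf)
  expect_equal(as.data.frame(back), as.data.frame(cl)[, c("cluster_id", "mirna_id")])
  dup <- tempfile(fileext = ".tsv")
  writeLines(c("cluster_id\tmirna_id", "c1\tm1", "c2\tm1"), dup)
  expect_error(read_cluster_table(dup), "at most one cluster")
})
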
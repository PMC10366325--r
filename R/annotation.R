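#' Reference data model for mature miRNAs
#'
#' Functions in this file load and annotate mature miRNA references:
#' sequences, seed extraction (positions 2-8 of the mature), genomic loci,
#' distance-based cluster derivation, and seed-based family assignment.
#'
#' @name annotation
#' @keywords internal
NULL

.rna_normalize <- function(x) {
  x <- toupper(x)
  gsub("T", "U", x, fixed = TRUE)
}

#' Extract the seed of a mature miRNA sequence
#'
#' The seed is defined as nucleotides 2-8 (1-based, inclusive) of the mature
#' sequence and is the principal determinant of target recognition.
#'
#' @param sequence Character vector of mature RNA sequences (length >= 8).
#' @return Character vector of 7-nt seeds.
#' @export
mirna_seed <- function(sequence) {
  if (any(nchar(sequence) < 8))
    stop("mature sequence shorter than 8 nt has no seed")
  substr(sequence, 2L, 8L)
}

#' Read miRNA loci from a GFF3 file
#'
#' Expects `miRNA` feature lines whose attributes carry `ID` (locus id) and
#' `Name` (mature miRNA name). Coordinates are 1-based inclusive.
#'
#' @param path Path to a GFF3 file.
#' @return data.frame with columns `locus_id`, `mirna_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @export
read_mirna_gff <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^\\s*(#|$)", lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L))
    stop(sprintf("malformed GFF3 line %d in %s: expected 9 tab-separated fields",
                 body[which(nfield != 9L)[1]], path))
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$Name) || is.null(mc$ID))
    stop("GFF3 records must carry ID and Name attributes")
  data.frame(
    locus_id = as.character(mc$ID),
    mirna_id = as.character(mc$Name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Load a mature miRNA reference
#'
#' Reads mature sequences from FASTA (DNA `T` alphabet is transparently
#' converted to RNA `U`), extracts seeds, and joins genomic loci from a GFF3
#' file by mature name. A mature name mapping to several loci (e.g. the two
#' genomic copies of miR-92a-3p) yields one row per locus; downstream
#' contribution analysis always works at the unique mature-name level.
#'
#' @param mature_fasta Path to a mature-sequence FASTA file.
#' @param loci_gff Optional path to a GFF3 file of genomic loci.
#' @param min_len,max_len Retained mature length window (defaults 16 and 27).
#' @return A data.frame of class `mirna_annotation` with columns `mirna_id`,
#'   `sequence`, `seed`, `chrom`, `start`, `end`, `strand`, `cluster_id`
#'   (initially `NA`), `family_id`.
#' @examples
#' fa <- system.file("extdata", "mature_synthetic.fa", package = "mirtraj")
#' gff <- system.file("extdata", "loci_synthetic.gff3", package = "mirtraj")
#' ann <- load_mirna_reference(fa, gff)
#' @export
load_mirna_reference <- function(mature_fasta, loci_gff = NULL,
                                 min_len = 16L, max_len = 27L) {
  seqs <- Biostrings::readBStringSet(mature_fasta)
  mirna_id <- sub("\\s.*$", "", names(seqs))
  sequence <- .rna_normalize(as.character(seqs))
  bad <- grepl("[^ACGU]", sequence)
  if (any(bad))
    stop(sprintf("mature entry %s contains characters outside {A,C,G,U/T}",
                 mirna_id[which(bad)[1]]))
  len <- nchar(sequence)
  drop <- len < min_len | len > max_len
  if (any(drop)) {
    warning(sprintf("dropping %d mature entr%s outside the %d-%d nt window: %s",
                    sum(drop), if (sum(drop) == 1) "y" else "ies",
                    min_len, max_len,
                    paste(mirna_id[drop], collapse = ", ")))
    mirna_id <- mirna_id[!drop]
    sequence <- sequence[!drop]
  }
  if (anyDuplicated(mirna_id))
    stop("duplicated mature names in FASTA")
  ann <- data.frame(
    mirna_id = mirna_id,
    sequence = sequence,
    seed = mirna_seed(sequence),
    chrom = NA_character_,
    start = NA_integer_,
    end = NA_integer_,
    strand = NA_character_,
    cluster_id = NA_character_,
    stringsAsFactors = FALSE
  )
  if (!is.null(loci_gff)) {
    loci <- read_mirna_gff(loci_gff)
    loci <- loci[loci$mirna_id %in% ann$mirna_id, , drop = FALSE]
    hit <- ann$mirna_id %in% loci$mirna_id
    if (any(!hit))
      warning(sprintf("no genomic locus for: %s (retained without cluster assignment)",
                      paste(ann$mirna_id[!hit], collapse = ", ")))
    with_loc <- merge(ann[hit, setdiff(names(ann), c("chrom", "start", "end", "strand"))],
                      loci[, c("mirna_id", "locus_id", "chrom", "start", "end", "strand")],
                      by = "mirna_id")
    without <- ann[!hit, , drop = FALSE]
    without[["locus_id"]] <- rep(NA_character_, nrow(without))
    ann <- rbind(with_loc[, names(without)], without)
    ann <- ann[order(match(ann$mirna_id, mirna_id), ann$chrom, ann$start), , drop = FALSE]
  } else {
    ann$locus_id <- NA_character_
  }
  fam <- assign_families(ann)
  ann$family_id <- fam$family_id[match(ann$seed, fam$seed)]
  rownames(ann) <- NULL
  class(ann) <- c("mirna_annotation", "data.frame")
  ann
}

#' Derive genomic miRNA clusters by single-linkage distance grouping
#'
#' Loci on the same chromosome (and, by default, the same strand) whose
#' inter-locus gaps are at most `max_gap_bp` are merged into one cluster;
#' singleton loci are excluded. The default 10 kb window follows the common
#' convention for polycistronic miRNA clusters.
#'
#' @param mirnas A `mirna_annotation` data.frame with populated loci.
#' @param max_gap_bp Maximum gap (bp) between successive loci (default 10000).
#' @param same_strand Require identical strand within a cluster (default TRUE).
#' @return data.frame of class `cluster_table` with columns `cluster_id`,
#'   `mirna_id` (members ordered by genomic position; a mature name appears at
#'   most once per cluster). The derivation parameters are kept as attributes
#'   `max_gap_bp` and `same_strand`.
#' @export
derive_clusters <- function(mirnas, max_gap_bp = 10000L, same_strand = TRUE) {
  loc <- mirnas[!is.na(mirnas$chrom), , drop = FALSE]
  empty <- data.frame(cluster_id = character(0), mirna_id = character(0),
                      stringsAsFactors = FALSE)
  attr(empty, "max_gap_bp") <- max_gap_bp
  attr(empty, "same_strand") <- same_strand
  class(empty) <- c("cluster_table", "data.frame")
  if (nrow(loc) == 0) return(empty)
  gr <- GenomicRanges::GRanges(
    loc$chrom, IRanges::IRanges(loc$start, loc$end),
    strand = if (same_strand) loc$strand else "*"
  )
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap_bp + 1L,
                               ignore.strand = !same_strand)
  ov <- GenomicRanges::findOverlaps(gr, red, ignore.strand = !same_strand)
  grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  keep_grp <- as.integer(names(which(table(grp) >= 2)))
  rows <- lapply(keep_grp, function(g) {
    m <- loc[grp == g, , drop = FALSE]
    m <- m[order(m$start, m$mirna_id), , drop = FALSE]
    members <- m$mirna_id[!duplicated(m$mirna_id)]
    if (length(members) < 2) return(NULL)
    data.frame(cluster_id = paste0("cl-", members[1]), mirna_id = members,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$mirna_id))
    out <- out[!duplicated(out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "max_gap_bp") <- max_gap_bp
  attr(out, "same_strand") <- same_strand
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' Assign miRNAs to seed-defined families
#'
#' Two miRNAs belong to the same family iff their 7-nt seeds are identical.
#' The family identifier is the lexicographically smallest member name,
#' prefixed with `"seed:"`.
#'
#' @param mirnas A `mirna_annotation` data.frame (or any data.frame with
#'   `mirna_id` and `seed` columns).
#' @return data.frame with columns `family_id`, `seed`, `mirna_id`.
#' @export
assign_families <- function(mirnas) {
  u <- unique(data.frame(mirna_id = mirnas$mirna_id, seed = mirnas$seed,
                         stringsAsFactors = FALSE))
  if (nrow(u) == 0)
    return(data.frame(family_id = character(0), seed = character(0),
                      mirna_id = character(0), stringsAsFactors = FALSE))
  fam_of_seed <- vapply(split(u$mirna_id, u$seed),
                        function(m) paste0("seed:", min(m)), character(1))
  out <- data.frame(family_id = fam_of_seed[u$seed], seed = u$seed,
                    mirna_id = u$mirna_id, stringsAsFactors = FALSE)
  out <- out[order(out$family_id, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.lcs_length <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  best <- 0L
  prev <- integer(length(y))
  for (i in seq_along(x)) {
    cur <- integer(length(y))
    for (j in seq_along(y)) {
      if (x[i] == y[j]) {
        cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

#' Compare two miRNA seeds
#'
#' Scores two 7-nt seeds by the length of their longest common substring and
#' categorizes the pair: `identical` (equal seeds), `similar` (score >= 6 but
#' not identical), else `dissimilar`. This reproduces both relations reported
#' for the stem-cell clusters: the miR-367 seed is identical to the
#' miR-92/miR-363 seed, and the miR-302 seed is highly similar (score 6) to
#' the miR-17/miR-106a seed.
#'
#' @param seed_a,seed_b 7-nt RNA seed strings.
#' @return list with elements `category` and `score`.
#' @examples
#' seed_similarity("AUUGCAC", "AUUGCAC")
#' @export
seed_similarity <- function(seed_a, seed_b) {
  if (nchar(seed_a) != 7L || nchar(seed_b) != 7L)
    stop("seeds must be exactly 7 nt")
  score <- .lcs_length(seed_a, seed_b)
  category <- if (seed_a == seed_b) "identical"
              else if (score >= 6L) "similar"
              else "dissimilar"
  list(category = category, score = score)
}

#' Load a contaminant (non-miRNA ncRNA) reference
#'
#' FASTA headers must carry a `class=` tag naming one of the five handled
#' non-coding RNA classes: rRNA, tRNA, snoRNA, snRNA, YRNA.
#'
#' @param fasta Path to the contaminant FASTA.
#' @return data.frame with columns `ref_id`, `ncrna_class`, `sequence` (RNA
#'   alphabet).
#' @export
load_contaminants <- function(fasta) {
  seqs <- Biostrings::readBStringSet(fasta)
  ref_id <- sub("\\s.*$", "", names(seqs))
  cls <- sub("^.*class=(\\S+).*$", "\\1", names(seqs))
  no_tag <- !grepl("class=", names(seqs))
  if (any(no_tag))
    stop(sprintf("contaminant entry %s lacks a class= tag", ref_id[which(no_tag)[1]]))
  allowed <- c("rRNA", "tRNA", "snoRNA", "snRNA", "YRNA")
  if (!all(cls %in% allowed))
    stop(sprintf("unknown contaminant class '%s' (allowed: %s)",
                 setdiff(cls, allowed)[1], paste(allowed, collapse = ", ")))
  data.frame(ref_id = ref_id, ncrna_class = cls,
             sequence = .rna_normalize(as.character(seqs)),
             stringsAsFactors = FALSE)
}

#' Read or write a two-column cluster table
#'
#' @param path TSV path with columns `cluster_id`, `mirna_id`.
#' @return `read_cluster_table`: a `cluster_table` data.frame.
#' @export
read_cluster_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cluster_id", "mirna_id") %in% names(out)))
    stop("cluster table needs columns cluster_id, mirna_id")
  if (anyDuplicated(out$mirna_id))
    stop("a miRNA may belong to at most one cluster")
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' @rdname read_cluster_table
#' @param clusters A `cluster_table` data.frame.
#' @export
write_cluster_table <- function(clusters, path) {
  utils::write.table(as.data.frame(clusters)[, c("cluster_id", "mirna_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a seed-family table as TSV
#'
#' @param families Output of [assign_families()].
#' @param path Output TSV path.
#' @export
write_family_table <- function(families, path) {
  utils::write.table(families, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stamp cluster membership onto an annotation table
#'
#' @param mirnas A `mirna_annotation` data.frame.
#' @param clusters A `cluster_table` (derived or user-provided).
#' @return `mirnas` with the `cluster_id` column filled in (NA when
#'   unclustered).
#' @export
apply_cluster_table <- function(mirnas, clusters) {
  mirnas$cluster_id <- clusters$cluster_id[match(mirnas$mirna_id, clusters$mirna_id)]
  mirnas
}
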
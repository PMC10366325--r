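#' Read filtering and read-to-miRNA counting
#'
#' The filtering chain is order-faithful to the small-RNA protocol it
#' implements: (1) 3' adapter trimming (reads without adapter evidence are
#' discarded), (2) removal of very low-quality read ends (Phred < 5),
#' (3) keep only reads with Phred >= 10 over at least 85% of the length,
#' (4) keep only reads of 16-27 nt. Surviving reads are assigned by
#' minimum-mismatch ungapped matching; reads matching a contaminant
#' (rRNA/tRNA/snoRNA/snRNA/YRNA) with strictly fewer mismatches than any
#' miRNA are excluded.
#'
#' @name preprocess
#' @keywords internal
NULL

#' Filtering and assignment parameters
#'
#' @param adapter 3' adapter sequence (DNA alphabet, >= 6 nt).
#' @param end_trim_phred Bases below this Phred score are stripped from both
#'   read ends (default 5).
#' @param min_phred Per-base threshold of the fraction rule (default 10).
#' @param min_fraction Minimum fraction of bases at or above `min_phred`
#'   (default 0.85).
#' @param min_len,max_len Retained length window (defaults 16, 27).
#' @param max_mismatches Maximum mismatches for a reference hit (default 1).
#' @param multimap Either "fractional" (1/k weights across equally best
#'   miRNAs) or "first" (first best hit in reference order).
#' @return Validated list of class `filter_params`.
#' @export
filter_params <- function(adapter, end_trim_phred = 5L, min_phred = 10L,
                          min_fraction = 0.85, min_len = 16L, max_len = 27L,
                          max_mismatches = 1L,
                          multimap = c("fractional", "first")) {
  multimap <- match.arg(multimap)
  if (nchar(adapter) < 6) stop("adapter must be at least 6 nt")
  if (min_fraction <= 0 || min_fraction > 1) stop("min_fraction must be in (0, 1]")
  if (min_len > max_len) stop("min_len must be <= max_len")
  if (max_mismatches < 0) stop("max_mismatches must be >= 0")
  structure(list(adapter = toupper(chartr("U", "T", adapter)),
                 end_trim_phred = as.integer(end_trim_phred),
                 min_phred = as.integer(min_phred),
                 min_fraction = min_fraction, min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 max_mismatches = as.integer(max_mismatches),
                 multimap = multimap),
            class = "filter_params")
}

#' Read a Phred+33 FASTQ file
#'
#' Parses with Biostrings; a malformed record is reported with its record
#' index. Phred+64-encoded files are detected heuristically (all quality
#' characters >= ';' and some above 'J') and rejected.
#'
#' @param path FASTQ path (plain or gzip).
#' @return list with `read_id`, `bases` (character), `quals` (list of
#'   integer Phred vectors).
#' @export
read_fastq <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) .diagnose_fastq(path, conditionMessage(e))
  )
  quals_chr <- tryCatch({
    q <- as.character(S4Vectors::mcols(x)$qualities)
    if (any(nchar(q) != Biostrings::width(x)))
      stop("sequence/quality length mismatch")
    q
  }, error = function(e) .diagnose_fastq(path, conditionMessage(e)))
  ascii <- utf8ToInt(paste(quals_chr, collapse = ""))
  if (length(ascii) && min(ascii) >= 59L && max(ascii) >= 75L)
    stop(sprintf("%s looks Phred+64-encoded; only Phred+33 FASTQ is supported", path))
  list(read_id = sub("\\s.*$", "", names(x)),
       bases = toupper(as.character(x)),
       quals = lapply(quals_chr, function(q) utf8ToInt(q) - 33L))
}

.diagnose_fastq <- function(path, parent_msg) {
  lines <- readLines(path, warn = FALSE)
  n_rec <- ceiling(length(lines) / 4)
  for (r in seq_len(n_rec)) {
    chunk <- lines[(4 * r - 3):min(4 * r, length(lines))]
    ok <- length(chunk) == 4 && startsWith(chunk[1], "@") &&
      startsWith(chunk[3], "+") && nchar(chunk[2]) == nchar(chunk[4])
    if (!isTRUE(ok))
      stop(sprintf("malformed FASTQ record %d in %s", r, path))
  }
  stop(sprintf("failed to parse FASTQ %s: %s", path, parent_msg))
}

#' Trim the 3' adapter from one read
#'
#' Truncates bases and qualities at the leftmost adapter occurrence, allowing
#' at most one mismatch in the matched prefix and requiring an overlap of at
#' least 6 nt (so a partial adapter at the read end still counts as
#' evidence). Reads with no adapter evidence get status `no_adapter`.
#'
#' @param bases Read sequence (character scalar).
#' @param quals Integer Phred vector of the same length.
#' @param params A [filter_params()].
#' @return list with `status` ("trimmed" or "no_adapter") and, when trimmed,
#'   `bases` and `quals` of the insert (possibly empty).
#' @export
trim_adapter <- function(bases, quals, params) {
  r <- utf8ToInt(bases)
  a <- utf8ToInt(params$adapter)
  L <- length(r)
  last_start <- L - 6L + 1L
  if (last_start >= 1L) {
    for (p in seq_len(last_start)) {
      ov <- min(length(a), L - p + 1L)
      if (sum(r[p:(p + ov - 1L)] != a[seq_len(ov)]) <= 1L) {
        keep <- seq_len(p - 1L)
        return(list(status = "trimmed",
                    bases = substr(bases, 1L, p - 1L),
                    quals = quals[keep]))
      }
    }
  }
  list(status = "no_adapter")
}

#' Quality- and length-filter one adapter-trimmed read
#'
#' Applies, in order: end-trimming of bases with Phred below
#' `end_trim_phred` from both ends inward; the fraction rule (at least
#' `min_fraction` of the remaining bases at Phred >= `min_phred`, otherwise
#' `quality_fail`); the length window (`length_fail` outside
#' `min_len`-`max_len`).
#'
#' @inheritParams trim_adapter
#' @return list with `status` ("pass", "quality_fail" or "length_fail") and,
#'   on pass, the surviving `bases` and `quals`.
#' @export
quality_filter <- function(bases, quals, params) {
  ok <- which(quals >= params$end_trim_phred)
  if (length(ok) == 0)
    return(list(status = "length_fail"))
  lo <- ok[1]; hi <- ok[length(ok)]
  quals <- quals[lo:hi]
  bases <- substr(bases, lo, hi)
  if (mean(quals >= params$min_phred) < params$min_fraction)
    return(list(status = "quality_fail"))
  n <- length(quals)
  if (n < params$min_len || n > params$max_len)
    return(list(status = "length_fail"))
  list(status = "pass", bases = bases, quals = quals)
}

#' Build a matching index over miRNA and contaminant references
#'
#' References are stored DNA-alphabet so filtered reads can be compared
#' directly.
#'
#' @param mirnas A `mirna_annotation` data.frame.
#' @param contaminants Optional contaminant reference data.frame.
#' @return list of class `ref_index`.
#' @export
build_ref_index <- function(mirnas, contaminants = NULL) {
  u <- unique(data.frame(mirna_id = mirnas$mirna_id, sequence = mirnas$sequence,
                         stringsAsFactors = FALSE))
  idx <- list(
    mirna_id = u$mirna_id,
    mirna_int = lapply(chartr("U", "T", u$sequence), utf8ToInt),
    contam_id = character(0),
    contam_int = list()
  )
  if (!is.null(contaminants) && nrow(contaminants) > 0) {
    idx$contam_id <- contaminants$ref_id
    idx$contam_int <- lapply(chartr("U", "T", contaminants$sequence), utf8ToInt)
  }
  class(idx) <- "ref_index"
  idx
}

# Minimum Hamming distance of `read` over all ungapped end-to-end placements
# within `ref`; Inf when the read is longer than the reference.
.min_mismatch <- function(read_int, ref_int) {
  L <- length(read_int); M <- length(ref_int)
  if (M < L) return(Inf)
  best <- Inf
  for (o in 0:(M - L)) {
    mm <- sum(read_int != ref_int[(o + 1L):(o + L)])
    if (mm < best) {
      best <- mm
      if (best == 0) break
    }
  }
  best
}

#' Assign one filtered read to a miRNA or exclude it as contaminant
#'
#' The read is placed ungapped and end-to-end at every offset within each
#' mature sequence, and as an ungapped substring within each contaminant.
#' A contaminant hit with strictly fewer mismatches than the best miRNA hit
#' excludes the read; ties are retained as miRNA. Equally best miRNAs share
#' the read with fractional 1/k weights (or the first best hit takes it all
#' under `multimap = "first"`).
#'
#' @param bases Filtered read sequence (DNA alphabet).
#' @param index A [build_ref_index()] result.
#' @param params A [filter_params()].
#' @return list with `status` ("counted", "contaminant_excluded" or
#'   "unmatched") and, when counted, `targets` and `weights` (summing to 1).
#' @export
assign_read <- function(bases, index, params) {
  r <- utf8ToInt(bases)
  mir_mm <- vapply(index$mirna_int, .min_mismatch, numeric(1), read_int = r)
  best_mir <- suppressWarnings(min(mir_mm))
  best_con <- if (length(index$contam_int))
    suppressWarnings(min(vapply(index$contam_int, .min_mismatch, numeric(1),
                                read_int = r)))
  else Inf
  mm <- params$max_mismatches
  if (best_mir > mm && best_con > mm) return(list(status = "unmatched"))
  if (best_con < best_mir) return(list(status = "contaminant_excluded"))
  hits <- which(mir_mm == best_mir)
  if (params$multimap == "first") hits <- hits[1]
  list(status = "counted", targets = index$mirna_id[hits],
       weights = rep(1 / length(hits), length(hits)))
}

# Run the full chain on one read; returns status plus targets/weights.
.process_read <- function(bases, quals, index, params) {
  tr <- trim_adapter(bases, quals, params)
  if (tr$status == "no_adapter") return(list(status = "no_adapter"))
  qf <- quality_filter(tr$bases, tr$quals, params)
  if (qf$status != "pass") return(list(status = qf$status))
  assign_read(qf$bases, index, params)
}

.status_levels <- c("counted", "no_adapter", "quality_fail", "length_fail",
                    "contaminant_excluded", "unmatched")

# Process one sample's reads; deduplicates identical (bases, quals) pairs so
# each distinct read is matched once.
.count_sample <- function(bases, quals, index, params) {
  key <- paste(bases, vapply(quals, paste, character(1), collapse = ","))
  first <- !duplicated(key)
  uidx <- which(first)
  lookup <- match(key, key[uidx])
  outcomes <- lapply(uidx, function(i)
    .process_read(bases[i], quals[[i]], index, params))
  status <- vapply(outcomes, `[[`, character(1), "status")[lookup]
  w <- numeric(length(index$mirna_id))
  names(w) <- index$mirna_id
  mult <- tabulate(lookup, nbins = length(uidx))
  for (k in seq_along(uidx)) {
    o <- outcomes[[k]]
    if (o$status == "counted")
      w[o$targets] <- w[o$targets] + o$weights * mult[k]
  }
  list(weights = w,
       status_counts = table(factor(status, levels = .status_levels)),
       status = status)
}

#' Build a count matrix from FASTQ files
#'
#' Runs the full filter/assign chain per sample and sums per-miRNA weights;
#' fractional sums are rounded to integers at the end (round-half-even).
#'
#' @param sample_sheet data.frame with columns `sample_id`, `cell_type`,
#'   `replicate`, `fastq`.
#' @param mirnas A `mirna_annotation` reference.
#' @param contaminants Optional contaminant reference.
#' @param params A [filter_params()].
#' @return list with `counts` (integer matrix, miRNA x sample), `report`
#'   (long data.frame of per-sample per-status read counts) and
#'   `sample_meta`.
#' @export
build_count_matrix <- function(sample_sheet, mirnas, contaminants = NULL,
                               params) {
  need <- c("sample_id", "cell_type", "replicate", "fastq")
  if (!all(need %in% names(sample_sheet)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  missing <- !file.exists(sample_sheet$fastq)
  if (any(missing))
    stop("FASTQ not found: ", paste(sample_sheet$fastq[missing], collapse = ", "))
  index <- build_ref_index(mirnas, contaminants)
  counts <- matrix(0, nrow = length(index$mirna_id), ncol = nrow(sample_sheet),
                   dimnames = list(index$mirna_id, sample_sheet$sample_id))
  report <- vector("list", nrow(sample_sheet))
  for (j in seq_len(nrow(sample_sheet))) {
    fq <- read_fastq(sample_sheet$fastq[j])
    res <- .count_sample(fq$bases, fq$quals, index, params)
    counts[, j] <- res$weights
    report[[j]] <- data.frame(sample_id = sample_sheet$sample_id[j],
                              status = names(res$status_counts),
                              n_reads = as.integer(res$status_counts),
                              stringsAsFactors = FALSE)
  }
  storage.mode(counts) <- "double"
  counts <- round(counts)
  storage.mode(counts) <- "integer"
  list(counts = counts, report = do.call(rbind, report),
       sample_meta = sample_sheet[, c("sample_id", "cell_type", "replicate")])
}

#' Heuristic adapter scan
#'
#' Flags the most frequent 12-mer in the read tails (everything beyond the
#' shortest plausible miRNA insert, default position 17) of up to the first
#' 10,000 reads as the putative adapter prefix. This is a fallback for when
#' the library's adapter is not known a priori; supplying the kit adapter is
#' always preferred.
#'
#' @param fastq FASTQ path.
#' @param k K-mer length (default 12).
#' @param tail_from First scanned position (default 17, one past the
#'   shortest retained insert).
#' @param max_reads Reads to scan (default 10000).
#' @return Character scalar: the over-represented k-mer.
#' @export
scan_adapter <- function(fastq, k = 12L, tail_from = 17L, max_reads = 10000L) {
  fq <- read_fastq(fastq)
  n <- min(length(fq$bases), max_reads)
  halves <- substr(fq$bases[seq_len(n)], tail_from,
                   nchar(fq$bases[seq_len(n)]))
  kmers <- unlist(lapply(halves, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1), k:L)
  }))
  names(which.max(table(kmers)))
}
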
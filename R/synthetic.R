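#' Synthetic small RNA-seq data with planted structure
#'
#' The generator emulates the study design of the differentiation series:
#' three cell states (hESC, self-renewing NSC, differentiating NSC) with
#' 3/8/6 replicate libraries, negative-binomial counts over a log-normal
#' abundance spectrum, trajectory groups planted as per-transition log2 fold
#' changes, planted cluster dominance (e.g. one cluster holding ~63% of the
#' reads in the hESC-like state), and 75-cycle reads carrying a 3' adapter.
#'
#' @name synthetic
#' @keywords internal
NULL

#' Default planted trajectory groups
#'
#' One entry per trajectory group G1-G8, each planting `n_per_group` miRNAs
#' with the canonical per-transition log2 fold-change signs of that group
#' (UP = +magnitude, DOWN = -magnitude, STABLE = 0).
#'
#' @param n_per_group miRNAs planted per group.
#' @param magnitude Absolute log2 fold change on each changing transition.
#' @return Named list of `list(n =, lfc = c(lfc1, lfc2))`.
#' @export
default_planted_groups <- function(n_per_group = 40L, magnitude = 2) {
  signs <- list(G1 = c(1, -1), G2 = c(-1, 1), G3 = c(1, 1), G4 = c(1, 0),
                G5 = c(-1, -1), G6 = c(-1, 0), G7 = c(0, 1), G8 = c(0, -1))
  lapply(signs, function(s) list(n = n_per_group, lfc = s * magnitude))
}

#' Specify a synthetic experiment
#'
#' Defaults reproduce the study conditions: cell types hESC/NSC/DiffNSC with
#' 3/8/6 replicates, 75 nt reads, and a kit-style 3' adapter. The negative
#' binomial is parameterized as variance = mu + dispersion * mu^2.
#'
#' @param n_mirnas Number of simulated miRNAs (count simulation only).
#' @param cell_types Ordered cell states.
#' @param replicates Libraries per cell state (same length as `cell_types`).
#' @param baseline_mean Expected baseline count per miRNA.
#' @param baseline_sdlog SD of the log-normal abundance spectrum across
#'   miRNAs (0 fixes every baseline at `baseline_mean`).
#' @param dispersion NB dispersion alpha (0 gives Poisson counts).
#' @param library_sdlog SD of per-library log-normal depth factors.
#' @param planted_groups Named list as from [default_planted_groups()], or
#'   NULL for an all-stable simulation.
#' @param planted_cluster_fraction Optional data.frame with columns
#'   `cell_type`, `cluster_id`, `fraction` giving target fractions of total
#'   expected reads.
#' @param adapter 3' adapter sequence (DNA alphabet).
#' @param read_length Sequenced read length (default 75 cycles).
#' @param n_reads Reads per simulated library.
#' @param read_error_rate Per-base substitution probability.
#' @param contaminant_fraction Fraction of reads drawn from contaminant
#'   references instead of miRNAs.
#' @param lowq_fraction Fraction of reads with a low-quality (~Q6) segment
#'   violating the 85%-above-Q10 rule.
#' @param end_low_fraction Fraction of reads whose first bases are Phred < 5
#'   (exercises the end-trim filter).
#' @param adapterless_fraction Fraction of reads without the adapter.
#' @param seed Integer RNG seed.
#' @return Validated list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_mirnas = 300L,
                            cell_types = c("hESC", "NSC", "DiffNSC"),
                            replicates = c(3L, 8L, 6L),
                            baseline_mean = 500,
                            baseline_sdlog = 1,
                            dispersion = 0.1,
                            library_sdlog = 0.2,
                            planted_groups = NULL,
                            planted_cluster_fraction = NULL,
                            adapter = "AGATCGGAAGAGCACACGTCT",
                            read_length = 75L,
                            n_reads = 2000L,
                            read_error_rate = 0.001,
                            contaminant_fraction = 0.05,
                            lowq_fraction = 0.05,
                            end_low_fraction = 0.1,
                            adapterless_fraction = 0.02,
                            seed = 1L) {
  errs <- character(0)
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(length(cell_types) >= 1 && !anyDuplicated(cell_types),
      "cell_types must be distinct")
  chk(length(replicates) == length(cell_types) && all(replicates >= 1),
      "replicates must match cell_types and be >= 1")
  chk(n_mirnas >= 1, "n_mirnas must be >= 1")
  chk(baseline_mean > 0, "baseline_mean must be > 0")
  chk(baseline_sdlog >= 0, "baseline_sdlog must be >= 0")
  chk(dispersion >= 0, "dispersion must be >= 0")
  chk(library_sdlog >= 0, "library_sdlog must be >= 0")
  for (p in c(read_error_rate, contaminant_fraction, lowq_fraction,
              end_low_fraction, adapterless_fraction))
    chk(p >= 0 && p <= 1, "rates/fractions must lie in [0, 1]")
  n_trans <- length(cell_types) - 1L
  if (!is.null(planted_groups)) {
    chk(all(vapply(planted_groups, function(g)
      length(g$lfc) == n_trans && g$n >= 0, logical(1))),
      sprintf("each planted group needs n >= 0 and %d per-transition log2 fold changes", n_trans))
    chk(sum(vapply(planted_groups, function(g) g$n, numeric(1))) <= n_mirnas,
        "planted miRNAs exceed n_mirnas")
  }
  if (!is.null(planted_cluster_fraction)) {
    chk(all(c("cell_type", "cluster_id", "fraction") %in%
              names(planted_cluster_fraction)),
        "planted_cluster_fraction needs cell_type, cluster_id, fraction")
    if (is.data.frame(planted_cluster_fraction)) {
      chk(all(planted_cluster_fraction$fraction >= 0 &
                planted_cluster_fraction$fraction <= 1),
          "planted fractions must lie in [0, 1]")
      sums <- tapply(planted_cluster_fraction$fraction,
                     planted_cluster_fraction$cell_type, sum)
      chk(all(sums <= 1), "planted fractions per cell type must sum to <= 1")
    }
  }
  chk(nchar(adapter) >= 6, "adapter must be at least 6 nt")
  chk(read_length >= 17, "read_length too short for any mature miRNA plus one adapter base")
  if (length(errs)) stop(paste(errs, collapse = "; "))
  structure(list(
    n_mirnas = as.integer(n_mirnas), cell_types = cell_types,
    replicates = as.integer(replicates), baseline_mean = baseline_mean,
    baseline_sdlog = baseline_sdlog, dispersion = dispersion,
    library_sdlog = library_sdlog, planted_groups = planted_groups,
    planted_cluster_fraction = planted_cluster_fraction,
    adapter = toupper(adapter), read_length = as.integer(read_length),
    n_reads = as.integer(n_reads), read_error_rate = read_error_rate,
    contaminant_fraction = contaminant_fraction,
    lowq_fraction = lowq_fraction, end_low_fraction = end_low_fraction,
    adapterless_fraction = adapterless_fraction, seed = as.integer(seed)
  ), class = "simulation_spec")
}

# Rescale expected means so planted cluster fractions hold in expectation for
# one cell type. `means` is the per-miRNA expected mean vector for that type.
.plant_fractions <- function(means, ids, plant, clusters) {
  total <- sum(means)
  planted_members <- character(0)
  scaled <- means
  for (k in seq_len(nrow(plant))) {
    members <- clusters$mirna_id[clusters$cluster_id == plant$cluster_id[k]]
    members <- intersect(members, ids)
    if (length(members) == 0)
      stop(sprintf("planted cluster %s has no members in the simulated set",
                   plant$cluster_id[k]))
    idx <- ids %in% members
    m_sum <- sum(means[idx])
    if (m_sum <= 0) stop("planted cluster has zero expected expression")
    scaled[idx] <- means[idx] * plant$fraction[k] * total / m_sum
    planted_members <- c(planted_members, members)
  }
  rest <- !(ids %in% planted_members)
  frac_rest <- 1 - sum(plant$fraction)
  if (frac_rest < 0) stop("planted fractions exceed 1")
  o_sum <- sum(means[rest])
  if (o_sum <= 0 && frac_rest > 1e-12)
    stop("no non-member expression left to carry the remaining fraction")
  if (o_sum > 0) scaled[rest] <- means[rest] * frac_rest * total / o_sum
  scaled
}

# Expected per-miRNA mean per cell type from baseline and planted log2 FCs.
.expected_means <- function(spec, ids, baseline, lfc, clusters = NULL) {
  n_types <- length(spec$cell_types)
  m <- matrix(baseline, nrow = length(ids), ncol = n_types,
              dimnames = list(ids, spec$cell_types))
  if (n_types > 1) {
    for (t in 2:n_types) m[, t] <- m[, t - 1] * 2^lfc[, t - 1]
  }
  plant <- spec$planted_cluster_fraction
  if (!is.null(plant)) {
    if (is.null(clusters))
      stop("planted_cluster_fraction requires a cluster table")
    for (ct in unique(plant$cell_type)) {
      if (!ct %in% spec$cell_types)
        stop(sprintf("planted cell type %s not in the design", ct))
      m[, ct] <- .plant_fractions(m[, ct], ids, plant[plant$cell_type == ct, ,
                                                      drop = FALSE], clusters)
    }
  }
  m
}

.assign_planted_groups <- function(spec, ids) {
  n <- length(ids)
  n_trans <- length(spec$cell_types) - 1L
  group <- rep("stable", n)
  lfc <- matrix(0, nrow = n, ncol = max(n_trans, 1L))
  if (!is.null(spec$planted_groups)) {
    counts <- vapply(spec$planted_groups, function(g) as.integer(g$n), integer(1))
    picked <- sample.int(n, sum(counts))
    at <- 0L
    for (g in names(spec$planted_groups)) {
      idx <- picked[seq_len(counts[[g]]) + at]
      at <- at + counts[[g]]
      group[idx] <- g
      lfc[idx, ] <- matrix(spec$planted_groups[[g]]$lfc, nrow = length(idx),
                           ncol = n_trans, byrow = TRUE)
    }
  }
  list(group = group, lfc = lfc)
}

#' Simulate a miRNA count matrix with planted structure
#'
#' Counts are drawn NB(mu, dispersion) where mu is the cell-type mean
#' (baseline times the cumulative planted log2 fold changes, rescaled for any
#' planted cluster fractions) times a per-library depth factor. Reproducible
#' given `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @param mirna_ids Optional miRNA names (defaults to `sim-mir-001`, ...).
#' @param clusters Optional `cluster_table`, required when
#'   `spec$planted_cluster_fraction` is set.
#' @return list with `counts` (integer matrix, miRNA x sample),
#'   `sample_meta` (data.frame: sample_id, cell_type, replicate), and `truth`
#'   (per-miRNA group and planted log2 fold changes, expected cell-type
#'   means, expected cluster fractions, library factors).
#' @export
simulate_counts <- function(spec, mirna_ids = NULL, clusters = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  ids <- if (is.null(mirna_ids)) sprintf("sim-mir-%03d", seq_len(spec$n_mirnas))
         else mirna_ids
  if (length(ids) != spec$n_mirnas)
    stop("mirna_ids length must equal n_mirnas")
  withr::with_seed(spec$seed, {
    baseline <- stats::rlnorm(length(ids), meanlog = log(spec$baseline_mean),
                              sdlog = spec$baseline_sdlog)
    pg <- .assign_planted_groups(spec, ids)
    m <- .expected_means(spec, ids, baseline, pg$lfc, clusters)
    cell_type <- rep(spec$cell_types, spec$replicates)
    replicate <- unlist(lapply(spec$replicates, seq_len))
    sample_id <- paste0(cell_type, "_R", replicate)
    libf <- stats::rlnorm(length(sample_id), 0, spec$library_sdlog)
    counts <- matrix(0L, nrow = length(ids), ncol = length(sample_id),
                     dimnames = list(ids, sample_id))
    for (j in seq_along(sample_id)) {
      mu <- m[, cell_type[j]] * libf[j]
      counts[, j] <- if (spec$dispersion > 0)
        stats::rnbinom(length(ids), mu = mu, size = 1 / spec$dispersion)
      else stats::rpois(length(ids), mu)
    }
    truth_groups <- data.frame(mirna_id = ids, group = pg$group,
                               stringsAsFactors = FALSE)
    n_trans <- length(spec$cell_types) - 1L
    if (n_trans >= 1)
      for (t in seq_len(n_trans))
        truth_groups[[paste0("lfc", t)]] <- pg$lfc[, t]
    expected_frac <- NULL
    if (!is.null(spec$planted_cluster_fraction) && !is.null(clusters)) {
      expected_frac <- do.call(rbind, lapply(spec$cell_types, function(ct) {
        tot <- sum(m[, ct])
        agg <- tapply(m[, ct],
                      clusters$cluster_id[match(ids, clusters$mirna_id)],
                      sum)
        if (is.null(agg) || length(agg) == 0) return(NULL)
        data.frame(cell_type = ct, cluster_id = names(agg),
                   fraction = as.numeric(agg) / tot, stringsAsFactors = FALSE)
      }))
    }
    list(counts = counts,
         sample_meta = data.frame(sample_id = sample_id, cell_type = cell_type,
                                  replicate = replicate, stringsAsFactors = FALSE),
         truth = list(groups = truth_groups, cell_means = m,
                      cluster_fraction = expected_frac, library_factors = libf))
  })
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_dna <- function(x, rate) {
  if (rate <= 0) return(x)
  b <- strsplit(x, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(b)) < rate)
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  paste(b, collapse = "")
}

#' Simulate a single small-RNA library as reads
#'
#' Each read is a mature miRNA sequence (with per-base substitution errors)
#' followed by the 3' adapter and random filler up to `spec$read_length`; a
#' configurable fraction of reads instead derive from contaminant references
#' (random 16-27 nt fragments), lack the adapter, carry a low-quality (~Q6)
#' segment violating the 85%-above-Q10 rule, or start with Phred-2 bases that
#' the end-trim step must remove. Qualities follow a two-state model (high
#' ~Q34, low ~Q6). miRNA abundances follow the same log-normal spectrum and
#' planted cluster fractions as the count simulator.
#'
#' @param spec A [simulation_spec()].
#' @param mirnas `mirna_annotation` reference supplying mature sequences.
#' @param contaminants Optional contaminant reference (required when
#'   `spec$contaminant_fraction > 0`).
#' @param cell_type Cell state whose planted cluster fractions apply.
#' @param n_reads Number of reads.
#' @param clusters Optional `cluster_table` for fraction planting.
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return list with `read_id`, `bases`, `quals` (list of integer Phred
#'   vectors) and `truth` (per-read source and planted anomaly flags).
#' @export
simulate_reads <- function(spec, mirnas, contaminants = NULL,
                           cell_type = spec$cell_types[1],
                           n_reads = spec$n_reads, clusters = NULL,
                           seed = spec$seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (spec$contaminant_fraction > 0 && is.null(contaminants))
    stop("contaminant_fraction > 0 requires a contaminant reference")
  u <- unique(data.frame(mirna_id = mirnas$mirna_id, sequence = mirnas$sequence,
                         stringsAsFactors = FALSE))
  if (spec$read_length < min(nchar(u$sequence)) + 1L)
    stop("read_length shorter than the shortest mature sequence plus one adapter base")
  withr::with_seed(seed, {
    base <- stats::rlnorm(nrow(u), log(spec$baseline_mean), spec$baseline_sdlog)
    w <- base
    plant <- spec$planted_cluster_fraction
    if (!is.null(plant) && cell_type %in% plant$cell_type) {
      if (is.null(clusters))
        stop("planted_cluster_fraction requires a cluster table")
      w <- .plant_fractions(w, u$mirna_id,
                            plant[plant$cell_type == cell_type, , drop = FALSE],
                            clusters)
    }
    p <- w / sum(w)
    from_contam <- stats::runif(n_reads) < spec$contaminant_fraction
    adapterless <- stats::runif(n_reads) < spec$adapterless_fraction
    lowq <- stats::runif(n_reads) < spec$lowq_fraction
    end_low <- stats::runif(n_reads) < spec$end_low_fraction
    src <- character(n_reads)
    bases <- character(n_reads)
    quals <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      if (from_contam[i]) {
        k <- sample.int(nrow(contaminants), 1)
        src[i] <- contaminants$ref_id[k]
        cs <- chartr("U", "T", contaminants$sequence[k])
        len <- sample(16:27, 1)
        at <- sample.int(nchar(cs) - len + 1L, 1)
        insert <- substr(cs, at, at + len - 1L)
      } else {
        k <- sample.int(nrow(u), 1, prob = p)
        src[i] <- u$mirna_id[k]
        insert <- chartr("U", "T", u$sequence[k])
      }
      insert <- .mutate_dna(insert, spec$read_error_rate)
      tail_len <- spec$read_length - nchar(insert)
      tail_seq <- if (adapterless[i]) .random_dna(tail_len)
                  else substr(paste0(spec$adapter, .random_dna(max(tail_len, 1))),
                              1L, tail_len)
      bases[i] <- substr(paste0(insert, tail_seq), 1L, spec$read_length)
      q <- rep(34L, spec$read_length)
      if (lowq[i]) q[sample.int(spec$read_length, round(0.4 * spec$read_length))] <- 6L
      if (end_low[i]) q[seq_len(sample(1:2, 1))] <- 2L
      quals[[i]] <- q
    }
    list(read_id = sprintf("read_%06d", seq_len(n_reads)), bases = bases,
         quals = quals,
         truth = data.frame(read_id = sprintf("read_%06d", seq_len(n_reads)),
                            source_id = src,
                            source_class = ifelse(from_contam, "contaminant", "miRNA"),
                            adapterless = adapterless, lowq = lowq,
                            end_low = end_low, stringsAsFactors = FALSE))
  })
}

#' Write simulated reads as Phred+33 FASTQ
#'
#' @param reads Output of [simulate_reads()].
#' @param path Output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(reads$quals, function(q)
    intToUtf8(pmin(q, 93L) + 33L), character(1))
  x <- Biostrings::DNAStringSet(reads$bases)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Simulate a full multi-sample FASTQ experiment
#'
#' Writes one FASTQ per library (cell types x replicates from `spec`), a
#' sample sheet, and a per-read ground-truth table. The per-sample RNG seed
#' is derived deterministically from `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @param mirnas,contaminants,clusters As for [simulate_reads()].
#' @param out_dir Output directory (created if needed).
#' @return list with `sample_sheet` (data.frame incl. `fastq` paths) and
#'   `truth` (per-read source table with a `sample_id` column).
#' @export
simulate_experiment_fastq <- function(spec, mirnas, contaminants = NULL,
                                      clusters = NULL, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cell_type <- rep(spec$cell_types, spec$replicates)
  replicate <- unlist(lapply(spec$replicates, seq_len))
  sample_id <- paste0(cell_type, "_R", replicate)
  truth <- vector("list", length(sample_id))
  fastq <- file.path(out_dir, paste0(sample_id, ".fastq"))
  for (j in seq_along(sample_id)) {
    reads <- simulate_reads(spec, mirnas, contaminants,
                            cell_type = cell_type[j], clusters = clusters,
                            seed = spec$seed + 1000L * j)
    write_fastq(reads, fastq[j])
    reads$truth$sample_id <- sample_id[j]
    truth[[j]] <- reads$truth
  }
  sheet <- data.frame(sample_id = sample_id, cell_type = cell_type,
                      replicate = replicate, fastq = fastq,
                      stringsAsFactors = FALSE)
  utils::write.table(sheet, file.path(out_dir, "sample_sheet.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- do.call(rbind, truth)
  utils::write.table(truth, file.path(out_dir, "read_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(sample_sheet = sheet, truth = truth)
}
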
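# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive each quantity with naive enumeration and a
# different code style from the package internals.

# Longest common substring by full enumeration of substrings of `a`.
oracle_lcs <- function(a, b) {
  best <- 0L
  na <- nchar(a)
  for (i in seq_len(na)) for (j in i:na) {
    sub <- substr(a, i, j)
    if (nchar(sub) > best && grepl(sub, b, fixed = TRUE))
      best <- nchar(sub)
  }
  best
}

# Benjamini-Hochberg step-up by direct double loop over ranks.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  for (k in seq_len(n)) {
    vals <- numeric(0)
    for (m in k:n) vals <- c(vals, p[ord[m]] * n / m)
    adj[ord[k]] <- min(1, vals)
  }
  adj
}

# Single-linkage clustering of loci by all-pairs transitive closure.
# `loci` has columns mirna_id, chrom, start, end, strand.
oracle_single_linkage <- function(loci, max_gap, same_strand = TRUE) {
  n <- nrow(loci)
  linked <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    same <- loci$chrom[i] == loci$chrom[j] &&
      (!same_strand || loci$strand[i] == loci$strand[j])
    gap <- max(loci$start[i], loci$start[j]) - min(loci$end[i], loci$end[j]) - 1
    linked[i, j] <- same && gap <= max_gap
  }
  # transitive closure
  repeat {
    new <- linked | (linked %*% linked > 0)
    if (all(new == linked)) break
    linked <- new
  }
  comp <- rep(NA_integer_, n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      next_id <- next_id + 1L
      comp[linked[i, ]] <- next_id
    }
  }
  comp
}

# Group label from the 9-cell truth table.
oracle_group <- function(state1, state2) {
  tab <- list("UP.DOWN" = "G1", "DOWN.UP" = "G2", "UP.UP" = "G3",
              "UP.STABLE" = "G4", "DOWN.DOWN" = "G5", "DOWN.STABLE" = "G6",
              "STABLE.UP" = "G7", "STABLE.DOWN" = "G8",
              "STABLE.STABLE" = "unclassified")
  tab[[paste(state1, state2, sep = ".")]]
}

# --- exhaustive per-read preprocessing oracle -------------------------------

oracle_trim_adapter <- function(bases, quals, adapter) {
  rb <- strsplit(bases, "")[[1]]
  ab <- strsplit(adapter, "")[[1]]
  L <- length(rb)
  for (p in seq_len(L)) {
    ov <- min(length(ab), L - p + 1)
    if (ov < 6) break
    mism <- 0
    for (i in seq_len(ov)) if (rb[p + i - 1] != ab[i]) mism <- mism + 1
    if (mism <= 1)
      return(list(found = TRUE,
                  bases = paste(rb[seq_len(p - 1)], collapse = ""),
                  quals = quals[seq_len(p - 1)]))
  }
  list(found = FALSE)
}

oracle_quality <- function(bases, quals) {
  while (length(quals) > 0 && quals[1] < 5) {
    quals <- quals[-1]; bases <- substr(bases, 2, nchar(bases))
  }
  while (length(quals) > 0 && quals[length(quals)] < 5) {
    quals <- quals[-length(quals)]; bases <- substr(bases, 1, nchar(bases) - 1)
  }
  if (length(quals) == 0) return(list(status = "length_fail"))
  if (sum(quals >= 10) / length(quals) < 0.85)
    return(list(status = "quality_fail"))
  if (length(quals) < 16 || length(quals) > 27)
    return(list(status = "length_fail"))
  list(status = "pass", bases = bases)
}

oracle_min_mm <- function(read, ref) {
  rb <- strsplit(read, "")[[1]]
  fb <- strsplit(ref, "")[[1]]
  if (length(fb) < length(rb)) return(Inf)
  best <- Inf
  for (off in 0:(length(fb) - length(rb))) {
    mm <- sum(rb != fb[(off + 1):(off + length(rb))])
    if (mm < best) best <- mm
  }
  best
}

# Full chain for one read; mirna_seqs / contam_seqs are named DNA-alphabet
# character vectors. Returns list(status, targets, weights).
oracle_process_read <- function(bases, quals, adapter, mirna_seqs,
                                contam_seqs, max_mm = 1) {
  tr <- oracle_trim_adapter(bases, quals, adapter)
  if (!tr$found) return(list(status = "no_adapter"))
  qf <- oracle_quality(tr$bases, tr$quals)
  if (qf$status != "pass") return(list(status = qf$status))
  mir_mm <- vapply(mirna_seqs, oracle_min_mm, numeric(1), read = qf$bases)
  con_mm <- if (length(contam_seqs))
    vapply(contam_seqs, oracle_min_mm, numeric(1), read = qf$bases)
  else Inf
  if (min(mir_mm) > max_mm && min(con_mm) > max_mm)
    return(list(status = "unmatched"))
  if (min(con_mm) < min(mir_mm))
    return(list(status = "contaminant_excluded"))
  hits <- names(mir_mm)[mir_mm == min(mir_mm)]
  list(status = "counted", targets = hits,
       weights = rep(1 / length(hits), length(hits)))
}
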
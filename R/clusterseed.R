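#' Cluster and family contributions to the miRNA population
#'
#' For each cell state, each genomic cluster's (or seed family's)
#' contribution is the summed mean normalized count of its members divided
#' by the summed mean normalized count of all miRNAs in the analysis
#' universe; unclustered reads fall into an "unassigned" unit so fractions
#' always sum to one. A seed-similarity report compares clusters pairwise by
#' their best member-seed pair.
#'
#' @name clusterseed
#' @keywords internal
NULL

# Mean normalized count per miRNA per cell type.
.celltype_means <- function(norm, mirnas = NULL) {
  meta <- norm$sample_meta
  if (is.null(mirnas)) mirnas <- rownames(norm$normalized)
  types <- unique(meta$cell_type)
  m <- vapply(types, function(ct)
    rowMeans(norm$normalized[mirnas, meta$sample_id[meta$cell_type == ct],
                             drop = FALSE]),
    numeric(length(mirnas)))
  rownames(m) <- mirnas
  m
}

.unit_contributions <- function(norm, unit_of, mirnas) {
  mu <- .celltype_means(norm, mirnas)
  units <- unit_of[mirnas]
  units[is.na(units)] <- "unassigned"
  out <- do.call(rbind, lapply(colnames(mu), function(ct) {
    tot <- sum(mu[, ct])
    if (tot <= 0)
      stop(sprintf("cell type %s has zero total normalized counts", ct))
    agg <- tapply(mu[, ct], units, sum)
    data.frame(cell_type = ct, unit_id = names(agg),
               fraction = as.numeric(agg) / tot, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$cell_type, out$unit_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contribution_table", "data.frame")
  out
}

#' Relative contribution of miRNA clusters per cell type
#'
#' @param norm A [normalize_counts()] result (pass only retained miRNAs via
#'   `mirnas` to work in the post-filter universe).
#' @param clusters A `cluster_table`.
#' @param mirnas Optional analysis universe (default: all matrix rows).
#' @return data.frame of class `contribution_table` with columns
#'   `cell_type`, `unit_id`, `fraction`; per cell type the fractions
#'   (including `"unassigned"`) sum to 1.
#' @export
cluster_contributions <- function(norm, clusters, mirnas = NULL) {
  if (is.null(mirnas)) mirnas <- rownames(norm$normalized)
  missing <- setdiff(clusters$mirna_id, rownames(norm$normalized))
  if (length(missing))
    warning("cluster members absent from the matrix, skipped: ",
            paste(missing, collapse = ", "))
  unit_of <- stats::setNames(clusters$cluster_id, clusters$mirna_id)
  .unit_contributions(norm, unit_of, mirnas)
}

#' Relative contribution of seed families per cell type
#'
#' Every miRNA belongs to exactly one seed family, so the unassigned
#' fraction is zero whenever the family table covers the analysis universe.
#'
#' @param norm A [normalize_counts()] result.
#' @param families Output of [assign_families()].
#' @param mirnas Optional analysis universe.
#' @return A `contribution_table` data.frame.
#' @export
family_contributions <- function(norm, families, mirnas = NULL) {
  if (is.null(mirnas)) mirnas <- rownames(norm$normalized)
  unit_of <- stats::setNames(families$family_id, families$mirna_id)
  .unit_contributions(norm, unit_of, mirnas)
}

#' Pairwise cluster seed-similarity report
#'
#' For every pair of clusters (including each cluster with itself) all
#' member-seed pairs are scored with [seed_similarity()] and the best
#' (maximum-score) pair is reported; ties resolve to the lexicographically
#' first member pair.
#'
#' @param clusters A `cluster_table`.
#' @param mirnas A `mirna_annotation` supplying member seeds.
#' @return data.frame with columns `cluster_a`, `cluster_b`, `mirna_a`,
#'   `mirna_b`, `seed_a`, `seed_b`, `score`, `category`; symmetric, with an
#'   `identical` diagonal.
#' @export
cluster_seed_report <- function(clusters, mirnas) {
  if (nrow(clusters) == 0) stop("cluster table is empty")
  seed_of <- stats::setNames(mirnas$seed, mirnas$mirna_id)
  ids <- unique(clusters$cluster_id)
  members <- split(clusters$mirna_id, clusters$cluster_id)[ids]
  rows <- list()
  for (a in ids) for (b in ids) {
    best <- NULL
    for (ma in sort(members[[a]])) for (mb in sort(members[[b]])) {
      s <- seed_similarity(seed_of[[ma]], seed_of[[mb]])
      if (is.null(best) || s$score > best$score ||
          (s$score == best$score && s$category == "identical" &&
           best$category != "identical")) {
        best <- list(mirna_a = ma, mirna_b = mb, seed_a = seed_of[[ma]],
                     seed_b = seed_of[[mb]], score = s$score,
                     category = s$category)
      }
    }
    rows[[paste(a, b)]] <- data.frame(cluster_a = a, cluster_b = b,
                                      mirna_a = best$mirna_a,
                                      mirna_b = best$mirna_b,
                                      seed_a = best$seed_a,
                                      seed_b = best$seed_b,
                                      score = best$score,
                                      category = best$category,
                                      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Diversity summary of a contribution table
#'
#' Per cell type: the top-k units by fraction (excluding "unassigned"),
#' their cumulative fraction, and the effective number of units, defined as
#' exp of the Shannon entropy of the unit fractions renormalized over
#' assigned units. A state dominated by one cluster has effective number
#' near 1; a state spread over many clusters has a larger effective number.
#'
#' @param contrib A `contribution_table`.
#' @param top_k How many top units to list (default 3).
#' @return data.frame with columns `cell_type`, `top_units`
#'   (comma-separated), `top_fraction`, `effective_units`.
#' @export
diversity_summary <- function(contrib, top_k = 3L) {
  out <- do.call(rbind, lapply(unique(contrib$cell_type), function(ct) {
    x <- contrib[contrib$cell_type == ct & contrib$unit_id != "unassigned", ,
                 drop = FALSE]
    x <- x[order(-x$fraction, x$unit_id), , drop = FALSE]
    f <- x$fraction[x$fraction > 0]
    f <- f / sum(f)
    eff <- exp(-sum(f * log(f)))
    top <- utils::head(x, top_k)
    data.frame(cell_type = ct,
               top_units = paste(top$unit_id, collapse = ","),
               top_fraction = sum(top$fraction),
               effective_units = eff, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
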
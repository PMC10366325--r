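#' Expression-trajectory classification
#'
#' Each retained miRNA gets a transition state for each of the two
#' developmental contrasts - UP (padj < 0.05 and log2fc > +0.6), DOWN
#' (padj < 0.05 and log2fc < -0.6), otherwise STABLE - and the pair of
#' states maps to one of eight trajectory groups: G1/G2 change only at the
#' first transition (specific to the self-renewing state), G3-G6 change
#' during differentiation, G7/G8 are stable in stem states and change only
#' with terminal differentiation. The (STABLE, STABLE) pair is unclassified.
#'
#' @name trajectory
#' @keywords internal
NULL

#' Default (state1, state2) to group mapping
#'
#' @return data.frame with columns `state1`, `state2`, `group` covering the
#'   eight non-(STABLE, STABLE) pairs.
#' @export
default_group_mapping <- function() {
  data.frame(
    state1 = c("UP", "DOWN", "UP", "UP", "DOWN", "DOWN", "STABLE", "STABLE"),
    state2 = c("DOWN", "UP", "UP", "STABLE", "DOWN", "STABLE", "UP", "DOWN"),
    group = paste0("G", 1:8),
    stringsAsFactors = FALSE
  )
}

#' Read a group mapping from TSV
#'
#' @param path TSV with columns `state1`, `state2`, `group`.
#' @return Validated mapping data.frame.
#' @export
read_group_mapping <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("state1", "state2", "group") %in% names(m)))
    stop("group mapping needs columns state1, state2, group")
  if (anyDuplicated(m[, c("state1", "state2")]))
    stop("group mapping must be injective over (state1, state2) pairs")
  m
}

#' Transition state from a contrast result
#'
#' Thresholds are strict, matching the printed criteria: UP requires
#' padj < p_thresh and log2fc > fc_thresh; DOWN requires padj < p_thresh
#' and log2fc < -fc_thresh.
#'
#' @param log2fc,padj Numeric vectors.
#' @param p_thresh,fc_thresh Significance and fold-change thresholds
#'   (defaults 0.05 and 0.6).
#' @return Character vector over {"UP", "DOWN", "STABLE"}.
#' @export
transition_state <- function(log2fc, padj, p_thresh = 0.05, fc_thresh = 0.6) {
  ifelse(padj < p_thresh & log2fc > fc_thresh, "UP",
         ifelse(padj < p_thresh & log2fc < -fc_thresh, "DOWN", "STABLE"))
}

#' Classify miRNAs into trajectory groups
#'
#' @param de1,de2 [nb_test()] results for the two contrasts; they must cover
#'   the same miRNA universe.
#' @param p_thresh,fc_thresh Thresholds (defaults 0.05, 0.6; strict).
#' @param mapping Group mapping (default [default_group_mapping()]).
#' @return data.frame with columns `mirna_id`, `state1`, `state2`, `group`
#'   (`"unclassified"` for the (STABLE, STABLE) pair or any unmapped pair).
#' @export
classify_trajectories <- function(de1, de2, p_thresh = 0.05, fc_thresh = 0.6,
                                  mapping = default_group_mapping()) {
  if (!setequal(de1$mirna_id, de2$mirna_id) ||
      nrow(de1) != nrow(de2))
    stop("the two contrasts must cover the same miRNA universe")
  de2 <- de2[match(de1$mirna_id, de2$mirna_id), , drop = FALSE]
  state1 <- transition_state(de1$log2fc, de1$padj, p_thresh, fc_thresh)
  state2 <- transition_state(de2$log2fc, de2$padj, p_thresh, fc_thresh)
  key <- paste(state1, state2)
  map_key <- paste(mapping$state1, mapping$state2)
  group <- mapping$group[match(key, map_key)]
  group[is.na(group)] <- "unclassified"
  data.frame(mirna_id = de1$mirna_id, state1 = state1, state2 = state2,
             group = group, stringsAsFactors = FALSE)
}

#' Top significantly changed miRNAs of one contrast
#'
#' Significant miRNAs (padj < `p_thresh`) of the requested sign, ordered by
#' ascending padj, ties broken by |log2fc| descending then mirna_id
#' ascending, truncated to `n`.
#'
#' @param de A [nb_test()] result.
#' @param direction "up" (log2fc > 0) or "down" (log2fc < 0).
#' @param n Maximum list length.
#' @param p_thresh Significance threshold (default 0.05).
#' @return Character vector of miRNA ids (possibly shorter than `n`).
#' @export
top_ranked <- function(de, direction = c("up", "down"), n = 20L,
                       p_thresh = 0.05) {
  direction <- match.arg(direction)
  if (n < 1) stop("n must be >= 1")
  sig <- de[de$padj < p_thresh &
              (if (direction == "up") de$log2fc > 0 else de$log2fc < 0), ,
            drop = FALSE]
  ord <- order(sig$padj, -abs(sig$log2fc), sig$mirna_id)
  utils::head(sig$mirna_id[ord], n)
}

#' Export volcano, heatmap, and group-membership tables
#'
#' The heatmap values are per-miRNA z-scores of log2(mean normalized count
#' + 1) across the cell types (a miRNA with equal means in all types gets an
#' all-zero row).
#'
#' @param calls [classify_trajectories()] output.
#' @param de1,de2 The two contrast results.
#' @param norm A [normalize_counts()] result.
#' @return list with data.frames `volcano`, `heatmap`, `groups`.
#' @export
trajectory_tables <- function(calls, de1, de2, norm) {
  volcano <- rbind(
    de1[, c("mirna_id", "log2fc", "pvalue", "padj", "contrast")],
    de2[, c("mirna_id", "log2fc", "pvalue", "padj", "contrast")]
  )
  meta <- norm$sample_meta
  types <- unique(meta$cell_type)
  mu <- vapply(types, function(ct)
    rowMeans(norm$normalized[calls$mirna_id,
                             meta$sample_id[meta$cell_type == ct],
                             drop = FALSE]),
    numeric(nrow(calls)))
  mu <- matrix(mu, nrow = nrow(calls),
               dimnames = list(calls$mirna_id, types))
  lg <- log2(mu + 1)
  ctr <- lg - rowMeans(lg)
  sdv <- apply(lg, 1, stats::sd)
  z <- ctr / ifelse(sdv > 0, sdv, 1)
  heatmap <- data.frame(mirna_id = calls$mirna_id, z,
                        check.names = FALSE, stringsAsFactors = FALSE)
  list(volcano = volcano, heatmap = heatmap, groups = calls)
}

#' Population doubling time from two time points
#'
#' Computed over the growth window (default 48 h between day 2 and day 4)
#' as `hours * ln(2) / ln(n_end / n_start)`.
#'
#' @param n_start,n_end Cell counts at the start and end of the window.
#' @param hours Window length in hours (default 48).
#' @return Doubling time in hours.
#' @examples
#' doubling_time(100, 200)  # 48 h
#' doubling_time(100, 800)  # 16 h
#' @export
doubling_time <- function(n_start, n_end, hours = 48) {
  if (any(n_start <= 0) || any(n_end <= 0))
    stop("cell counts must be positive")
  if (any(n_end <= n_start))
    stop("no growth over the window: n_end must exceed n_start")
  hours * log(2) / log(n_end / n_start)
}
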
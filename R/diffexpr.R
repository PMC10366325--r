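#' Normalization, abundance filtering, and the NB Wald test
#'
#' Normalization is median-of-ratios (per-sample size factors rescaled to
#' geometric mean 1). Differential expression between two cell states is a
#' negative-binomial Wald test: size-factor-weighted group means, pooled
#' method-of-moments dispersion shrunk 50/50 toward a fitted mean-dispersion
#' trend a0/mu + a1, log2 fold change with a 0.5 pseudo-mean, delta-method
#' standard error, two-sided normal p-value, and Benjamini-Hochberg
#' adjustment within each contrast.
#'
#' @name diffexpr
#' @keywords internal
NULL

#' Median-of-ratios normalization
#'
#' For every miRNA with strictly positive counts in all samples a
#' per-sample ratio to the gene's geometric mean is formed; the per-sample
#' size factor is the median of those ratios, rescaled so the size factors
#' have geometric mean 1. Normalized counts are raw counts divided by the
#' size factor.
#'
#' @param counts Non-negative integer matrix, miRNA x sample.
#' @param sample_meta data.frame with columns `sample_id`, `cell_type`,
#'   `replicate` matching the matrix columns.
#' @return list of class `norm_matrix` with `counts`, `normalized`,
#'   `size_factors`, `sample_meta`.
#' @export
normalize_counts <- function(counts, sample_meta) {
  if (ncol(counts) < 2) stop("need at least two samples")
  if (!all(colnames(counts) == sample_meta$sample_id))
    stop("sample_meta must match count-matrix columns (same order)")
  pos <- rowSums(counts <= 0) == 0
  if (!any(pos))
    stop(paste("no miRNA has positive counts in every sample;",
               "consider a pseudo-reference fallback on a filtered matrix"))
  ref <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
  ratios <- counts[pos, , drop = FALSE] / ref
  sf <- apply(ratios, 2, stats::median)
  sf <- sf / exp(mean(log(sf)))
  out <- list(counts = counts,
              normalized = sweep(counts, 2, sf, "/"),
              size_factors = stats::setNames(sf, colnames(counts)),
              sample_meta = sample_meta)
  class(out) <- "norm_matrix"
  out
}

#' Abundance filter
#'
#' Keeps a miRNA iff some cell type has at least `min_samples` samples with
#' normalized counts strictly above `threshold`. A cell type with fewer than
#' `min_samples` samples triggers a warning and can never qualify a miRNA on
#' its own.
#'
#' @param norm A [normalize_counts()] result.
#' @param threshold Normalized-count threshold (default 50, strict).
#' @param min_samples Minimum qualifying samples within one cell type
#'   (default 2).
#' @return Character vector of retained miRNA ids.
#' @export
abundance_filter <- function(norm, threshold = 50, min_samples = 2L) {
  meta <- norm$sample_meta
  keep <- rep(FALSE, nrow(norm$normalized))
  for (ct in unique(meta$cell_type)) {
    cols <- meta$sample_id[meta$cell_type == ct]
    if (length(cols) < min_samples) {
      warning(sprintf("cell type %s has fewer than %d samples and cannot qualify miRNAs",
                      ct, min_samples))
      next
    }
    keep <- keep |
      rowSums(norm$normalized[, cols, drop = FALSE] > threshold) >= min_samples
  }
  rownames(norm$normalized)[keep]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  pmin(1, cummin(p[o] * n / seq.int(n, 1)))[order(o)]
}

#' Negative-binomial Wald test between two cell states
#'
#' Per miRNA: group means are size-factor-weighted means of raw counts
#' (sum of counts over sum of size factors); the dispersion is the pooled
#' within-group method-of-moments residual estimate, floored at 1e-8 and
#' shrunk 50/50 toward the least-squares mean-dispersion trend
#' a0/mu + a1 fitted over all tested miRNAs; the log2 fold change uses a
#' 0.5 pseudo-mean; the Wald statistic divides it by a delta-method standard
#' error and is referred to the standard normal (two-sided). p-values are
#' BH-adjusted within the contrast. A miRNA with zero counts in both groups
#' reports log2fc 0 and p 1.
#'
#' @param norm A [normalize_counts()] result.
#' @param group_a,group_b Cell types to contrast; positive log2 fold change
#'   means higher in `group_b`.
#' @param mirnas Optional miRNA ids to test (e.g. from
#'   [abundance_filter()]); defaults to all rows.
#' @param contrast Label stored in the result (default "b_vs_a").
#' @return data.frame with columns `mirna_id`, `baseMean_a`, `baseMean_b`,
#'   `log2fc`, `se`, `pvalue`, `padj`, `contrast`.
#' @export
nb_test <- function(norm, group_a, group_b, mirnas = NULL, contrast = NULL) {
  meta <- norm$sample_meta
  for (g in c(group_a, group_b))
    if (sum(meta$cell_type == g) < 2)
      stop(sprintf("group %s needs at least 2 samples", g))
  if (is.null(mirnas)) mirnas <- rownames(norm$counts)
  if (is.null(contrast)) contrast <- paste0(group_b, "_vs_", group_a)
  ca <- meta$sample_id[meta$cell_type == group_a]
  cb <- meta$sample_id[meta$cell_type == group_b]
  K_a <- norm$counts[mirnas, ca, drop = FALSE]
  K_b <- norm$counts[mirnas, cb, drop = FALSE]
  s_a <- norm$size_factors[ca]
  s_b <- norm$size_factors[cb]
  mu_a <- rowSums(K_a) / sum(s_a)
  mu_b <- rowSums(K_b) / sum(s_b)
  z_a <- sweep(K_a, 2, s_a, "/")
  z_b <- sweep(K_b, 2, s_b, "/")
  n_a <- length(ca); n_b <- length(cb)
  v_a <- apply(z_a, 1, stats::var)
  v_b <- apply(z_b, 1, stats::var)
  df <- n_a + n_b - 2
  v_pool <- ((n_a - 1) * v_a + (n_b - 1) * v_b) / df
  w_mu <- ((n_a - 1) * mu_a + (n_b - 1) * mu_b) / df
  w_mu2 <- ((n_a - 1) * mu_a^2 + (n_b - 1) * mu_b^2) / df
  alpha_raw <- (v_pool - w_mu) / w_mu2
  mu_all <- (rowSums(K_a) + rowSums(K_b)) / (sum(s_a) + sum(s_b))
  fit_ok <- is.finite(alpha_raw) & mu_all > 0
  # One-step bias correction: E[mu_hat^2] exceeds mu^2 by Var(mu_hat), which
  # deflates the moment estimate by a few percent; subtract a plug-in
  # estimate of that variance from the squared-mean denominator.
  plug <- if (any(fit_ok)) max(mean(alpha_raw[fit_ok]), 0) else 0
  var_hat_a <- (mu_a * sum(s_a) + plug * mu_a^2 * sum(s_a^2)) / sum(s_a)^2
  var_hat_b <- (mu_b * sum(s_b) + plug * mu_b^2 * sum(s_b^2)) / sum(s_b)^2
  w_mu2_c <- ((n_a - 1) * (mu_a^2 - var_hat_a) +
                (n_b - 1) * (mu_b^2 - var_hat_b)) / df
  w_mu2_c <- ifelse(w_mu2_c > 0, w_mu2_c, w_mu2)
  alpha_gene <- (v_pool - w_mu) / w_mu2_c
  # Pool the gene-wise moment estimates across miRNAs (a 4-6 df gene-wise
  # dispersion is far too noisy to plug into a Wald SE on its own), then
  # shrink 50/50 toward the fitted mean-dispersion trend a0/mu + a1.
  pooled <- if (any(fit_ok)) max(mean(alpha_gene[fit_ok]), 1e-8) else 1e-8
  alpha_trend <- rep(pooled, length(mirnas))
  if (sum(fit_ok) >= 2) {
    X <- cbind(1 / mu_all[fit_ok], 1)
    coefs <- stats::lm.fit(X, alpha_gene[fit_ok])$coefficients
    alpha_trend <- coefs[1] / mu_all + coefs[2]
  }
  alpha <- 0.5 * pooled + 0.5 * pmax(alpha_trend, 1e-8)
  alpha[!is.finite(alpha)] <- pooled
  eps <- 0.5
  log2fc <- log2((mu_b + eps) / (mu_a + eps))
  var_mu_a <- (sum(s_a) * mu_a + alpha * mu_a^2 * sum(s_a^2)) / sum(s_a)^2
  var_mu_b <- (sum(s_b) * mu_b + alpha * mu_b^2 * sum(s_b^2)) / sum(s_b)^2
  se <- sqrt(var_mu_a / (mu_a + eps)^2 + var_mu_b / (mu_b + eps)^2) / log(2)
  stat <- ifelse(se > 0, log2fc / se, 0)
  pvalue <- 2 * stats::pnorm(-abs(stat))
  both_zero <- mu_a == 0 & mu_b == 0
  log2fc[both_zero] <- 0
  pvalue[both_zero] <- 1
  se[both_zero] <- NA_real_
  out <- data.frame(mirna_id = mirnas, baseMean_a = mu_a, baseMean_b = mu_b,
                    log2fc = log2fc, se = se, pvalue = pvalue,
                    padj = bh_adjust(pvalue), contrast = contrast,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Run the two developmental contrasts
#'
#' Contrast 1 compares the second cell state over the first (positive log2
#' fold change = higher in the second state); contrast 2 compares the third
#' over the second.
#'
#' @param norm A [normalize_counts()] result.
#' @param design Ordered character vector of the three cell types, e.g.
#'   `c("hESC", "NSC", "DiffNSC")`.
#' @param mirnas Optional retained miRNA ids (see [abundance_filter()]).
#' @return list with elements `de1` and `de2` (data.frames from
#'   [nb_test()]).
#' @export
run_contrasts <- function(norm, design = c("hESC", "NSC", "DiffNSC"),
                          mirnas = NULL) {
  if (length(design) != 3)
    stop("design must name three ordered cell types")
  missing <- setdiff(design, unique(norm$sample_meta$cell_type))
  if (length(missing))
    stop("cell type(s) absent from the data: ", paste(missing, collapse = ", "))
  list(de1 = nb_test(norm, design[1], design[2], mirnas),
       de2 = nb_test(norm, design[2], design[3], mirnas))
}

#' Write a differential-expression table as TSV
#'
#' @param de A [nb_test()] result.
#' @param path Output path.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
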
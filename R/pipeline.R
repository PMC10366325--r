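#' End-to-end orchestration
#'
#' A validated YAML config drives the fixed stage order: load references ->
#' (optionally) simulate reads -> preprocess -> normalize + filter ->
#' contrasts -> trajectory classification -> cluster/family contributions ->
#' run report. Outputs are deterministic given the config seed.
#'
#' @name pipeline
#' @keywords internal
NULL

.config_defaults <- function() {
  list(
    mature_fasta = NULL, loci_gff = NULL, contaminant_fasta = NULL,
    cluster_table = NULL, sample_sheet = NULL, count_matrix = NULL,
    sample_meta = NULL, simulate_reads = FALSE,
    design = c("hESC", "NSC", "DiffNSC"),
    adapter = "AGATCGGAAGAGCACACGTCT",
    end_trim_phred = 5, min_phred = 10, min_fraction = 0.85,
    min_len = 16, max_len = 27, max_mismatches = 1,
    filter_threshold = 50, filter_min_samples = 2,
    p_thresh = 0.05, lfc_thresh = 0.6,
    cluster_gap = 10000, n_reads = 2000,
    seed = 1, outdir = "mirtraj_out"
  )
}

#' Validate a run configuration
#'
#' Accepts a YAML path or a named list; unknown keys are rejected and all
#' problems are reported at once.
#'
#' @param config YAML file path or named list.
#' @return Validated config list of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- .config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  errs <- character(0)
  if (length(unknown))
    errs <- c(errs, paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  num_ge0 <- c(end_trim_phred = NA, min_phred = NA, max_mismatches = NA,
               filter_threshold = NA, lfc_thresh = NA, cluster_gap = NA)
  for (k in names(num_ge0))
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 0)
      errs <- c(errs, sprintf("%s must be a number >= 0", k))
  if (!is.numeric(cfg$min_fraction) || cfg$min_fraction <= 0 || cfg$min_fraction > 1)
    errs <- c(errs, "min_fraction must lie in (0, 1]")
  if (!is.numeric(cfg$p_thresh) || cfg$p_thresh <= 0 || cfg$p_thresh > 1)
    errs <- c(errs, "p_thresh must lie in (0, 1]")
  if (!is.numeric(cfg$min_len) || !is.numeric(cfg$max_len) ||
      cfg$min_len > cfg$max_len)
    errs <- c(errs, "min_len must be <= max_len")
  if (!is.numeric(cfg$filter_min_samples) || cfg$filter_min_samples < 1)
    errs <- c(errs, "filter_min_samples must be >= 1")
  if (length(cfg$design) != 3)
    errs <- c(errs, "design must list three ordered cell types")
  if (!is.null(cfg$sample_sheet) && !is.null(cfg$count_matrix))
    errs <- c(errs, "sample_sheet and count_matrix are exclusive entry points: choose one")
  if (is.null(cfg$sample_sheet) && is.null(cfg$count_matrix) &&
      !isTRUE(cfg$simulate_reads))
    errs <- c(errs, "no entry point: set sample_sheet, count_matrix, or simulate_reads")
  if (is.null(cfg$mature_fasta))
    errs <- c(errs, "mature_fasta is required")
  if (nchar(cfg$adapter) < 6)
    errs <- c(errs, "adapter must be at least 6 nt")
  if (length(errs)) stop(paste(errs, collapse = "\n"))
  class(cfg) <- c("run_config", "list")
  cfg
}

.log_line <- function(stage, msg, logfile = NULL) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE, sep = "")
  invisible(line)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Stages run in a fixed order and any failure aborts with the stage name.
#' All outputs are TSV files under `config$outdir` plus a YAML run report
#' with per-stage record counts.
#'
#' @param config A [validate_config()]-validated config (or raw list/path,
#'   validated here).
#' @return Invisibly, the run report list.
#' @export
run_all <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(cfg$outdir, "run.log")
  if (file.exists(logfile)) unlink(logfile)
  report <- list(parameters = unclass(cfg), stages = list())
  stage <- function(name, expr) {
    .log_line(name, "start", logfile)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  ann <- stage("reference", {
    a <- load_mirna_reference(cfg$mature_fasta, cfg$loci_gff)
    .log_line("reference", sprintf("%d mature miRNAs, %d with loci",
                                   length(unique(a$mirna_id)),
                                   sum(!is.na(a$chrom))), logfile)
    a
  })
  clusters <- stage("clusters", {
    cl <- if (!is.null(cfg$cluster_table)) read_cluster_table(cfg$cluster_table)
          else derive_clusters(ann, max_gap_bp = cfg$cluster_gap)
    .log_line("clusters", sprintf("%d clusters / %d clustered miRNAs",
                                  length(unique(cl$cluster_id)), nrow(cl)), logfile)
    cl
  })
  contaminants <- if (!is.null(cfg$contaminant_fasta))
    load_contaminants(cfg$contaminant_fasta) else NULL
  report$stages$reference <- list(mirnas = length(unique(ann$mirna_id)),
                                  clusters = length(unique(clusters$cluster_id)))

  params <- filter_params(cfg$adapter, cfg$end_trim_phred, cfg$min_phred,
                          cfg$min_fraction, cfg$min_len, cfg$max_len,
                          cfg$max_mismatches)

  if (!is.null(cfg$count_matrix)) {
    entry <- stage("load_counts", {
      tab <- utils::read.delim(cfg$count_matrix, check.names = FALSE)
      counts <- as.matrix(tab[, -1, drop = FALSE])
      rownames(counts) <- tab[[1]]
      storage.mode(counts) <- "integer"
      meta <- utils::read.delim(cfg$sample_meta %||% stop("count_matrix entry needs sample metadata"))
      list(counts = counts, sample_meta = meta)
    })
  } else {
    sheet <- if (isTRUE(cfg$simulate_reads)) {
      stage("simulate", {
        spec <- simulation_spec(adapter = cfg$adapter, seed = cfg$seed,
                                n_reads = cfg$n_reads)
        sim <- simulate_experiment_fastq(spec, ann, contaminants, clusters,
                                         out_dir = file.path(cfg$outdir, "fastq"))
        .log_line("simulate", sprintf("%d libraries x %d reads",
                                      nrow(sim$sample_sheet), cfg$n_reads), logfile)
        sim$sample_sheet
      })
    } else {
      utils::read.delim(cfg$sample_sheet, stringsAsFactors = FALSE)
    }
    entry <- stage("preprocess", {
      res <- build_count_matrix(sheet, ann, contaminants, params)
      .write_tsv(res$report, file.path(cfg$outdir, "filter_report.tsv"))
      counts_df <- data.frame(mirna_id = rownames(res$counts), res$counts,
                              check.names = FALSE)
      .write_tsv(counts_df, file.path(cfg$outdir, "counts.tsv"))
      total_in <- sum(res$report$n_reads)
      .log_line("preprocess",
                sprintf("%d reads in, %d counted",
                        total_in,
                        sum(res$report$n_reads[res$report$status == "counted"])),
                logfile)
      report$stages$preprocess <- list(
        reads_in = total_in,
        by_status = stats::setNames(
          as.list(tapply(res$report$n_reads, res$report$status, sum)), NULL))
      list(counts = res$counts, sample_meta = res$sample_meta)
    })
  }

  de <- stage("diffexpr", {
    norm <- normalize_counts(entry$counts, entry$sample_meta)
    retained <- abundance_filter(norm, cfg$filter_threshold,
                                 cfg$filter_min_samples)
    .log_line("diffexpr", sprintf("%d of %d miRNAs pass the abundance filter",
                                  length(retained), nrow(entry$counts)), logfile)
    if (length(retained) < 2) stop("fewer than two miRNAs pass the filter")
    cons <- run_contrasts(norm, cfg$design, retained)
    .write_tsv(cons$de1, file.path(cfg$outdir, "de_contrast1.tsv"))
    .write_tsv(cons$de2, file.path(cfg$outdir, "de_contrast2.tsv"))
    report$stages$diffexpr <- list(retained = length(retained),
                                    tested = nrow(cons$de1))
    list(norm = norm, retained = retained, de1 = cons$de1, de2 = cons$de2)
  })

  calls <- stage("trajectory", {
    cl <- classify_trajectories(de$de1, de$de2, cfg$p_thresh, cfg$lfc_thresh)
    tabs <- trajectory_tables(cl, de$de1, de$de2, de$norm)
    .write_tsv(tabs$volcano, file.path(cfg$outdir, "volcano.tsv"))
    .write_tsv(tabs$heatmap, file.path(cfg$outdir, "heatmap.tsv"))
    .write_tsv(tabs$groups, file.path(cfg$outdir, "trajectory_groups.tsv"))
    .log_line("trajectory",
              sprintf("%d classified / %d unclassified",
                      sum(cl$group != "unclassified"),
                      sum(cl$group == "unclassified")), logfile)
    report$stages$trajectory <- as.list(table(cl$group))
    cl
  })

  stage("clusterseed", {
    contrib <- cluster_contributions(de$norm, clusters, de$retained)
    fams <- assign_families(ann)
    famc <- family_contributions(de$norm, fams, de$retained)
    .write_tsv(contrib, file.path(cfg$outdir, "cluster_contributions.tsv"))
    .write_tsv(famc, file.path(cfg$outdir, "family_contributions.tsv"))
    .write_tsv(diversity_summary(contrib),
               file.path(cfg$outdir, "cluster_diversity.tsv"))
    present <- clusters[clusters$mirna_id %in% de$retained, , drop = FALSE]
    if (nrow(present) > 0)
      .write_tsv(cluster_seed_report(present, ann),
                 file.path(cfg$outdir, "cluster_seed_similarity.tsv"))
    report$stages$clusterseed <- list(
      clusters_reported = length(setdiff(unique(contrib$unit_id), "unassigned")))
    NULL
  })

  report$software <- list(package = "mirtraj",
                          version = as.character(utils::packageVersion("mirtraj")))
  yaml::write_yaml(report, file.path(cfg$outdir, "run_report.yaml"))
  .log_line("report", sprintf("written to %s", cfg$outdir), logfile)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
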
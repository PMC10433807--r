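#' Run the amplicon transfer analysis end to end
#'
#' Builds the cohort, detects transfer events at the threshold, counts them
#' per dyad, summarises them per ASV, runs the group comparisons
#' (Kruskal-Wallis + Dunn by delivery mode and by intrapartum antibiotics),
#' and assembles the cohort-level headline block (dyads with at least one
#' event, their fraction, and the range/median of per-dyad counts among
#' positive dyads).
#'
#' @param table a [feature_table()] or path readable by
#'   [read_feature_table()].
#' @param meta sample metadata tibble or TSV path.
#' @param taxonomy optional taxonomy tibble or path; when absent the
#'   summary carries `"unassigned"` labels (with a warning).
#' @param threshold relative-abundance threshold (default 0.001).
#' @param inclusive inclusive (`>=`, default) or strict gate.
#' @param orientation passed to [read_feature_table()] when `table` is a
#'   path.
#' @param out_dir optional directory; when given, writes `events.tsv`,
#'   `summary.tsv`, `per_dyad.tsv`, `stats.json` and `manifest.json`.
#' @return list of class `transfer_report`: `$cohort`, `$events`,
#'   `$per_dyad`, `$summary`, `$stats` (list with `delivery_mode` and
#'   `ip_antibiotics` group comparisons), `$headline` (one-row tibble),
#'   `$threshold`.
#' @export
run_transfer_analysis <- function(table, meta, taxonomy = NULL,
                                  threshold = 0.001, inclusive = TRUE,
                                  orientation = "samples_rows",
                                  out_dir = NULL) {
  if (is.character(table)) table <- read_feature_table(table, orientation)
  if (is.character(meta)) meta <- read_sample_meta(meta)
  if (is.character(taxonomy)) taxonomy <- read_taxonomy(taxonomy)
  if (is.null(taxonomy))
    warning("no taxonomy supplied; summary rows labelled 'unassigned'")

  cohort <- build_cohort(meta, table)
  events <- detect_transfers(cohort, table, threshold, inclusive)
  per_dyad <- count_per_dyad(events, cohort)
  summary <- summarize_by_asv(events, cohort, table, taxonomy,
                              threshold, inclusive)

  stats <- list(
    delivery_mode = group_stat_or_null(per_dyad, "delivery_mode"),
    ip_antibiotics = group_stat_or_null(per_dyad, "ip_antibiotics")
  )

  positive <- per_dyad$n_transfer_events[per_dyad$n_transfer_events > 0]
  headline <- tibble::tibble(
    n_dyads = nrow(per_dyad),
    n_positive_dyads = length(positive),
    positive_fraction = length(positive) / max(1, nrow(per_dyad)),
    n_events = nrow(events),
    n_10d = sum(events$category == "ten_day_only"),
    n_3mo = sum(events$category == "three_month_only"),
    n_both = sum(events$category == "both"),
    min_events_positive = if (length(positive)) min(positive) else NA_integer_,
    max_events_positive = if (length(positive)) max(positive) else NA_integer_,
    median_events_positive = if (length(positive))
      stats::median(positive) else NA_real_
  )

  report <- structure(list(
    cohort = cohort, events = events, per_dyad = per_dyad,
    summary = summary, stats = stats, headline = headline,
    threshold = threshold
  ), class = "transfer_report")

  if (!is.null(out_dir)) write_transfer_report(report, out_dir)
  report
}

group_stat_or_null <- function(per_dyad, column) {
  groups <- per_dyad[[column]]
  if (length(unique(groups[!is.na(groups)])) < 2) return(NULL)
  kruskal_dunn(per_dyad, n_transfer_events, !!rlang::sym(column))
}

write_transfer_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$events, file.path(out_dir, "events.tsv"))
  readr::write_tsv(report$summary, file.path(out_dir, "summary.tsv"))
  readr::write_tsv(report$per_dyad, file.path(out_dir, "per_dyad.tsv"))
  stats_json <- purrr::map(
    purrr::compact(report$stats),
    function(s) list(groups = s$groups, statistic = s$statistic, df = s$df,
                     p_value = s$p_value, pairwise = s$pairwise))
  jsonlite::write_json(
    list(headline = report$headline, threshold = report$threshold,
         stats = stats_json),
    file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, c("events.tsv", "summary.tsv", "per_dyad.tsv",
                            "stats.json"),
                 list(threshold = report$threshold,
                      n_events = nrow(report$events)))
  invisible(out_dir)
}

#' @export
print.transfer_report <- function(x, ...) {
  h <- x$headline
  cat(sprintf(paste0(
    "<transfer_report> threshold %.4g\n",
    "  %d of %d dyads with >=1 transfer event (%.1f%%)\n",
    "  %d events: %d 10-day only, %d 3-month only, %d both\n"),
    x$threshold, h$n_positive_dyads, h$n_dyads,
    100 * h$positive_fraction, h$n_events, h$n_10d, h$n_3mo, h$n_both))
  if (!is.na(h$median_events_positive))
    cat(sprintf("  per positive dyad: range %d-%d, median %g\n",
                h$min_events_positive, h$max_events_positive,
                h$median_events_positive))
  invisible(x)
}

#' @rdname run_transfer_analysis
#' @param x a `transfer_report`.
#' @param ... unused.
#' @export
glance.transfer_report <- function(x, ...) x$headline

#' Run the genomic strain-identity analysis end to end
#'
#' From a whole-genome alignment (and optionally a gene presence/absence
#' matrix): pairwise SNP distances, k-mer ANI, within- vs between-dyad
#' partitions with Mann-Whitney comparisons, UPGMA trees, per-dyad strain
#' identity calls, and contingency tests of the calls against delivery
#' mode when labels carry one.
#'
#' @param genomes an aligned [genome_set()] or FASTA path.
#' @param labels labels tibble or TSV path (`genome_id`, `dyad_id`,
#'   `origin`, optional `species`, `delivery_mode`); required when
#'   `genomes` lacks them.
#' @param gene_matrix optional logical genes x genomes matrix (or path read
#'   with [read_gene_matrix()] in binary dialect).
#' @param k,ani_mode,sketch_size passed to [ani_matrix()].
#' @param ani_threshold,snp_threshold passed to [strain_identity_call()].
#' @param out_dir optional directory; writes `snp_matrix.tsv`,
#'   `ani_matrix.tsv`, `snp_tree.nwk`, identity calls, partition summaries
#'   and `manifest.json`.
#' @return list of class `genomic_report`: `$snp` (matrix), `$ani`
#'   (matrix), `$snp_partition`, `$ani_partition` (`dyad_partition`s or
#'   NULL when not testable), `$snp_tree`, `$gene_tree` (phylo or NULL),
#'   `$gene_partition`, `$identity_calls`, `$contingency` (list of
#'   `contingency_result`s, possibly empty).
#' @export
run_genomic_analysis <- function(genomes, labels = NULL, gene_matrix = NULL,
                                 k = 21, ani_mode = "exact_sets",
                                 sketch_size = 1000,
                                 ani_threshold = 0.999, snp_threshold = 25,
                                 out_dir = NULL) {
  if (is.character(genomes))
    genomes <- read_alignment(genomes, aligned = TRUE, labels = labels)
  else if (!is.null(labels)) {
    if (is.character(labels)) labels <- read_genome_labels(labels)
    genomes <- genome_set(genomes$sequences, labels = labels,
                          aligned = genomes$aligned)
  }
  if (!"dyad_id" %in% names(genomes$labels))
    stop("genome labels must include dyad_id")
  if (is.character(gene_matrix))
    gene_matrix <- read_gene_matrix(gene_matrix, dialect = "binary")

  snp <- snp_distance_matrix(genomes)
  ani <- ani_matrix(genomes, k = k, mode = ani_mode,
                    sketch_size = sketch_size)

  snp_part <- partition_by_dyad(snp)
  ani_part <- partition_by_dyad(ani)
  snp_tree <- upgma(snp)

  gene_tree <- NULL; gene_part <- NULL
  if (!is.null(gene_matrix)) {
    gd <- jaccard_gene_distance(gene_matrix, labels = genomes$labels)
    gene_tree <- upgma(gd)
    gene_part <- partition_by_dyad(gd)
  }

  calls <- if ("origin" %in% names(genomes$labels))
    strain_identity_call(snp, ani_threshold, snp_threshold) else NULL

  contingency <- list()
  if (!is.null(calls) && "delivery_mode" %in% names(genomes$labels)) {
    mode_of <- dplyr::distinct(
      dplyr::select(genomes$labels, "dyad_id", "delivery_mode"))
    assessed <- dplyr::inner_join(
      dplyr::filter(calls, .data$call != "not_assessable"),
      mode_of, by = "dyad_id")
    tab <- table(assessed$delivery_mode,
                 factor(assessed$call, c("identical", "nonidentical")))
    if (nrow(tab) >= 2 && all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      contingency$delivery_mode <- chi_square(unclass(tab))
  }

  report <- structure(list(
    snp = snp, ani = ani, snp_partition = snp_part, ani_partition = ani_part,
    snp_tree = snp_tree, gene_tree = gene_tree, gene_partition = gene_part,
    identity_calls = calls, contingency = contingency
  ), class = "genomic_report")

  if (!is.null(out_dir)) write_genomic_report(report, out_dir)
  report
}

write_genomic_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(report$snp, file.path(out_dir, "snp_matrix.tsv"))
  write_matrix(report$ani, file.path(out_dir, "ani_matrix.tsv"))
  write_newick(report$snp_tree, file.path(out_dir, "snp_tree.nwk"))
  files <- c("snp_matrix.tsv", "ani_matrix.tsv", "snp_tree.nwk")
  if (!is.null(report$identity_calls)) {
    readr::write_tsv(report$identity_calls,
                     file.path(out_dir, "identity_calls.tsv"))
    files <- c(files, "identity_calls.tsv")
  }
  partitions <- purrr::compact(list(
    snp = report$snp_partition, ani = report$ani_partition,
    gene = report$gene_partition))
  jsonlite::write_json(purrr::map(partitions, function(p) glance(p)),
                       file.path(out_dir, "partitions.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, "partitions.json")
  write_manifest(out_dir, files, list(n_genomes = nrow(report$snp)))
  invisible(out_dir)
}

#' @export
print.genomic_report <- function(x, ...) {
  cat(sprintf("<genomic_report> %d genomes\n", nrow(x$snp)))
  print(x$snp_partition)
  print(x$ani_partition)
  if (!is.null(x$identity_calls)) {
    tab <- table(x$identity_calls$call)
    cat("  identity calls:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# run manifest: digests + row counts so re-runs are checkable
write_manifest <- function(out_dir, files, extra = list()) {
  paths <- file.path(out_dir, files)
  manifest <- c(list(
    tool = "dyadtrace",
    version = as.character(utils::packageVersion("dyadtrace")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = purrr::map2(files, paths, function(f, p)
      list(file = f, md5 = unname(tools::md5sum(p)),
           bytes = file.size(p)))
  ), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
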
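#' Detect potential mother-to-infant ASV transfer events
#'
#' A potential transfer event is the detection of the same ASV at or above a
#' relative-abundance threshold in a mother's vaginal sample and in at least
#' one stool sample from her infant. One event is recorded per (dyad, ASV)
#' regardless of how many infant samples pass; the `category` records which
#' time points passed: `"both"` when the 10-day and 3-month samples both
#' pass, otherwise `"ten_day_only"` / `"three_month_only"`.
#'
#' The threshold gate applies symmetrically to the maternal and infant
#' abundances and is inclusive (`>=`) by default; set `inclusive = FALSE`
#' for a strict `>` gate.
#'
#' @param cohort a `dyad_cohort` built from the same table.
#' @param table a [feature_table()].
#' @param threshold relative-abundance threshold, a fraction in (0, 1);
#'   default 0.001 (0.1%).
#' @param inclusive logical; compare with `>=` (default) or `>`.
#' @return tibble with one row per event: `dyad_id`, `asv_id`, `category`,
#'   `maternal_ra`, `infant10_ra`, `infant3m_ra` (NA when the sample is
#'   absent), sorted by dyad then ASV.
#' @export
detect_transfers <- function(cohort, table, threshold = 0.001,
                             inclusive = TRUE) {
  stopifnot(inherits(cohort, "dyad_cohort"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must be a single fraction in (0, 1)")
  passes <- if (inclusive) function(x) x >= threshold else function(x) x > threshold

  dyads <- analysis_dyads(cohort)
  empty <- tibble::tibble(
    dyad_id = character(), asv_id = character(), category = character(),
    maternal_ra = double(), infant10_ra = double(), infant3m_ra = double()
  )
  if (nrow(dyads) == 0) return(empty)

  ra <- dplyr::select(tibble::as_tibble(table),
                      "sample_id", "asv_id", "rel_abundance")

  ra_for <- function(sample_col, out) {
    key <- dplyr::select(dyads, "dyad_id", sample_id = dplyr::all_of(sample_col))
    key <- dplyr::filter(key, !is.na(.data$sample_id))
    out_ra <- dplyr::inner_join(key, ra, by = "sample_id")
    out_ra <- dplyr::filter(out_ra, passes(.data$rel_abundance))
    dplyr::select(out_ra, "dyad_id", "asv_id", !!out := "rel_abundance")
  }

  mat <- ra_for("maternal_sample", "maternal_ra")
  if (nrow(mat) == 0) return(empty)
  i10 <- ra_for("infant10_sample", "infant10_ra")
  i3m <- ra_for("infant3m_sample", "infant3m_ra")

  ev <- dplyr::left_join(mat, i10, by = c("dyad_id", "asv_id"))
  ev <- dplyr::left_join(ev, i3m, by = c("dyad_id", "asv_id"))
  ev <- dplyr::filter(ev, !is.na(.data$infant10_ra) | !is.na(.data$infant3m_ra))
  ev <- dplyr::mutate(ev, category = dplyr::case_when(
    !is.na(.data$infant10_ra) & !is.na(.data$infant3m_ra) ~ "both",
    !is.na(.data$infant10_ra) ~ "ten_day_only",
    TRUE ~ "three_month_only"
  ))
  dplyr::arrange(
    dplyr::select(ev, "dyad_id", "asv_id", "category", "maternal_ra",
                  "infant10_ra", "infant3m_ra"),
    .data$dyad_id, .data$asv_id
  )
}

#' Count transfer events per dyad
#'
#' Every analysable dyad of the cohort appears, including those with zero
#' events, so the counts feed group comparisons without selection bias.
#'
#' @param events event tibble from [detect_transfers()].
#' @param cohort the `dyad_cohort` the events came from.
#' @return tibble: `dyad_id`, `n_transfer_events`, `delivery_mode`,
#'   `ip_antibiotics`.
#' @export
count_per_dyad <- function(events, cohort) {
  stopifnot(inherits(cohort, "dyad_cohort"))
  dyads <- analysis_dyads(cohort)
  n_ev <- dplyr::count(events, .data$dyad_id, name = "n_transfer_events")
  out <- dplyr::left_join(
    dplyr::select(dyads, "dyad_id", "delivery_mode", "ip_antibiotics"),
    n_ev, by = "dyad_id")
  out <- dplyr::mutate(out, n_transfer_events = dplyr::coalesce(
    .data$n_transfer_events, 0L))
  dplyr::select(out, "dyad_id", "n_transfer_events", "delivery_mode",
                "ip_antibiotics")
}

#' Summarise transfer events per ASV (or genus)
#'
#' Produces the per-taxon accounting used in the study's transfer tables:
#' for each ASV, the number of maternal samples at/above the threshold, the
#' number of transfer events, their breakdown by infant time-point category,
#' and the transfer rate (events / maternal detections).
#'
#' @inheritParams detect_transfers
#' @param events event tibble from [detect_transfers()] run on the same
#'   cohort/table/threshold.
#' @param taxonomy optional taxonomy tibble (`asv_id`, `taxon`,
#'   `pct_identity`); ASVs without a row are labelled `"unassigned"`.
#' @param level `"asv"` (default) or `"genus"` — genus aggregates by the
#'   first word of the taxon label.
#' @return tibble sorted by `n_transfers` descending (ties broken by
#'   `asv_id`): `asv_id`, `taxon`, `pct_identity`, `n_maternal`,
#'   `n_transfers`, `n_both`, `n_10d`, `n_3mo`, `transfer_rate`.
#' @export
summarize_by_asv <- function(events, cohort, table, taxonomy = NULL,
                             threshold = 0.001, inclusive = TRUE,
                             level = c("asv", "genus")) {
  level <- match.arg(level)
  stopifnot(inherits(cohort, "dyad_cohort"))
  passes <- if (inclusive) function(x) x >= threshold else function(x) x > threshold

  # maternal detections per ASV over analysable dyads
  mat_samples <- analysis_dyads(cohort)$maternal_sample
  ra <- dplyr::filter(tibble::as_tibble(table),
                      .data$sample_id %in% mat_samples,
                      passes(.data$rel_abundance))
  n_mat <- dplyr::count(ra, .data$asv_id, name = "n_maternal")

  ev_counts <- dplyr::summarise(
    dplyr::group_by(events, .data$asv_id),
    n_transfers = dplyr::n(),
    n_both = sum(.data$category == "both"),
    n_10d = sum(.data$category == "ten_day_only"),
    n_3mo = sum(.data$category == "three_month_only"),
    .groups = "drop")

  out <- dplyr::left_join(n_mat, ev_counts, by = "asv_id")
  out <- dplyr::mutate(out, dplyr::across(
    c("n_transfers", "n_both", "n_10d", "n_3mo"),
    ~ dplyr::coalesce(.x, 0L)))

  if (!is.null(taxonomy)) {
    out <- dplyr::left_join(
      out, dplyr::select(taxonomy, "asv_id", "taxon", "pct_identity"),
      by = "asv_id")
    out$taxon <- dplyr::coalesce(out$taxon, "unassigned")
  } else {
    out$taxon <- "unassigned"
    out$pct_identity <- NA_real_
  }

  if (level == "genus") {
    out <- dplyr::summarise(
      dplyr::group_by(out, taxon = genus_of(.data$taxon)),
      pct_identity = NA_real_,
      n_maternal = sum(.data$n_maternal),
      n_transfers = sum(.data$n_transfers),
      n_both = sum(.data$n_both), n_10d = sum(.data$n_10d),
      n_3mo = sum(.data$n_3mo), .groups = "drop")
    out$asv_id <- out$taxon
  }

  out <- dplyr::mutate(out, transfer_rate = ifelse(
    .data$n_maternal > 0, .data$n_transfers / .data$n_maternal, NA_real_))
  out <- dplyr::select(out, "asv_id", "taxon", "pct_identity", "n_maternal",
                       "n_transfers", "n_both", "n_10d", "n_3mo",
                       "transfer_rate")
  dplyr::arrange(out, dplyr::desc(.data$n_transfers), .data$asv_id)
}

genus_of <- function(taxon) stringr::word(taxon, 1)

#' Read an already-summarised per-ASV transfer table
#'
#' Reads a per-ASV summary in the layout of the study's printed transfer
#' tables: `asv_id`, `taxon`, `pct_identity`, `n_maternal`, `n_transfers`,
#' `n_both`, `n_10d`, `n_3mo`.
#'
#' @param path TSV/CSV path.
#' @return validated tibble with `transfer_rate` derived.
#' @export
read_transfer_summary <- function(path) {
  s <- read_delim_auto(path)
  need <- c("asv_id", "taxon", "pct_identity", "n_maternal", "n_transfers",
            "n_both", "n_10d", "n_3mo")
  missing <- setdiff(need, names(s))
  if (length(missing))
    stop("summary missing column(s): ", paste(missing, collapse = ", "))
  bad <- with(s, n_both + n_10d + n_3mo != n_transfers)
  if (any(bad))
    stop("category counts do not sum to n_transfers for ASV(s): ",
         paste(s$asv_id[bad], collapse = ", "))
  if (any(s$n_transfers > s$n_maternal))
    stop("n_transfers exceeds n_maternal for some ASV(s)")
  dplyr::mutate(tibble::as_tibble(s),
                asv_id = as.character(.data$asv_id),
                transfer_rate = .data$n_transfers / .data$n_maternal)
}

#' Aggregate a per-ASV transfer summary into table totals
#'
#' @param summary per-ASV summary (from [summarize_by_asv()] or
#'   [read_transfer_summary()]).
#' @return one-row tibble: `n_asvs`, `n_maternal`, `n_transfers`, `n_both`,
#'   `n_10d`, `n_3mo`, `transfer_rate`, `persistence_fraction`
#'   (share of transfers present at both time points).
#' @export
summary_totals <- function(summary) {
  tibble::tibble(
    n_asvs = nrow(summary),
    n_maternal = sum(summary$n_maternal),
    n_transfers = sum(summary$n_transfers),
    n_both = sum(summary$n_both),
    n_10d = sum(summary$n_10d),
    n_3mo = sum(summary$n_3mo),
    transfer_rate = sum(summary$n_transfers) / sum(summary$n_maternal),
    persistence_fraction = sum(summary$n_both) / sum(summary$n_transfers)
  )
}

#' Agreement between two per-dyad boolean classifications
#'
#' Cross-tabulates, per dyad, amplicon-level sharing (a shared ASV above
#' threshold) against strain-level identity (e.g. identical PFGE banding or
#' genome identity) and reports the agreement fraction.
#'
#' @param shared named logical vector (names = dyad ids): ASV shared?
#' @param identical_strain named logical vector over the same dyads:
#'   strain called identical?
#' @return list of class `concordance_result`: `agreement` (fraction of
#'   dyads where the booleans agree), `n`, and `table` (2x2 matrix,
#'   shared x identical).
#' @export
concordance <- function(shared, identical_strain) {
  if (is.null(names(shared)) || is.null(names(identical_strain)))
    stop("both inputs must be named by dyad id")
  if (!setequal(names(shared), names(identical_strain)))
    stop("dyad sets differ between the two classifications")
  identical_strain <- identical_strain[names(shared)]
  tab <- table(
    shared = factor(shared, levels = c(TRUE, FALSE)),
    identical_strain = factor(identical_strain, levels = c(TRUE, FALSE))
  )
  structure(list(
    agreement = mean(shared == identical_strain),
    n = length(shared),
    table = unclass(tab)
  ), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance> %d dyads, agreement %.1f%%\n",
              x$n, 100 * x$agreement))
  print(x$table)
  invisible(x)
}

#' @rdname concordance
#' @param x a `concordance_result`.
#' @param ... unused.
#' @export
tidy.concordance_result <- function(x, ...) {
  tibble::as_tibble(as.data.frame(as.table(x$table), stringsAsFactors = FALSE))
}

#' @rdname concordance
#' @export
glance.concordance_result <- function(x, ...) {
  tibble::tibble(n = x$n, agreement = x$agreement)
}
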
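#' Assemble mother-infant dyads from sample metadata
#'
#' Groups samples into dyads: one maternal vaginal sample per dyad plus up to
#' one infant stool sample at each of the two infant time points (10 days,
#' 3 months). Dyads without any infant sample are kept for bookkeeping but
#' excluded from transfer detection; the validation report counts them.
#'
#' @param meta sample metadata tibble (see [read_sample_meta()]).
#' @param table a [feature_table()] covering the metadata samples. Every
#'   metadata `sample_id` must exist in the table; table samples absent from
#'   the metadata are allowed and reported.
#' @return An object of class `dyad_cohort`: a list with `$dyads` (tibble:
#'   `dyad_id`, `maternal_sample`, `infant10_sample`, `infant3m_sample`,
#'   `delivery_mode`, `ip_antibiotics`, `has_infant`) and `$report` (named
#'   list of validation counts).
#' @export
build_cohort <- function(meta, table) {
  meta <- validate_sample_meta(meta)
  table_samples <- ft_samples(table)$sample_id
  absent <- setdiff(meta$sample_id, table_samples)
  if (length(absent))
    stop("metadata sample(s) missing from feature table: ",
         paste(absent, collapse = ", "))
  extra <- setdiff(table_samples, meta$sample_id)

  unknown <- is.na(meta$dyad_id) | meta$dyad_id == "" | meta$dyad_id == "NA"
  if (any(unknown)) {
    warning(sum(unknown), " sample(s) with unknown dyad dropped: ",
            paste(meta$sample_id[unknown], collapse = ", "))
    meta <- meta[!unknown, , drop = FALSE]
  }

  mat <- dplyr::filter(meta, .data$sample_type == "maternal_vaginal")
  dup_mat <- unique(mat$dyad_id[duplicated(mat$dyad_id)])
  if (length(dup_mat))
    stop("more than one maternal sample for dyad(s): ",
         paste(dup_mat, collapse = ", "))

  inf <- dplyr::filter(meta, .data$sample_type == "infant_stool")
  dup_inf <- dplyr::count(inf, .data$dyad_id, .data$time_point) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup_inf))
    stop("more than one infant sample per time point for dyad(s): ",
         paste(unique(dup_inf$dyad_id), collapse = ", "))

  orphan <- !inf$dyad_id %in% mat$dyad_id
  if (any(orphan)) {
    warning(sum(orphan), " infant sample(s) without a maternal sample ",
            "dropped: ", paste(inf$sample_id[orphan], collapse = ", "))
    inf <- inf[!orphan, , drop = FALSE]
  }

  inf_wide <- tidyr::pivot_wider(
    dplyr::select(inf, "dyad_id", "time_point", "sample_id"),
    names_from = "time_point", values_from = "sample_id"
  )
  for (col in c("10_days", "3_months"))
    if (!col %in% names(inf_wide)) inf_wide[[col]] <- NA_character_

  dyads <- dplyr::left_join(
    dplyr::select(mat, "dyad_id", maternal_sample = "sample_id",
                  "delivery_mode", "ip_antibiotics"),
    dplyr::select(inf_wide, "dyad_id", infant10_sample = "10_days",
                  infant3m_sample = "3_months"),
    by = "dyad_id"
  )
  dyads <- dplyr::mutate(
    dyads,
    has_infant = !is.na(.data$infant10_sample) | !is.na(.data$infant3m_sample)
  )
  dyads <- dplyr::arrange(
    dplyr::select(dyads, "dyad_id", "maternal_sample", "infant10_sample",
                  "infant3m_sample", "delivery_mode", "ip_antibiotics",
                  "has_infant"),
    .data$dyad_id
  )

  report <- list(
    n_dyads = nrow(dyads),
    n_analysis_dyads = sum(dyads$has_infant),
    n_with_10d = sum(!is.na(dyads$infant10_sample)),
    n_with_3m = sum(!is.na(dyads$infant3m_sample)),
    n_with_both = sum(!is.na(dyads$infant10_sample) &
                        !is.na(dyads$infant3m_sample)),
    n_no_infant = sum(!dyads$has_infant),
    n_dropped_unknown_dyad = sum(unknown),
    n_dropped_orphan_infants = sum(orphan),
    extra_table_samples = extra
  )
  structure(list(dyads = dyads, report = report), class = "dyad_cohort")
}

#' Dyads eligible for transfer analysis (at least one infant sample)
#' @param cohort a `dyad_cohort`.
#' @return tibble of dyad rows with `has_infant == TRUE`.
#' @export
analysis_dyads <- function(cohort) {
  stopifnot(inherits(cohort, "dyad_cohort"))
  dplyr::filter(cohort$dyads, .data$has_infant)
}

#' @export
print.dyad_cohort <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0(
    "<dyad_cohort> %d dyads (%d analysable: %d with 10-day, %d with ",
    "3-month, %d with both; %d maternal-only)\n"),
    r$n_dyads, r$n_analysis_dyads, r$n_with_10d, r$n_with_3m,
    r$n_with_both, r$n_no_infant))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname build_cohort
#' @param x a `dyad_cohort`.
#' @param ... unused.
#' @export
tidy.dyad_cohort <- function(x, ...) x$dyads

#' @rdname build_cohort
#' @export
glance.dyad_cohort <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    n_dyads = r$n_dyads, n_analysis_dyads = r$n_analysis_dyads,
    n_with_10d = r$n_with_10d, n_with_3m = r$n_with_3m,
    n_with_both = r$n_with_both, n_no_infant = r$n_no_infant
  )
}
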
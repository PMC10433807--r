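#' Build a feature table from a counts matrix
#'
#' A feature table holds ASV read counts per sample together with per-sample
#' relative abundances (count / sample total). It is stored long: one row per
#' non-zero (sample, ASV) cell. Samples whose total read count is zero are
#' retained in the sample ledger (see [ft_samples()]) and flagged, but
#' contribute no rows and are excluded from downstream detection.
#'
#' @param counts numeric matrix of non-negative integer read counts,
#'   samples in rows and ASVs in columns, with dimnames set.
#' @return A tibble of class `feature_table` with columns `sample_id`,
#'   `asv_id`, `count`, `rel_abundance`, carrying a `samples` attribute
#'   (tibble: `sample_id`, `total_reads`, `flagged_zero`).
#' @export
feature_table <- function(counts) {
  stopifnot(is.matrix(counts))
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts matrix must have sample (row) and ASV (column) names")
  validate_ids(rownames(counts), "sample")
  validate_ids(colnames(counts), "ASV")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")

  totals <- rowSums(counts)
  long <- tibble::as_tibble(as.table(counts), .name_repair = "minimal")
  names(long) <- c("sample_id", "asv_id", "count")
  long <- dplyr::filter(long, .data$count > 0)
  long <- dplyr::mutate(long,
    sample_id = as.character(.data$sample_id),
    asv_id = as.character(.data$asv_id),
    rel_abundance = .data$count / unname(totals[.data$sample_id])
  )
  long <- dplyr::arrange(long, .data$sample_id, .data$asv_id)

  samples <- tibble::tibble(
    sample_id = rownames(counts),
    total_reads = unname(totals),
    flagged_zero = unname(totals) == 0
  )
  new_feature_table(long, samples)
}

new_feature_table <- function(long, samples) {
  out <- tibble::new_tibble(long, class = "feature_table")
  attr(out, "samples") <- samples
  out
}

#' Per-sample ledger of a feature table
#'
#' @param table a [feature_table()].
#' @return tibble with `sample_id`, `total_reads`, `flagged_zero`.
#' @export
ft_samples <- function(table) {
  s <- attr(table, "samples")
  if (is.null(s)) {
    # attribute lost through manipulation: rebuild from the rows we still have
    s <- dplyr::summarise(dplyr::group_by(table, .data$sample_id),
                          total_reads = sum(.data$count), .groups = "drop")
    s$flagged_zero <- s$total_reads == 0
  }
  s
}

#' Read an ASV read-count feature table
#'
#' Reads a TSV/CSV table (delimiter chosen from the file extension) whose
#' first column holds row identifiers, validates it, and derives relative
#' abundances. The caller declares the orientation rather than the reader
#' guessing it.
#'
#' @param path file path (`.tsv`/`.txt` tab-delimited, `.csv` comma).
#' @param orientation `"samples_rows"` if samples are rows and ASVs columns,
#'   `"samples_cols"` for the transpose.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path,
                               orientation = c("samples_rows", "samples_cols")) {
  orientation <- match.arg(orientation)
  df <- read_delim_auto(path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop(sprintf("non-numeric values in column '%s' of %s",
                 names(df)[bad + 1L], path))
  }
  rownames(m) <- ids
  if (orientation == "samples_cols") m <- t(m)
  feature_table(m)
}

#' Read sample metadata
#'
#' Expects the columns `sample_id`, `dyad_id`, `sample_type`, `time_point`,
#' `delivery_mode`, `ip_antibiotics` with the study vocabulary:
#' sample types `maternal_vaginal` / `infant_stool`, time points `delivery` /
#' `10_days` / `3_months`, delivery modes `vaginal` / `elective_CS` /
#' `emergency_CS`, antibiotics `exposed` / `unexposed` / `unknown`.
#'
#' @param path TSV/CSV file path.
#' @return validated tibble of sample metadata.
#' @export
read_sample_meta <- function(path) {
  validate_sample_meta(read_delim_auto(path))
}

sample_type_levels <- c("maternal_vaginal", "infant_stool")
time_point_levels <- c("delivery", "10_days", "3_months")
delivery_mode_levels <- c("vaginal", "elective_CS", "emergency_CS")
antibiotic_levels <- c("exposed", "unexposed", "unknown")

validate_sample_meta <- function(meta) {
  need <- c("sample_id", "dyad_id", "sample_type", "time_point",
            "delivery_mode", "ip_antibiotics")
  missing <- setdiff(need, names(meta))
  if (length(missing))
    stop("metadata missing column(s): ", paste(missing, collapse = ", "))
  meta <- dplyr::mutate(meta, dplyr::across(dplyr::all_of(need), as.character))
  validate_ids(meta$sample_id, "sample")
  check_vocab(meta$sample_type, sample_type_levels, "sample_type")
  check_vocab(meta$time_point, time_point_levels, "time_point")
  check_vocab(meta$delivery_mode, delivery_mode_levels, "delivery_mode")
  check_vocab(meta$ip_antibiotics, antibiotic_levels, "ip_antibiotics")
  bad <- meta$sample_type == "maternal_vaginal" & meta$time_point != "delivery"
  if (any(bad))
    stop("maternal samples must have time_point = delivery: ",
         paste(meta$sample_id[bad], collapse = ", "))
  tibble::as_tibble(meta)
}

#' Read an ASV taxonomy table
#'
#' @param path TSV/CSV with columns `asv_id`, `taxon`, `pct_identity`
#'   (percent sequence identity to the closest reference, in \[0, 100\]).
#' @return validated tibble.
#' @export
read_taxonomy <- function(path) {
  tax <- read_delim_auto(path)
  need <- c("asv_id", "taxon", "pct_identity")
  missing <- setdiff(need, names(tax))
  if (length(missing))
    stop("taxonomy missing column(s): ", paste(missing, collapse = ", "))
  validate_ids(tax$asv_id, "ASV")
  if (any(tax$pct_identity > 100 | tax$pct_identity < 0, na.rm = TRUE))
    stop("pct_identity must lie in [0, 100]")
  tibble::as_tibble(tax)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

validate_ids <- function(ids, what) {
  if (anyNA(ids) || any(ids == ""))
    stop(what, " identifiers must be non-missing")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ", what, " identifier(s): ", paste(dup, collapse = ", "))
  invisible(ids)
}

check_vocab <- function(x, levels, what) {
  bad <- setdiff(unique(x), levels)
  if (length(bad))
    stop(sprintf("unknown %s value(s): %s (expected %s)", what,
                 paste(bad, collapse = ", "), paste(levels, collapse = "/")))
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  s <- ft_samples(x)
  cat(sprintf("<feature_table> %d samples x %d ASVs (%d non-zero cells",
              nrow(s), length(unique(x$asv_id)), nrow(x)))
  if (any(s$flagged_zero))
    cat(sprintf("; %d zero-read sample(s) flagged", sum(s$flagged_zero)))
  cat(")\n")
  NextMethod()
}
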
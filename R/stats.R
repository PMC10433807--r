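#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Omnibus Kruskal-Wallis H (tie-corrected ranks) across groups, followed by
#' Dunn's pairwise z tests on pooled rank means. Raw two-sided p-values are
#' adjusted Bonferroni-style (multiplied by the number of pairwise
#' comparisons, capped at 1), matching common practice for Dunn's multiple
#' comparison correction.
#'
#' @param data data frame with one row per observation.
#' @param value column of numeric values (tidy-eval).
#' @param group column of group labels (tidy-eval).
#' @param p_adjust `"bonferroni"` (default) or `"none"`.
#' @return object of class `group_comparison`: `$groups` (per-group n,
#'   mean, sd, median), `$statistic` (H), `$df`, `$p_value`, `$pairwise`
#'   (tibble: group1, group2, z, p_raw, p_adj).
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
#' kruskal_dunn(d, y, g)
#' @export
kruskal_dunn <- function(data, value, group,
                         p_adjust = c("bonferroni", "none")) {
  p_adjust <- match.arg(p_adjust)
  values <- dplyr::pull(data, {{ value }})
  groups <- as.character(dplyr::pull(data, {{ group }}))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  if (length(unique(groups)) < 2)
    stop("kruskal_dunn needs at least two groups")

  per_group <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(value = values, group = groups),
                    .data$group),
    n = dplyr::n(), mean = mean(.data$value), sd = stats::sd(.data$value),
    median = stats::median(.data$value), .groups = "drop")

  kw <- stats::kruskal.test(values, factor(groups))
  H <- unname(kw$statistic)
  if (is.nan(H)) H <- 0          # all values identical: no rank variance
  p_omni <- unname(kw$p.value)
  if (is.nan(p_omni)) p_omni <- 1

  # Dunn's z: pooled (mid-)ranks, tie-corrected variance
  r <- rank(values)
  n <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  labels <- sort(unique(groups))
  rbar <- vapply(labels, function(g) mean(r[groups == g]), numeric(1))
  ng <- vapply(labels, function(g) sum(groups == g), numeric(1))
  pairs <- utils::combn(labels, 2)
  m <- ncol(pairs)
  pairwise <- purrr::map_dfr(seq_len(m), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ng[g1] + 1 / ng[g2]))
    z <- if (se > 0) (rbar[g1] - rbar[g2]) / se else 0
    p_raw <- 2 * stats::pnorm(-abs(z))
    tibble::tibble(group1 = g1, group2 = g2, z = z, p_raw = p_raw)
  })
  mult <- if (p_adjust == "bonferroni") m else 1
  pairwise$p_adj <- pmin(1, pairwise$p_raw * mult)

  structure(list(
    groups = per_group, statistic = H, df = length(labels) - 1,
    p_value = p_omni, pairwise = pairwise,
    method = "Kruskal-Wallis with Dunn's post hoc",
    p_adjust = p_adjust
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s\nH = %.4g, df = %d, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  print(x$groups)
  print(x$pairwise)
  invisible(x)
}

#' @rdname kruskal_dunn
#' @param x a `group_comparison`.
#' @param ... unused.
#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' @rdname kruskal_dunn
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 n = sum(x$groups$n), n_groups = nrow(x$groups))
}

#' Chi-square test of independence on a contingency table
#'
#' Pearson chi-square against independence expecteds. Yates' continuity
#' correction (subtract 0.5 from each |O - E| before squaring) is defined
#' for 2x2 tables only. The default is uncorrected.
#'
#' @param observed integer matrix (at least 2x2) of observed counts.
#' @param correction `"none"` (default) or `"yates"`.
#' @return object of class `contingency_result`: `$observed`, `$expected`,
#'   `$statistic`, `$df`, `$p_value`, `$correction`.
#' @export
chi_square <- function(observed, correction = c("none", "yates")) {
  correction <- match.arg(correction)
  observed <- as.matrix(observed)
  if (nrow(observed) < 2 || ncol(observed) < 2)
    stop("observed must be at least 2x2")
  if (any(observed < 0) || anyNA(observed))
    stop("observed counts must be non-negative")
  if (any(rowSums(observed) == 0) || any(colSums(observed) == 0))
    stop("a zero row/column total leaves expected counts undefined")
  if (correction == "yates" && !all(dim(observed) == c(2, 2)))
    stop("Yates' correction is defined for 2x2 tables only")
  res <- suppressWarnings(
    stats::chisq.test(observed, correct = correction == "yates"))
  structure(list(
    observed = observed, expected = res$expected,
    statistic = unname(res$statistic), df = unname(res$parameter),
    p_value = unname(res$p.value), correction = correction
  ), class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency> chi-square = %.4g, df = %d, p = %.4g (%s)\n",
              x$statistic, x$df, x$p_value,
              if (x$correction == "yates") "Yates-corrected" else "uncorrected"))
  invisible(x)
}

#' @rdname chi_square
#' @param x a `contingency_result`.
#' @param ... unused.
#' @export
tidy.contingency_result <- function(x, ...) {
  obs <- as.data.frame(as.table(x$observed), stringsAsFactors = FALSE)
  exp <- as.data.frame(as.table(x$expected), stringsAsFactors = FALSE)
  names(obs) <- c("row", "col", "observed")
  obs$expected <- exp[[3]]
  tibble::as_tibble(obs)
}

#' @rdname chi_square
#' @export
glance.contingency_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 correction = x$correction)
}

#' Mann-Whitney U test (two-sided, normal approximation)
#'
#' Rank-sum U with a two-sided p-value from the tie-corrected normal
#' approximation (no continuity correction), the convention used for large
#' pairwise-distance samples.
#'
#' @param sample_a,sample_b numeric vectors, both non-empty.
#' @return object of class `two_sample_result`: `$statistic` (U for
#'   `sample_a`), `$p_value`, `$median_a`, `$median_b`, `$n_a`, `$n_b`.
#' @export
mann_whitney <- function(sample_a, sample_b) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be non-empty")
  res <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, exact = FALSE, correct = FALSE))
  structure(list(
    statistic = unname(res$statistic), p_value = unname(res$p.value),
    median_a = stats::median(sample_a), median_b = stats::median(sample_b),
    n_a = length(sample_a), n_b = length(sample_b)
  ), class = "two_sample_result")
}

#' @export
print.two_sample_result <- function(x, ...) {
  cat(sprintf(
    "<two_sample> Mann-Whitney U = %.4g, p = %.4g (medians %.4g vs %.4g)\n",
    x$statistic, x$p_value, x$median_a, x$median_b))
  invisible(x)
}

#' @rdname mann_whitney
#' @param x a `two_sample_result`.
#' @param ... unused.
#' @export
tidy.two_sample_result <- function(x, ...) glance.two_sample_result(x)

#' @rdname mann_whitney
#' @export
glance.two_sample_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 median_a = x$median_a, median_b = x$median_b,
                 n_a = x$n_a, n_b = x$n_b)
}
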
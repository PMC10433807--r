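# shared in-code fixtures

extdata <- function(name) {
  system.file("extdata", name, package = "dyadtrace", mustWork = TRUE)
}

# tiny three-sample cohort: one dyad with both infant time points
tiny_counts <- function() {
  m <- matrix(
    c(900, 100,   0,
      500,  20, 480,
      998,   0,   2),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("m1", "i10", "i3m"), c("asvA", "asvB", "asvC")))
  m
}

tiny_meta <- function() {
  tibble::tibble(
    sample_id = c("m1", "i10", "i3m"),
    dyad_id = "d1",
    sample_type = c("maternal_vaginal", "infant_stool", "infant_stool"),
    time_point = c("delivery", "10_days", "3_months"),
    delivery_mode = "vaginal",
    ip_antibiotics = "unexposed")
}

# brute-force transfer-detection oracle: loop over every (dyad, ASV) and
# every sample, recomputing relative abundances from raw counts
oracle_transfers <- function(counts, meta, threshold, inclusive = TRUE) {
  ra <- sweep(counts, 1, pmax(1, rowSums(counts)), "/")
  pass <- function(x) if (inclusive) x >= threshold else x > threshold
  out <- list()
  for (d in unique(meta$dyad_id)) {
    rows <- meta[meta$dyad_id == d, ]
    mat <- rows$sample_id[rows$sample_type == "maternal_vaginal"]
    i10 <- rows$sample_id[rows$time_point == "10_days"]
    i3m <- rows$sample_id[rows$time_point == "3_months"]
    if (!length(mat) || (!length(i10) && !length(i3m))) next
    for (a in colnames(counts)) {
      if (!pass(ra[mat, a])) next
      p10 <- length(i10) && pass(ra[i10, a])
      p3m <- length(i3m) && pass(ra[i3m, a])
      if (!p10 && !p3m) next
      cat_a <- if (p10 && p3m) "both" else
        if (p10) "ten_day_only" else "three_month_only"
      out[[paste(d, a)]] <- tibble::tibble(dyad_id = d, asv_id = a,
                                           category = cat_a)
    }
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res))
    return(tibble::tibble(dyad_id = character(), asv_id = character(),
                          category = character()))
  dplyr::arrange(res, dyad_id, asv_id)
}

# random small cohort (counts + metadata) for oracle-equivalence tests
random_small_cohort <- function(n_dyads, n_asvs, seed) {
  withr::local_seed(seed)
  asvs <- sprintf("a%02d", seq_len(n_asvs))
  meta <- list(); counts <- list()
  for (d in seq_len(n_dyads)) {
    dy <- sprintf("d%02d", d)
    has10 <- runif(1) < 0.8
    has3m <- runif(1) < 0.7
    if (!has10 && !has3m) has10 <- TRUE
    sids <- c(paste0(dy, "m"),
              if (has10) paste0(dy, "i10"),
              if (has3m) paste0(dy, "i3m"))
    tps <- c("delivery", if (has10) "10_days", if (has3m) "3_months")
    sts <- c("maternal_vaginal", rep("infant_stool", length(sids) - 1))
    meta[[dy]] <- tibble::tibble(
      sample_id = sids, dyad_id = dy, sample_type = sts, time_point = tps,
      delivery_mode = sample(c("vaginal", "elective_CS", "emergency_CS"), 1),
      ip_antibiotics = sample(c("exposed", "unexposed"), 1))
    for (s in sids)
      counts[[s]] <- rpois(n_asvs, lambda = sample(c(0, 1, 5, 50), n_asvs,
                                                   replace = TRUE))
  }
  meta <- dplyr::bind_rows(meta)
  m <- do.call(rbind, counts)
  colnames(m) <- asvs
  list(counts = m, meta = meta)
}

# brute-force per-column SNP oracle
oracle_snp <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  n <- 0L
  for (i in seq_along(a)) {
    if (a[i] %in% c("A", "C", "G", "T") && b[i] %in% c("A", "C", "G", "T") &&
        a[i] != b[i]) n <- n + 1L
  }
  n
}

# small genome set with explicit dyad structure for partition tests
block_matrix_4 <- function(within = 5, between = 100) {
  ids <- c("d1M", "d1I", "d2M", "d2I")
  m <- matrix(between, 4, 4, dimnames = list(ids, ids))
  m[1, 2] <- m[2, 1] <- within
  m[3, 4] <- m[4, 3] <- within
  diag(m) <- 0
  labels <- tibble::tibble(
    genome_id = ids, dyad_id = c("d1", "d1", "d2", "d2"),
    origin = c("maternal", "infant", "maternal", "infant"))
  pairwise_matrix(m, metric = "snp_count", labels = labels)
}
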
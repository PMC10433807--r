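co_tiny <- function() {
  ft <- feature_table(tiny_counts())
  list(ft = ft, co = build_cohort(tiny_meta(), ft))
}

test_that("transfer definition: maternal and >=1 infant sample above threshold", {
  # asvA: maternal 90%, 10-day 96.2% (500/520... recompute): counts are
  # m1 (900,100,0); i10 (500,20,480); i3m (998,0,2)
  x <- co_tiny()
  ev <- detect_transfers(x$co, x$ft, threshold = 0.001)
  # asvA passes everywhere -> both; asvB maternal 10% / i10 3.8% -> both?
  # i3m has asvB at 0 -> ten_day_only; asvC maternal 0 -> no event
  expect_equal(ev$asv_id, c("asvA", "asvB"))
  expect_equal(ev$category[ev$asv_id == "asvA"], "both")
  expect_equal(ev$category[ev$asv_id == "asvB"], "ten_day_only")
  expect_false("asvC" %in% ev$asv_id)
})

test_that("maternal gate failing suppresses events regardless of infant abundance", {
  m <- matrix(c(1, 1999, 100, 1900), nrow = 2, byrow = TRUE,
              dimnames = list(c("m1", "i10"), c("asvA", "asvB")))
  meta <- tiny_meta()[1:2, ]
  ft <- feature_table(m)
  co <- build_cohort(meta, ft)
  # asvA maternal 0.05% < 0.1%; infant 5% -> no event
  ev <- detect_transfers(co, ft, threshold = 0.001)
  expect_false("asvA" %in% ev$asv_id)
  expect_true("asvB" %in% ev$asv_id)
})

test_that("threshold gate is inclusive by default and strict on request", {
  m <- matrix(c(1, 999, 1, 999), nrow = 2, byrow = TRUE,
              dimnames = list(c("m1", "i10"), c("asvA", "asvB")))
  ft <- feature_table(m)
  co <- build_cohort(tiny_meta()[1:2, ], ft)
  ev_inc <- detect_transfers(co, ft, threshold = 0.001, inclusive = TRUE)
  ev_strict <- detect_transfers(co, ft, threshold = 0.001, inclusive = FALSE)
  expect_true("asvA" %in% ev_inc$asv_id)      # exactly at 0.1%
  expect_false("asvA" %in% ev_strict$asv_id)
  expect_error(detect_transfers(co, ft, threshold = 0), "threshold")
  expect_error(detect_transfers(co, ft, threshold = 1), "threshold")
})

test_that("detect_transfers equals the brute-force oracle on random small cohorts", {
  for (seed in 1:12) {
    n_dyads <- 2 + seed %% 9      # up to 10 dyads
    n_asvs <- 5 + seed %% 16      # up to 20 ASVs
    rc <- random_small_cohort(n_dyads, n_asvs, seed = 100 + seed)
    ft <- feature_table(rc$counts)
    co <- build_cohort(rc$meta, ft)
    for (thr in c(0.001, 0.01, 0.1)) {
      got <- detect_transfers(co, ft, thr)[, c("dyad_id", "asv_id", "category")]
      want <- oracle_transfers(rc$counts, rc$meta, thr)
      expect_equal(as.data.frame(got), as.data.frame(want),
                   info = sprintf("seed %d thr %g", seed, thr))
    }
  }
})

test_that("raising the threshold never increases the number of events", {
  rc <- random_small_cohort(8, 15, seed = 42)
  ft <- feature_table(rc$counts)
  co <- build_cohort(rc$meta, ft)
  thresholds <- c(0.0005, 0.001, 0.005, 0.01, 0.05, 0.2)
  n_ev <- vapply(thresholds,
                 function(t) nrow(detect_transfers(co, ft, t)), numeric(1))
  expect_true(all(diff(n_ev) <= 0))
})

test_that("per-dyad counts include zero dyads and partition the event set", {
  rc <- random_small_cohort(7, 10, seed = 5)
  ft <- feature_table(rc$counts)
  co <- build_cohort(rc$meta, ft)
  ev <- detect_transfers(co, ft, 0.01)
  pd <- count_per_dyad(ev, co)
  expect_equal(nrow(pd), nrow(analysis_dyads(co)))
  expect_equal(sum(pd$n_transfer_events), nrow(ev))

  pd0 <- count_per_dyad(ev[0, ], co)
  expect_true(all(pd0$n_transfer_events == 0))
})

test_that("per-ASV summary accounts maternal detections, categories and rate", {
  # 4 mothers carry the ASV above threshold, 1 transfer -> rate 0.25
  m <- matrix(0, nrow = 8, ncol = 2,
              dimnames = list(c(paste0("m", 1:4), paste0("i", 1:4)),
                              c("asvA", "other")))
  m[1:4, "asvA"] <- 100; m[1:4, "other"] <- 900
  m[5, "asvA"] <- 50; m[5:8, "other"] <- 950; m[6:8, "other"] <- 1000
  meta <- tibble::tibble(
    sample_id = rownames(m),
    dyad_id = rep(paste0("d", 1:4), 2),
    sample_type = rep(c("maternal_vaginal", "infant_stool"), each = 4),
    time_point = rep(c("delivery", "10_days"), each = 4),
    delivery_mode = "vaginal", ip_antibiotics = "unexposed")
  ft <- feature_table(m)
  co <- build_cohort(meta, ft)
  ev <- detect_transfers(co, ft, 0.001)
  s <- summarize_by_asv(ev, co, ft, taxonomy = NULL, threshold = 0.001)
  row <- s[s$asv_id == "asvA", ]
  expect_equal(row$n_maternal, 4L)
  expect_equal(row$n_transfers, 1L)
  expect_equal(row$transfer_rate, 0.25)
  expect_equal(row$taxon, "unassigned")
  expect_equal(row$n_both + row$n_10d + row$n_3mo, row$n_transfers)
})

test_that("summary invariants hold on simulated cohorts and genus rollup sums", {
  sc <- simulate_cohort(sim_config(n_dyads = 25), seed = 3)
  co <- build_cohort(sc$meta, sc$table)
  ev <- detect_transfers(co, sc$table, 0.001)
  tax <- tibble::tibble(asv_id = sort(unique(sc$table$asv_id)),
                        taxon = paste("Genus", rep(1:5, length.out = length(asv_id)),
                                      "species"),
                        pct_identity = 99)
  s <- summarize_by_asv(ev, co, sc$table, tax, 0.001)
  expect_true(all(s$n_both + s$n_10d + s$n_3mo == s$n_transfers))
  expect_true(all(s$n_transfers <= s$n_maternal))
  expect_true(all(s$transfer_rate >= 0 & s$transfer_rate <= 1, na.rm = TRUE))
  expect_true(all(diff(s$n_transfers) <= 0))  # sorted descending

  g <- summarize_by_asv(ev, co, sc$table, tax, 0.001, level = "genus")
  expect_equal(sum(g$n_transfers), sum(s$n_transfers))
  expect_equal(sum(g$n_maternal), sum(s$n_maternal))
})

test_that("printed-table ingestion validates and aggregates", {
  t2 <- read_transfer_summary(extdata("table2_bifidobacterium_asvs.tsv"))
  expect_equal(nrow(t2), 17)
  expect_true(all(t2$n_both + t2$n_10d + t2$n_3mo == t2$n_transfers))

  d <- withr::local_tempdir()
  p <- file.path(d, "bad.tsv")
  writeLines(c("asv_id\ttaxon\tpct_identity\tn_maternal\tn_transfers\tn_both\tn_10d\tn_3mo",
               "1\tX\t99\t4\t3\t1\t1\t0"), p)
  expect_error(read_transfer_summary(p), "do not sum")
})

test_that("concordance agrees with hand computation and validates dyad sets", {
  a <- c(d1 = TRUE, d2 = FALSE, d3 = TRUE)
  expect_equal(concordance(a, a)$agreement, 1)
  expect_equal(concordance(a, !a)$agreement, 0)

  b <- c(d1 = TRUE, d2 = TRUE, d3 = FALSE)
  cc <- concordance(a, b)
  expect_equal(cc$agreement, 1 / 3)
  expect_equal(sum(cc$table), 3)
  expect_equal(glance(cc)$n, 3)

  expect_error(concordance(a, c(d1 = TRUE, d9 = FALSE, d3 = TRUE)),
               "dyad sets differ")
  # 21 of 33 dyads agreeing -> 63.6%
  s33 <- stats::setNames(rep(c(TRUE, FALSE), c(25, 8)), paste0("d", 1:33))
  i33 <- s33; i33[1:12] <- !i33[1:12]
  expect_equal(round(concordance(s33, i33)$agreement, 3), 0.636)
})
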
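test_that("SNP distance follows snp-dists semantics on hand-checkable pairs", {
  gs <- genome_set(c(g1 = "ACGT", g2 = "ACGT", g3 = "ACGA", g4 = "AC-T",
                     g5 = "ACNT"), aligned = TRUE)
  m <- snp_distance_matrix(gs)
  expect_equal(unclass(m)["g1", "g2"], 0)
  expect_equal(unclass(m)["g1", "g3"], 1)
  expect_equal(unclass(m)["g1", "g4"], 0)  # gap column skipped
  expect_equal(unclass(m)["g1", "g5"], 0)  # N column skipped
  expect_true(isSymmetric(unclass(m)))
  expect_error(snp_distance_matrix(genome_set(c(a = "ACGT", b = "ACG"),
                                              aligned = FALSE)),
               "aligned")
})

test_that("SNP distance is case-insensitive and equals the per-column oracle", {
  withr::local_seed(7)
  for (i in 1:10) {
    L <- sample(50:300, 1)
    a <- random_genome(L)
    b <- mutate_genome(a, sample(0:20, 1))
    # sprinkle gaps/Ns/lowercase into copies
    ac <- strsplit(a, "")[[1]]; bc <- strsplit(as.character(b), "")[[1]]
    idx <- sample(L, L %/% 10)
    ac[idx[seq_len(length(idx) %/% 2)]] <- "-"
    bc[idx[length(idx)]] <- "N"
    a2 <- paste(tolower(ac), collapse = "")
    b2 <- paste(bc, collapse = "")
    gs <- genome_set(c(x = a2, y = b2), aligned = TRUE)
    expect_equal(unclass(snp_distance_matrix(gs))["x", "y"],
                 oracle_snp(a2, b2))
  }
})

test_that("planted substitutions are recovered exactly", {
  ref <- random_genome(1000, seed = 8)
  for (n in c(0, 1, 15, 500)) {
    mut <- mutate_genome(ref, n, seed = 9)
    gs <- genome_set(c(r = ref, m = as.character(mut)), aligned = TRUE)
    expect_equal(unclass(snp_distance_matrix(gs))["r", "m"], n)
  }
  expect_error(mutate_genome(ref, 1001), "exceeds")
})

test_that("two independent mutants respect the position-bookkeeping bounds", {
  ref <- random_genome(500, seed = 10)
  m1 <- mutate_genome(ref, 12, seed = 11)
  m2 <- mutate_genome(ref, 30, seed = 12)
  d <- unclass(snp_distance_matrix(genome_set(
    c(a = as.character(m1), b = as.character(m2)), aligned = TRUE)))["a", "b"]
  expect_gte(d, abs(30 - 12))
  expect_lte(d, 30 + 12)
  # per-position oracle from the recorded mutation maps
  p1 <- stats::setNames(attr(m1, "new_bases"), attr(m1, "positions"))
  p2 <- stats::setNames(attr(m2, "new_bases"), attr(m2, "positions"))
  only1 <- setdiff(names(p1), names(p2)); only2 <- setdiff(names(p2), names(p1))
  shared <- intersect(names(p1), names(p2))
  expect_equal(d, length(only1) + length(only2) + sum(p1[shared] != p2[shared]))
})

test_that("ANI closed forms: self-identity and J = 0.5 at k = 21", {
  g <- random_genome(5000, seed = 13)
  self <- ani_estimate(g, g)
  expect_equal(self$jaccard, 1)
  expect_equal(self$ani, 1)
  # at J = 0.5 the estimator gives 1 - ln(3/2)/k
  expect_equal(1 + log(2 * 0.5 / 1.5) / 21, 0.98069, tolerance = 1e-4)

  unrelated <- ani_estimate(random_genome(2000, seed = 14),
                            random_genome(2000, seed = 15))
  expect_true(unrelated$unrelated || unrelated$ani < 0.8)
  expect_error(ani_estimate(g, g, k = 20), "odd")
  expect_error(ani_estimate("ACGT", g), "shorter than k")
})

test_that("ANI uses canonical k-mers: reverse complement gives J = 1", {
  g <- random_genome(3000, seed = 16)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  res <- ani_estimate(g, rc)
  expect_equal(res$jaccard, 1)
  expect_equal(res$ani, 1)
})

test_that("ANI recovers planted mutation rates and is monotone in rate", {
  rates <- c(0.001, 0.005, 0.01, 0.02, 0.05)
  L <- 50000
  ref <- random_genome(L, seed = 17)
  anis <- vapply(seq_along(rates), function(i) {
    mut <- mutate_genome(ref, round(rates[i] * L), seed = 20 + i)
    ani_estimate(ref, as.character(mut))$ani
  }, numeric(1))
  expect_true(all(abs(anis - (1 - rates)) <= 0.005))
  expect_true(all(diff(anis) < 0))
})

test_that("MinHash sketching converges to exact sets at large sketch size", {
  L <- 20000
  ref <- random_genome(L, seed = 18)
  mut <- as.character(mutate_genome(ref, round(0.01 * L), seed = 19))
  exact <- ani_estimate(ref, mut, mode = "exact_sets")$ani
  sk <- ani_estimate(ref, mut, mode = "minhash", sketch_size = 5000)$ani
  expect_lt(abs(exact - sk), 0.002)
  # determinism: no RNG involved
  expect_identical(sk, ani_estimate(ref, mut, mode = "minhash",
                                    sketch_size = 5000)$ani)
})

test_that("gene-content Jaccard distance matches set arithmetic", {
  gm <- matrix(c(1, 1, 1, 0,   0, 1, 1, 1,   1, 1, 1, 0,  0, 0, 0, 0),
               nrow = 4,
               dimnames = list(c("a", "b", "c", "d"),
                               c("g1", "g2", "g3", "g4")))
  d <- jaccard_gene_distance(gm == 1)
  expect_equal(unclass(d)["g1", "g2"], 0.5)   # {a,b,c} vs {b,c,d}
  expect_equal(unclass(d)["g1", "g3"], 0)     # identical sets
  expect_equal(unclass(d)["g1", "g4"], 1)     # empty vs non-empty
  expect_equal(unclass(d)["g4", "g4"], 0)
  gm2 <- cbind(gm, g5 = c(0, 0, 0, 0))
  d2 <- jaccard_gene_distance(gm2 == 1)
  expect_equal(unclass(d2)["g4", "g5"], 0)    # two empties
})

test_that("UPGMA matches the closed-form three-leaf merge and is ultrametric", {
  m <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma(pairwise_matrix(m, metric = "snp_count"))
  expect_equal(ape::write.tree(tree), "((A:1,B:1):2,C:3);")
  expect_true(is_ultrametric(tree))

  m0 <- matrix(0, 3, 3, dimnames = dimnames(m))
  t0 <- upgma(pairwise_matrix(m0, metric = "snp_count"))
  expect_true(is_ultrametric(t0))
  expect_equal(max(ape::node.depth.edgelength(t0)), 0)

  expect_error(upgma(pairwise_matrix(matrix(0, 1, 1,
                                            dimnames = list("A", "A")),
                                     metric = "snp_count")),
               "at least two")
})

test_that("UPGMA is ultrametric on random distance matrices", {
  withr::local_seed(20)
  for (i in 1:5) {
    n <- sample(4:10, 1)
    ids <- paste0("g", seq_len(n))
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    d[upper.tri(d)] <- sample(1:100, sum(upper.tri(d)), replace = TRUE)
    d <- d + t(d)
    tree <- upgma(pairwise_matrix(d, metric = "snp_count"))
    expect_true(is_ultrametric(tree))
    expect_setequal(tree$tip.label, ids)
  }
})

test_that("dyad partition conserves pairs and recovers block medians", {
  m <- block_matrix_4(within = 5, between = 100)
  p <- partition_by_dyad(m)
  expect_equal(p$median_within, 5)
  expect_equal(p$median_between, 100)
  expect_equal(length(p$within) + length(p$between), choose(4, 2))
  expect_equal(length(p$within), 2)
  expect_equal(glance(p)$n_between, 4)
})

test_that("a single-genome dyad contributes only between-pairs", {
  ids <- c("d1M", "d1I", "d2M")
  m <- matrix(c(0, 5, 90, 5, 0, 95, 90, 95, 0), 3,
              dimnames = list(ids, ids))
  labels <- tibble::tibble(genome_id = ids, dyad_id = c("d1", "d1", "d2"),
                           origin = c("maternal", "infant", "maternal"))
  p <- partition_by_dyad(pairwise_matrix(m, metric = "snp_count",
                                         labels = labels))
  expect_equal(length(p$within), 1)
  expect_equal(length(p$between), 2)
})

test_that("strain identity calls honour thresholds and assessability", {
  ids <- c("d1M", "d1I", "d2M", "d2I", "d3M")
  ani <- matrix(0.98, 5, 5, dimnames = list(ids, ids))
  diag(ani) <- 1
  ani["d1M", "d1I"] <- ani["d1I", "d1M"] <- 0.99998
  ani["d2M", "d2I"] <- ani["d2I", "d2M"] <- 0.982
  labels <- tibble::tibble(
    genome_id = ids, dyad_id = c("d1", "d1", "d2", "d2", "d3"),
    origin = c("maternal", "infant", "maternal", "infant", "maternal"))
  calls <- strain_identity_call(pairwise_matrix(ani, metric = "ani",
                                                labels = labels))
  expect_equal(calls$call[calls$dyad_id == "d1"], "identical")
  expect_equal(calls$call[calls$dyad_id == "d2"], "nonidentical")
  expect_equal(calls$call[calls$dyad_id == "d3"], "not_assessable")

  # boundary conventions: SNPs inclusive (<=), ANI exclusive (>)
  snp <- block_matrix_4(within = 25, between = 20000)
  calls_snp <- strain_identity_call(snp, snp_threshold = 25)
  expect_true(all(calls_snp$call == "identical"))
  ani_b <- ani; ani_b["d1M", "d1I"] <- ani_b["d1I", "d1M"] <- 0.999
  calls_b <- strain_identity_call(pairwise_matrix(ani_b, metric = "ani",
                                                  labels = labels))
  expect_equal(calls_b$call[calls_b$dyad_id == "d1"], "nonidentical")
})
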
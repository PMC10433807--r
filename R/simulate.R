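#' Simulation configuration for synthetic dyad cohorts
#'
#' The defaults emulate the study conditions: 585 dyads, 10-day stool
#' availability 568/585 and 3-month availability 459/585, maternal vaginal
#' profiles dominated by a Lactobacillus-like ASV, ~6 maternal ASVs per
#' dyad placed at or above the detection threshold, a per-eligible-ASV
#' transfer probability of 0.06 across the 7 transferable ASVs (landing near
#' the study's 0.44 events per dyad and ~35% positive dyads), the transfer
#' category split 147:72:41
#' (10-day only : 3-month only : both), read depth 20,000, and the 0.1%
#' relative-abundance threshold.
#'
#' Planted (ground-truth) ASV counts are placed deterministically at the
#' configured margins — shared ASVs at >= `shared_margin` x threshold in
#' mother and designated infant sample(s), non-transferred maternal ASVs in
#' infants at 0 or <= `unshared_margin` x threshold — while the residual
#' read depth is drawn multinomially from a Dirichlet background, so the
#' detection-gate margins hold exactly in every realisation.
#'
#' @param n_dyads number of mother-infant dyads.
#' @param n_asvs size of the ASV pool.
#' @param p_10d,p_3m probability an infant has a 10-day / 3-month sample.
#' @param n_eligible maternal ASVs per dyad planted at/above threshold
#'   (besides the dominant one).
#' @param p_transfer per-eligible-ASV transfer probability; scalar or a
#'   named vector over delivery modes (`vaginal`, `elective_CS`,
#'   `emergency_CS`) for mode-dependent transfer.
#' @param category_probs probabilities that a planted transfer lands in the
#'   10-day sample only, the 3-month sample only, or both (renormalised
#'   over the time points the infant actually has).
#' @param delivery_probs,antibiotic_probs named label proportions.
#' @param threshold detection threshold the margins are anchored to.
#' @param shared_margin,unshared_margin abundance placement margins as
#'   multiples of `threshold` (shared >= 2x, unshared <= 0.5x).
#' @param depth reads per sample.
#' @param dirichlet_dominant,dirichlet_rare Dirichlet concentrations of the
#'   dominant Lactobacillus-like component and the rare background taxa.
#' @param n_background background ASVs drawn per sample.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_dyads = 585, n_asvs = 200,
                       p_10d = 568 / 585, p_3m = 459 / 585,
                       n_eligible = 6, p_transfer = 0.06,
                       category_probs = c(ten_day_only = 147, three_month_only = 72,
                                          both = 41) / 260,
                       delivery_probs = c(vaginal = 0.6, elective_CS = 0.2,
                                          emergency_CS = 0.2),
                       antibiotic_probs = c(unexposed = 0.6, exposed = 0.4),
                       threshold = 0.001, shared_margin = 2,
                       unshared_margin = 0.5, depth = 20000,
                       dirichlet_dominant = 30, dirichlet_rare = 0.5,
                       n_background = 25) {
  cfg <- as.list(environment())
  stopifnot(
    n_dyads >= 1, n_asvs > n_eligible + 1,
    p_10d >= 0, p_10d <= 1, p_3m >= 0, p_3m <= 1,
    all(p_transfer >= 0), all(p_transfer <= 1),
    abs(sum(category_probs) - 1) < 1e-9,
    abs(sum(delivery_probs) - 1) < 1e-9,
    abs(sum(antibiotic_probs) - 1) < 1e-9,
    threshold > 0, threshold < 1, shared_margin > 1,
    unshared_margin < 1, depth >= 1
  )
  if (shared_margin * threshold * depth < 1)
    stop("depth too low to represent the shared margin: ",
         "shared_margin * threshold * depth must be >= 1")
  structure(cfg, class = "sim_config")
}

transfer_prob_for <- function(p_transfer, mode) {
  if (length(p_transfer) == 1 && is.null(names(p_transfer)))
    return(unname(p_transfer))
  if (!mode %in% names(p_transfer))
    stop("p_transfer has no entry for delivery mode ", mode)
  unname(p_transfer[[mode]])
}

#' Simulate a dyad-structured amplicon cohort with known ground truth
#'
#' Generates maternal vaginal and infant stool samples for `n_dyads`
#' mother-infant pairs under a [sim_config()], planting transfer events
#' with exact abundance margins around the detection threshold (see
#' [sim_config()] for the placement scheme).
#'
#' @param config a [sim_config()].
#' @param seed integer seed; fixes all randomness end to end.
#' @return list of class `sim_cohort`: `$table` (a [feature_table()]),
#'   `$meta` (sample metadata tibble), `$truth` (list with `$events` — the
#'   planted transfer events as a tibble `dyad_id`, `asv_id`, `category` —
#'   and `$config`, `$seed`).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(as.integer(seed))
  cfg <- config

  asv_ids <- sprintf("ASV%04d", seq_len(cfg$n_asvs))
  # first block of the pool acts as the Lactobacillus-like dominant class
  n_dominant <- max(3, cfg$n_asvs %/% 20)
  dominant_pool <- asv_ids[seq_len(n_dominant)]

  meta <- list(); rows <- list(); truth <- list()
  thr_counts <- function(margin_lo, margin_hi) {
    lo <- ceiling(margin_lo * cfg$threshold * cfg$depth)
    hi <- max(lo, floor(margin_hi * cfg$threshold * cfg$depth))
    sample(lo:hi, 1)
  }

  for (d in seq_len(cfg$n_dyads)) {
    dyad_id <- sprintf("D%04d", d)
    mode <- sample(names(cfg$delivery_probs), 1, prob = cfg$delivery_probs)
    abx <- sample(names(cfg$antibiotic_probs), 1, prob = cfg$antibiotic_probs)
    has10 <- stats::runif(1) < cfg$p_10d
    has3m <- stats::runif(1) < cfg$p_3m
    if (!has10 && !has3m) has10 <- TRUE  # study design: >=1 infant sample

    dominant <- sample(dominant_pool, 1)
    eligible <- sample(setdiff(asv_ids, dominant), cfg$n_eligible)

    # planted maternal counts: dominant >> threshold, eligible at 2-30x
    mat_planted <- c(
      stats::setNames(round(cfg$depth * stats::runif(1, 0.4, 0.8)), dominant),
      stats::setNames(
        vapply(eligible, function(a) thr_counts(cfg$shared_margin, 30),
               numeric(1)), eligible))

    p_tr <- transfer_prob_for(cfg$p_transfer, mode)
    transferred <- c(dominant, eligible)[
      stats::runif(length(eligible) + 1) < p_tr]

    # per transferred ASV: pick target time points among available ones
    inf10_planted <- numeric(0); inf3m_planted <- numeric(0)
    ev <- list()
    for (a in transferred) {
      probs <- cfg$category_probs
      if (!has10) probs[c("ten_day_only", "both")] <- 0
      if (!has3m) probs[c("three_month_only", "both")] <- 0
      if (sum(probs) == 0) next
      cat_a <- sample(names(probs), 1, prob = probs)
      if (cat_a %in% c("ten_day_only", "both"))
        inf10_planted[a] <- thr_counts(cfg$shared_margin, 30)
      if (cat_a %in% c("three_month_only", "both"))
        inf3m_planted[a] <- thr_counts(cfg$shared_margin, 30)
      ev[[a]] <- tibble::tibble(dyad_id = dyad_id, asv_id = a,
                                category = cat_a)
    }
    truth[[dyad_id]] <- dplyr::bind_rows(ev)

    # non-transferred maternal ASVs leak into infants at <= unshared margin
    leak_counts <- function(asvs) {
      if (!length(asvs)) return(numeric(0))
      cap <- floor(cfg$unshared_margin * cfg$threshold * cfg$depth)
      stats::setNames(sample(0:cap, length(asvs), replace = TRUE), asvs)
    }
    not_tr <- setdiff(c(dominant, eligible), transferred)
    if (has10)
      inf10_planted <- c(inf10_planted,
                         leak_counts(setdiff(not_tr, names(inf10_planted))))
    if (has3m)
      inf3m_planted <- c(inf3m_planted,
                         leak_counts(setdiff(not_tr, names(inf3m_planted))))

    sample_counts <- function(planted, exclude) {
      planted <- planted[planted > 0]
      resid <- cfg$depth - sum(planted)
      if (resid < 0)
        stop("planted counts exceed depth; lower margins or n_eligible")
      bg_pool <- setdiff(asv_ids, c(names(planted), exclude))
      bg <- sample(bg_pool, min(cfg$n_background, length(bg_pool)))
      w <- stats::rgamma(length(bg), shape = cfg$dirichlet_rare)
      if (all(w == 0)) w <- rep(1, length(bg))
      bg_counts <- stats::rmultinom(1, resid, prob = w)[, 1]
      c(planted, stats::setNames(bg_counts, bg))
    }

    mk_row <- function(sid, counts) {
      counts <- counts[counts > 0]
      tibble::tibble(sample_id = sid, asv_id = names(counts),
                     count = as.integer(counts))
    }

    mat_sid <- paste0(dyad_id, "_M")
    mat_counts <- sample_counts(mat_planted, NULL)
    rows[[mat_sid]] <- mk_row(mat_sid, mat_counts)
    meta[[mat_sid]] <- tibble::tibble(
      sample_id = mat_sid, dyad_id = dyad_id,
      sample_type = "maternal_vaginal", time_point = "delivery",
      delivery_mode = mode, ip_antibiotics = abx)

    # infant background avoids every maternal ASV (background ones can sit
    # above threshold too) so shared presence is exactly the planted truth
    mat_any <- names(mat_counts)
    if (has10) {
      sid <- paste0(dyad_id, "_I10")
      rows[[sid]] <- mk_row(sid, sample_counts(inf10_planted, mat_any))
      meta[[sid]] <- tibble::tibble(
        sample_id = sid, dyad_id = dyad_id, sample_type = "infant_stool",
        time_point = "10_days", delivery_mode = mode, ip_antibiotics = abx)
    }
    if (has3m) {
      sid <- paste0(dyad_id, "_I3M")
      rows[[sid]] <- mk_row(sid, sample_counts(inf3m_planted, mat_any))
      meta[[sid]] <- tibble::tibble(
        sample_id = sid, dyad_id = dyad_id, sample_type = "infant_stool",
        time_point = "3_months", delivery_mode = mode, ip_antibiotics = abx)
    }
  }

  long <- dplyr::bind_rows(rows)
  meta <- dplyr::bind_rows(meta)
  counts <- tidyr::pivot_wider(long, names_from = "asv_id",
                               values_from = "count", values_fill = 0L)
  m <- as.matrix(counts[, -1, drop = FALSE])
  rownames(m) <- counts$sample_id
  m <- m[, sort(colnames(m)), drop = FALSE]

  events <- dplyr::bind_rows(truth)
  if (!nrow(events))
    events <- tibble::tibble(dyad_id = character(), asv_id = character(),
                             category = character())
  events <- dplyr::arrange(events, .data$dyad_id, .data$asv_id)

  structure(list(
    table = feature_table(m), meta = meta,
    truth = list(events = events, config = cfg, seed = seed)
  ), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d samples, %d planted transfer events (seed %s)\n",
              nrow(x$meta), nrow(x$truth$events), x$truth$seed))
  invisible(x)
}

#' Random reference genome
#'
#' @param length genome length in bases.
#' @param seed optional integer seed.
#' @param gc GC content, default 0.5.
#' @return character scalar over A/C/G/T.
#' @export
random_genome <- function(length, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Plant an exact number of substitutions into a genome
#'
#' Changes exactly `n_substitutions` distinct positions, each to a base
#' different from the original, and records positions and new bases so
#' downstream SNP counts can be scored against ground truth.
#'
#' @param reference character scalar over A/C/G/T.
#' @param n_substitutions number of positions to change (<= length).
#' @param seed optional integer seed.
#' @return mutated sequence with attributes `positions` (1-based) and
#'   `new_bases`.
#' @export
mutate_genome <- function(reference, n_substitutions, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  chars <- strsplit(toupper(reference), "", fixed = TRUE)[[1]]
  if (any(!chars %in% c("A", "C", "G", "T")))
    stop("reference must be over A/C/G/T")
  L <- length(chars)
  if (n_substitutions > L) stop("n_substitutions exceeds genome length")
  if (n_substitutions == 0) {
    out <- paste(chars, collapse = "")
    attr(out, "positions") <- integer(0)
    attr(out, "new_bases") <- character(0)
    return(out)
  }
  pos <- sort(sample.int(L, n_substitutions))
  bases <- c("A", "C", "G", "T")
  new <- vapply(chars[pos],
                function(b) sample(setdiff(bases, b), 1), character(1))
  chars[pos] <- new
  out <- paste(chars, collapse = "")
  attr(out, "positions") <- pos
  attr(out, "new_bases") <- unname(new)
  out
}

# mutation maps are named character vectors (names = positions relative to
# the root, values = current base). Composing a child's substitutions onto
# its parent's map keeps per-genome bookkeeping exact without rescanning
# sequences.
compose_map <- function(parent_map, root_chars, positions, new_bases) {
  map <- parent_map
  for (i in seq_along(positions)) {
    p <- as.character(positions[i])
    if (new_bases[i] == root_chars[positions[i]]) {
      map <- map[setdiff(names(map), p)]     # reverted to the root base
    } else {
      map[p] <- new_bases[i]
    }
  }
  map
}

map_distance <- function(map_a, map_b) {
  only_a <- setdiff(names(map_a), names(map_b))
  only_b <- setdiff(names(map_b), names(map_a))
  shared <- intersect(names(map_a), names(map_b))
  length(only_a) + length(only_b) + sum(map_a[shared] != map_b[shared])
}

#' Simulate a dyad-structured genome alignment with exact SNP ground truth
#'
#' Per dyad, an ancestor genome diverges from a global root by a
#' between-dyad substitution load (`between_rate` x `length`, Poisson),
#' then the maternal and infant genomes each diverge from that ancestor by
#' `within_subs` substitutions. Evolution is substitution-only, so the
#' genomes are returned as a gap-free alignment and pairwise SNP counts are
#' exact. Ground-truth pairwise distances are computed from per-genome
#' mutation bookkeeping (never by rescanning sequences).
#'
#' @param n_dyads number of dyads (two genomes each).
#' @param within_subs substitutions separating each of the maternal and
#'   infant genomes from their dyad ancestor (default 15, echoing
#'   transmission-scale SNP distances).
#' @param between_rate per-base substitution rate separating each dyad
#'   ancestor from the root (default 0.02, i.e. tens of thousands of
#'   substitutions at 1 Mb scale; between-dyad ANI ~ 96-98%).
#' @param length alignment length in bases (>= 10 kb recommended).
#' @param seed integer seed.
#' @return list of class `sim_genomes`: `$genomes` (aligned
#'   [genome_set()] with labels `genome_id`, `dyad_id`, `origin`),
#'   `$truth` (list with `$pairwise` tibble `genome_a`, `genome_b`,
#'   `planted_snps`, `within_dyad`; and `$seed`).
#' @export
simulate_genome_cohort <- function(n_dyads = 6, within_subs = 15,
                                   between_rate = 0.02, length = 20000,
                                   seed = 1) {
  withr::local_seed(as.integer(seed))
  root <- random_genome(length)
  root_chars <- strsplit(root, "", fixed = TRUE)[[1]]

  seqs <- character(0); maps <- list()
  labels <- list()
  for (d in seq_len(n_dyads)) {
    dyad_id <- sprintf("D%02d", d)
    n_between <- stats::rpois(1, between_rate * length)
    n_between <- min(n_between, length)
    anc <- mutate_genome(root, n_between)
    anc_map <- compose_map(stats::setNames(character(0), character(0)),
                           root_chars, attr(anc, "positions"),
                           attr(anc, "new_bases"))
    for (origin in c("maternal", "infant")) {
      g <- mutate_genome(as.character(anc), within_subs)
      gid <- sprintf("%s_%s", dyad_id, if (origin == "maternal") "M" else "I")
      seqs[gid] <- as.character(g)
      maps[[gid]] <- compose_map(anc_map, root_chars,
                                 attr(g, "positions"), attr(g, "new_bases"))
      labels[[gid]] <- tibble::tibble(genome_id = gid, dyad_id = dyad_id,
                                      origin = origin)
    }
  }
  labels <- dplyr::bind_rows(labels)

  ids <- names(seqs)
  pairs <- utils::combn(ids, 2)
  dyad_of <- stats::setNames(labels$dyad_id, labels$genome_id)
  pairwise <- tibble::tibble(
    genome_a = pairs[1, ], genome_b = pairs[2, ],
    planted_snps = vapply(seq_len(ncol(pairs)), function(i)
      map_distance(maps[[pairs[1, i]]], maps[[pairs[2, i]]]), numeric(1)),
    within_dyad = dyad_of[pairs[1, ]] == dyad_of[pairs[2, ]]
  )

  structure(list(
    genomes = genome_set(seqs, labels = labels, aligned = TRUE),
    truth = list(pairwise = pairwise, seed = seed)
  ), class = "sim_genomes")
}

#' Simulate a dyad-blocked gene presence/absence matrix
#'
#' All genomes carry the core genes; each dyad additionally carries a
#' private accessory block shared by its two genomes; remaining accessory
#' genes are present independently per genome with probability
#' `noise_prob`. The planted structure makes dyad-mates the most similar
#' pairs, so UPGMA on the Jaccard distances should recover each dyad as a
#' cherry.
#'
#' @param n_dyads number of dyads (two genomes each).
#' @param core_genes number of genes present in every genome.
#' @param accessory_genes size of the accessory pool.
#' @param dyad_shared_fraction fraction of the accessory pool partitioned
#'   into dyad-private shared blocks.
#' @param noise_prob presence probability of residual accessory genes.
#' @param seed integer seed.
#' @return list of class `sim_genes`: `$matrix` (logical genes x genomes),
#'   `$labels` (tibble `genome_id`, `dyad_id`, `origin`), `$truth` (list
#'   with `$block_genes` per dyad and `$seed`).
#' @export
simulate_gene_matrix <- function(n_dyads = 6, core_genes = 1500,
                                 accessory_genes = 300,
                                 dyad_shared_fraction = 0.6,
                                 noise_prob = 0.3, seed = 1) {
  stopifnot(dyad_shared_fraction >= 0, dyad_shared_fraction <= 1)
  withr::local_seed(as.integer(seed))
  gids <- as.vector(vapply(seq_len(n_dyads), function(d)
    sprintf("D%02d_%s", d, c("M", "I")), character(2)))
  labels <- tibble::tibble(
    genome_id = gids,
    dyad_id = rep(sprintf("D%02d", seq_len(n_dyads)), each = 2),
    origin = rep(c("maternal", "infant"), n_dyads))

  n_block_total <- round(accessory_genes * dyad_shared_fraction)
  block_size <- if (n_dyads > 0) n_block_total %/% n_dyads else 0
  n_noise <- accessory_genes - block_size * n_dyads
  genes <- c(sprintf("core%05d", seq_len(core_genes)),
             sprintf("acc%05d", seq_len(accessory_genes)))
  m <- matrix(FALSE, nrow = length(genes), ncol = length(gids),
              dimnames = list(genes, gids))
  m[seq_len(core_genes), ] <- TRUE

  acc_start <- core_genes
  block_genes <- list()
  for (d in seq_len(n_dyads)) {
    idx <- acc_start + (d - 1) * block_size + seq_len(block_size)
    cols <- labels$genome_id[labels$dyad_id == sprintf("D%02d", d)]
    m[idx, cols] <- TRUE
    block_genes[[sprintf("D%02d", d)]] <- genes[idx]
  }
  noise_idx <- (acc_start + block_size * n_dyads + 1):length(genes)
  if (n_noise > 0)
    m[noise_idx, ] <- matrix(
      stats::runif(n_noise * length(gids)) < noise_prob,
      nrow = n_noise)

  structure(list(matrix = m, labels = labels,
                 truth = list(block_genes = block_genes, seed = seed)),
            class = "sim_genes")
}
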
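#' Construct a labelled symmetric pairwise matrix
#'
#' Container for the three pairwise metrics the genomic analysis uses:
#' SNP counts (`snp_count`, diagonal 0), average nucleotide identity
#' (`ani`, diagonal 1), and gene-content Jaccard distance
#' (`jaccard_distance`, diagonal 0).
#'
#' @param values symmetric numeric matrix with genome ids as dimnames.
#' @param metric one of `"snp_count"`, `"ani"`, `"jaccard_distance"`.
#' @param labels optional tibble with `genome_id` and `dyad_id` (plus any
#'   other per-genome columns); needed by [partition_by_dyad()].
#' @return matrix of class `pairwise_matrix` with `metric` and `labels`
#'   attributes.
#' @export
pairwise_matrix <- function(values,
                            metric = c("snp_count", "ani", "jaccard_distance"),
                            labels = NULL) {
  metric <- match.arg(metric)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("pairwise matrix must be square")
  if (is.null(rownames(values)))
    stop("pairwise matrix must have genome ids as dimnames")
  if (is.null(colnames(values))) colnames(values) <- rownames(values)
  if (!identical(rownames(values), colnames(values)))
    stop("row and column ids differ")
  if (max(abs(values - t(values))) > 1e-9)
    stop("pairwise matrix must be symmetric")
  if (metric == "snp_count" && any(values < 0 | values != round(values)))
    stop("snp_count entries must be non-negative integers")
  if (!is.null(labels)) {
    stopifnot(all(c("genome_id") %in% names(labels)))
    missing <- setdiff(rownames(values), labels$genome_id)
    if (length(missing))
      stop("labels missing for genome(s): ", paste(missing, collapse = ", "))
    labels <- dplyr::slice(labels, match(rownames(values), labels$genome_id))
  }
  structure(values, metric = metric, labels = labels,
            class = c("pairwise_matrix", "matrix", "array"))
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("<pairwise_matrix> metric %s, %d genomes\n",
              attr(x, "metric"), nrow(x)))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Long tibble of the unordered off-diagonal pairs of a pairwise matrix
#'
#' @param x a `pairwise_matrix`.
#' @param ... unused.
#' @return tibble: `genome_a`, `genome_b`, `value`, and `within_dyad`
#'   (logical, when dyad labels are attached).
#' @export
tidy.pairwise_matrix <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  out <- tibble::tibble(
    genome_a = ids[idx[, 1]], genome_b = ids[idx[, 2]],
    value = x[idx]
  )
  labels <- attr(x, "labels")
  if (!is.null(labels) && "dyad_id" %in% names(labels)) {
    dyad <- labels$dyad_id[match(ids, labels$genome_id)]
    out$within_dyad <- dyad[idx[, 1]] == dyad[idx[, 2]] &
      !is.na(dyad[idx[, 1]]) & !is.na(dyad[idx[, 2]])
  }
  out
}

# integer-encode a sequence for fast mismatch counting:
# A/C/G/T -> 1..4, everything else (gap, N, ambiguity) -> NA
encode_acgt <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  match(chars, c("A", "C", "G", "T"))
}

#' Pairwise SNP distance matrix from a whole-genome alignment
#'
#' Entry (i, j) counts alignment columns where both genomes carry an
#' unambiguous base (`A/C/G/T`, case-insensitive) and the bases differ.
#' Columns with a gap or `N` in either sequence are skipped, following
#' snp-dists semantics.
#'
#' @param genomes an aligned [genome_set()].
#' @return `pairwise_matrix` with metric `snp_count`, carrying the set's
#'   labels.
#' @export
snp_distance_matrix <- function(genomes) {
  stopifnot(inherits(genomes, "genome_set"))
  if (!genomes$aligned)
    stop("snp_distance_matrix requires an aligned genome_set")
  enc <- lapply(genomes$sequences, encode_acgt)
  n <- length(enc)
  ids <- names(genomes$sequences)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (n < 2) stop("need at least two genomes")
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- enc[[i]]; b <- enc[[j]]
      ok <- !is.na(a) & !is.na(b)
      d <- sum(a[ok] != b[ok])
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  pairwise_matrix(m, metric = "snp_count", labels = genomes$labels)
}

revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# canonical k-mer multiplicity-free set of one sequence; k-mers containing
# N or - are dropped. Canonical = lexicographic min of k-mer and its
# reverse complement.
canonical_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) stop("sequence shorter than k")
  starts <- seq_len(L - k + 1)
  fwd <- substring(seq, starts, starts + k - 1)
  rcseq <- revcomp_chr(seq)
  # k-mer starting at i on the forward strand is the reverse complement of
  # the k-mer starting at L-k-i+2 on the reverse-complemented sequence
  rev <- substring(rcseq, L - k - starts + 2, L - starts + 1)
  keep <- !stringr::str_detect(fwd, "[^ACGT]")
  unique(pmin(fwd[keep], rev[keep]))
}

# order-scrambling hash of base-4-encoded k-mers for bottom-s MinHash
# sketching; exact in doubles for k <= 26
hash_kmers <- function(kmers) {
  k <- nchar(kmers[1])
  digits <- vapply(strsplit(kmers, "", fixed = TRUE), function(ch)
    sum((match(ch, c("A", "C", "G", "T")) - 1) * 4^(seq_len(k) - 1)),
    numeric(1))
  p <- 2147483647  # 2^31 - 1
  ((digits %% p) * 1103515 + 12345) %% p
}

#' k-mer Jaccard ANI estimate between two genomes
#'
#' Estimates average nucleotide identity from the Jaccard similarity `J` of
#' canonical k-mer sets via the Mash relation
#' `ANI = 1 + (1/k) * log(2J / (1 + J))`, clamped to \[0, 1\]. `J = 0`
#' yields `ani = 0` with `unrelated = TRUE`. Mode `"exact_sets"` uses the
#' full k-mer sets; `"minhash"` uses a bottom-`sketch_size` sketch of a
#' shared hash ordering (deterministic).
#'
#' @param genome_a,genome_b sequences (character scalars) of length >= k.
#' @param k odd k-mer size, default 21.
#' @param mode `"exact_sets"` or `"minhash"`.
#' @param sketch_size sketch size for minhash mode (default 1000).
#' @return one-row tibble: `ani`, `jaccard`, `n_kmers_a`, `n_kmers_b`,
#'   `mode`, `unrelated`.
#' @export
ani_estimate <- function(genome_a, genome_b, k = 21,
                         mode = c("exact_sets", "minhash"),
                         sketch_size = 1000) {
  mode <- match.arg(mode)
  if (k %% 2 == 0) stop("k must be odd")
  genome_a <- toupper(genome_a); genome_b <- toupper(genome_b)
  ka <- canonical_kmers(genome_a, k)
  kb <- canonical_kmers(genome_b, k)
  if (mode == "exact_sets") {
    J <- length(intersect(ka, kb)) / length(union(ka, kb))
  } else {
    ha <- sort(hash_kmers(ka)); hb <- sort(hash_kmers(kb))
    s <- min(sketch_size, length(ha), length(hb))
    merged <- sort(union(ha[seq_len(s)], hb[seq_len(s)]))
    merged <- merged[seq_len(min(s, length(merged)))]
    J <- sum(merged %in% ha & merged %in% hb) / length(merged)
  }
  if (J > 0) {
    ani <- 1 + log(2 * J / (1 + J)) / k
    ani <- min(max(ani, 0), 1)
  } else {
    ani <- 0
  }
  tibble::tibble(ani = ani, jaccard = J,
                 n_kmers_a = length(ka), n_kmers_b = length(kb),
                 mode = mode, unrelated = J == 0)
}

#' Pairwise ANI matrix over a genome set
#'
#' @param genomes a [genome_set()] (assemblies or alignment rows; gaps are
#'   ignored by k-mer extraction).
#' @inheritParams ani_estimate
#' @return `pairwise_matrix` with metric `ani` (diagonal 1).
#' @export
ani_matrix <- function(genomes, k = 21, mode = c("exact_sets", "minhash"),
                       sketch_size = 1000) {
  stopifnot(inherits(genomes, "genome_set"))
  mode <- match.arg(mode)
  seqs <- gsub("-", "", genomes$sequences, fixed = TRUE)
  ids <- names(seqs)
  n <- length(ids)
  m <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- ani_estimate(seqs[[i]], seqs[[j]], k = k, mode = mode,
                        sketch_size = sketch_size)$ani
      m[i, j] <- a; m[j, i] <- a
    }
  }
  pairwise_matrix(m, metric = "ani", labels = genomes$labels)
}

#' Gene-content Jaccard distance matrix
#'
#' Distance between genomes i and j is `1 - |Gi intersect Gj| / |Gi union
#' Gj|` over their gene sets. Two genomes with empty gene sets are at
#' distance 0 from each other and 1 from any non-empty genome.
#'
#' @param gene_matrix logical genes x genomes matrix
#'   (see [read_gene_matrix()]).
#' @param labels optional per-genome labels tibble.
#' @return `pairwise_matrix` with metric `jaccard_distance`.
#' @export
jaccard_gene_distance <- function(gene_matrix, labels = NULL) {
  gm <- gene_matrix * 1L
  inter <- crossprod(gm)                      # genomes x genomes
  sizes <- colSums(gm)
  uni <- outer(sizes, sizes, "+") - inter
  d <- ifelse(uni > 0, 1 - inter / uni, 0)
  diag(d) <- 0
  dimnames(d) <- list(colnames(gene_matrix), colnames(gene_matrix))
  pairwise_matrix(d, metric = "jaccard_distance", labels = labels)
}

#' UPGMA clustering of a pairwise distance matrix
#'
#' Standard size-weighted average-linkage agglomeration producing a rooted
#' ultrametric tree; branch lengths are merge-height differences (leaf
#' depth = merge height / 2). Labels are sorted lexicographically before
#' clustering so tie-breaking is deterministic.
#'
#' @param matrix a `pairwise_matrix` of distances (`snp_count` or
#'   `jaccard_distance`; for ANI cluster on `1 - ani`).
#' @return an [ape::phylo] tree with leaf labels = genome ids.
#' @export
upgma <- function(matrix) {
  stopifnot(inherits(matrix, "pairwise_matrix"))
  if (nrow(matrix) < 2) stop("need at least two genomes to cluster")
  if (any(diag(matrix) != 0)) stop("distance matrix must have zero diagonal")
  ord <- order(rownames(matrix))
  m <- unclass(matrix)[ord, ord]
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  tree <- ape::as.phylo(hc)   # heights halved -> ultrametric
  # canonical child order: rotate towards the sorted tip sequence so the
  # newick serialization is deterministic under distance ties
  ape::rotateConstr(tree, sort(tree$tip.label))
}

#' Check that a tree is ultrametric (equal root-to-leaf depths)
#'
#' @param tree an [ape::phylo].
#' @param tol numeric tolerance on depth differences.
#' @return logical scalar.
#' @export
is_ultrametric <- function(tree, tol = 1e-9) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  max(depths) - min(depths) <= tol
}

#' Partition the pairs of a matrix into within- and between-dyad sets
#'
#' Splits all unordered off-diagonal pairs by whether the two genomes share
#' a dyad label, reports the two medians, and (when both sides are
#' non-empty) a Mann-Whitney U comparison. A dyad contributing a single
#' genome yields only between-pairs.
#'
#' @param matrix a `pairwise_matrix` whose labels carry `dyad_id`.
#' @return object of class `dyad_partition`: `$within`, `$between` (numeric
#'   vectors), `$median_within`, `$median_between`, `$test`
#'   (a `two_sample_result` or `NULL` when one side is empty), `$metric`.
#' @export
partition_by_dyad <- function(matrix) {
  stopifnot(inherits(matrix, "pairwise_matrix"))
  labels <- attr(matrix, "labels")
  if (is.null(labels) || !"dyad_id" %in% names(labels))
    stop("matrix must carry per-genome dyad_id labels")
  pairs <- tidy(matrix)
  within <- pairs$value[pairs$within_dyad]
  between <- pairs$value[!pairs$within_dyad]
  test <- if (length(within) && length(between))
    mann_whitney(within, between) else NULL
  structure(list(
    within = within, between = between,
    median_within = if (length(within)) stats::median(within) else NA_real_,
    median_between = if (length(between)) stats::median(between) else NA_real_,
    test = test, metric = attr(matrix, "metric")
  ), class = "dyad_partition")
}

#' @export
print.dyad_partition <- function(x, ...) {
  cat(sprintf(
    "<dyad_partition> %s: %d within-dyad pairs (median %.6g) vs %d between (median %.6g)\n",
    x$metric, length(x$within), x$median_within,
    length(x$between), x$median_between))
  if (!is.null(x$test))
    cat(sprintf("  Mann-Whitney U = %.4g, p = %.4g\n",
                x$test$statistic, x$test$p_value))
  else cat("  comparison not testable (one side empty)\n")
  invisible(x)
}

#' @rdname partition_by_dyad
#' @param x a `dyad_partition`.
#' @param ... unused.
#' @export
tidy.dyad_partition <- function(x, ...) {
  tibble::tibble(
    side = rep(c("within", "between"), c(length(x$within), length(x$between))),
    value = c(x$within, x$between)
  )
}

#' @rdname partition_by_dyad
#' @export
glance.dyad_partition <- function(x, ...) {
  tibble::tibble(
    metric = x$metric,
    n_within = length(x$within), n_between = length(x$between),
    median_within = x$median_within, median_between = x$median_between,
    p_value = if (is.null(x$test)) NA_real_ else x$test$p_value
  )
}

#' Per-dyad strain identity calls from a pairwise matrix
#'
#' A dyad is called `identical` when any of its maternal-infant genome
#' pairs passes the active threshold: ANI strictly greater than
#' `ani_threshold` (default 0.999), or SNP count less than or equal to
#' `snp_threshold` (default 25), depending on the matrix metric. Dyads with
#' genomes from only one side are `not_assessable`.
#'
#' @param matrix a `pairwise_matrix` (metric `ani` or `snp_count`) whose
#'   labels carry `dyad_id` and `origin`.
#' @param ani_threshold ANI fraction above which a pair is identical.
#' @param snp_threshold SNP count at/below which a pair is identical.
#' @return tibble: `dyad_id`, `call` (`identical` / `nonidentical` /
#'   `not_assessable`), `best_value` (max ANI or min SNPs over
#'   maternal-infant pairs), `n_pairs`.
#' @export
strain_identity_call <- function(matrix, ani_threshold = 0.999,
                                 snp_threshold = 25) {
  stopifnot(inherits(matrix, "pairwise_matrix"))
  metric <- attr(matrix, "metric")
  if (!metric %in% c("ani", "snp_count"))
    stop("identity calls need an ani or snp_count matrix")
  labels <- attr(matrix, "labels")
  if (is.null(labels) || !all(c("dyad_id", "origin") %in% names(labels)))
    stop("matrix labels must carry dyad_id and origin")
  ids <- rownames(matrix)
  lab <- dplyr::slice(labels, match(ids, labels$genome_id))
  purrr::map_dfr(sort(unique(lab$dyad_id)), function(d) {
    mat_ids <- ids[lab$dyad_id == d & lab$origin == "maternal"]
    inf_ids <- ids[lab$dyad_id == d & lab$origin == "infant"]
    if (!length(mat_ids) || !length(inf_ids))
      return(tibble::tibble(dyad_id = d, call = "not_assessable",
                            best_value = NA_real_, n_pairs = 0L))
    vals <- as.vector(unclass(matrix)[mat_ids, inf_ids, drop = FALSE])
    if (metric == "ani") {
      best <- max(vals); hit <- best > ani_threshold
    } else {
      best <- min(vals); hit <- best <= snp_threshold
    }
    tibble::tibble(dyad_id = d,
                   call = if (hit) "identical" else "nonidentical",
                   best_value = best,
                   n_pairs = length(vals))
  })
}
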
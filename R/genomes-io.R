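#' Construct a genome set
#'
#' A genome set holds DNA sequences (assemblies or rows of a whole-genome
#' alignment) with per-genome labels: dyad, origin (maternal/infant), and
#' optional species and delivery mode.
#'
#' @param sequences named character vector of sequences over
#'   `A C G T N -` (case-insensitive).
#' @param labels optional tibble with `genome_id` plus any of `dyad_id`,
#'   `origin`, `species`, `delivery_mode`.
#' @param aligned logical: are the sequences rows of one alignment
#'   (equal length required)?
#' @return object of class `genome_set`: list with `$sequences`, `$labels`,
#'   `$aligned`.
#' @export
genome_set <- function(sequences, labels = NULL, aligned = FALSE) {
  if (!length(sequences)) stop("empty genome set")
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    stop("sequences must be named by genome_id")
  validate_ids(names(sequences), "genome")
  sequences <- toupper(sequences)
  if (any(nchar(sequences) == 0)) stop("empty sequence(s)")
  bad <- stringr::str_detect(sequences, "[^ACGTN-]")
  if (any(bad))
    stop("illegal characters (outside A/C/G/T/N/-) in: ",
         paste(names(sequences)[bad], collapse = ", "))
  if (aligned && length(unique(nchar(sequences))) != 1)
    stop("alignment mode requires equal-length sequences")
  if (is.null(labels)) {
    labels <- tibble::tibble(genome_id = names(sequences))
  } else {
    stopifnot("genome_id" %in% names(labels))
    missing <- setdiff(names(sequences), labels$genome_id)
    if (length(missing))
      stop("labels missing for genome(s): ", paste(missing, collapse = ", "))
    labels <- dplyr::slice(labels,
                           match(names(sequences), labels$genome_id))
  }
  structure(list(sequences = sequences, labels = tibble::as_tibble(labels),
                 aligned = aligned),
            class = "genome_set")
}

#' Read genomes or a whole-genome alignment from FASTA
#'
#' @param path multi-FASTA file.
#' @param aligned logical; `TRUE` (default) enforces equal-length records
#'   (alignment mode), `FALSE` reads free-length assemblies.
#' @param labels optional labels tibble (see [genome_set()]) or path to a
#'   TSV read with [read_genome_labels()].
#' @return a `genome_set`.
#' @export
read_alignment <- function(path, aligned = TRUE, labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("empty FASTA: ", path)
  seqs <- as.character(set)
  names(seqs) <- stringr::word(names(set), 1)   # drop FASTA descriptions
  if (is.character(labels) && length(labels) == 1)
    labels <- read_genome_labels(labels)
  genome_set(seqs, labels = labels, aligned = aligned)
}

#' Read per-genome labels
#'
#' @param path TSV with column `genome_id` plus any of `dyad_id`, `origin`,
#'   `species`, `delivery_mode`.
#' @return tibble.
#' @export
read_genome_labels <- function(path) {
  lab <- read_delim_auto(path)
  if (!"genome_id" %in% names(lab))
    stop("labels file must have a genome_id column")
  if ("origin" %in% names(lab))
    check_vocab(lab$origin, c("maternal", "infant"), "origin")
  tibble::as_tibble(lab)
}

#' @export
print.genome_set <- function(x, ...) {
  cat(sprintf("<genome_set> %d genome(s), %s, length %s\n",
              length(x$sequences),
              if (x$aligned) "aligned" else "unaligned",
              paste(range(nchar(x$sequences)), collapse = "-")))
  invisible(x)
}

#' Write / read a labelled pairwise matrix as TSV
#'
#' The TSV has genome ids as both the header row and the first column, so
#' `read_matrix(write_matrix(m))` round-trips exactly.
#'
#' @param matrix a [pairwise_matrix()].
#' @param path output TSV path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns a
#'   `pairwise_matrix`.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "pairwise_matrix"))
  df <- tibble::as_tibble(unclass(matrix), rownames = "genome_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix
#' @param metric metric name recorded on the read matrix
#'   (`snp_count`, `ani`, or `jaccard_distance`).
#' @param labels optional labels tibble attached to the matrix.
#' @export
read_matrix <- function(path, metric = "snp_count", labels = NULL) {
  df <- read_delim_auto(path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  pairwise_matrix(m, metric = metric, labels = labels)
}

#' Read a gene presence/absence matrix
#'
#' Two dialects: `"binary"` — a plain CSV/TSV of 0/1 with gene rows and a
#' first column of gene names; `"roary"` — a Roary
#' `gene_presence_absence.csv`, where a non-empty cell marks presence and
#' the genome columns start at `first_genome_col` (Roary writes 14 metadata
#' columns, so the default is 15).
#'
#' @param path file path.
#' @param dialect `"binary"` or `"roary"`.
#' @param first_genome_col index of the first genome column (roary dialect).
#' @return logical matrix, genes x genomes.
#' @export
read_gene_matrix <- function(path, dialect = c("binary", "roary"),
                             first_genome_col = 15) {
  dialect <- match.arg(dialect)
  df <- read_delim_auto(path)
  if (dialect == "binary") {
    genes <- as.character(df[[1]])
    if (nrow(df) == 0) {
      m <- matrix(logical(0), nrow = 0, ncol = ncol(df) - 1,
                  dimnames = list(NULL, names(df)[-1]))
      return(m)
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m) || !all(m %in% c(0, 1)))
      stop("binary gene matrix must contain only 0/1")
    m <- m == 1
  } else {
    if (first_genome_col > ncol(df))
      stop("first_genome_col beyond the last column")
    genes <- as.character(df[[1]])
    block <- df[, first_genome_col:ncol(df), drop = FALSE]
    m <- vapply(block, function(col) !is.na(col) & col != "",
                logical(nrow(df)))
    m <- matrix(m, nrow = nrow(df),
                dimnames = list(NULL, names(block)))
  }
  rownames(m) <- genes
  m
}

#' Write a tree to newick
#'
#' @param tree an [ape::phylo] tree (e.g. from [upgma()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
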
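#' Shared identical k-mer counts between cluster members
#'
#' For every pair of member sequences, counts the number of *distinct* k-mers
#' (default k = 28, the trimmed read length) present in both. This is the
#' mappability question a short read poses: a read is ambiguous between two
#' members exactly when its sequence is a k-mer the two share. The diagonal
#' holds each member's own distinct k-mer count (at most length - k + 1).
#' Set semantics, not occurrence pairs: a k-mer occurring twice in one member
#' still counts once.
#'
#' @param x An `ncrna_cluster`, a locus `data.frame` with `locus_id` and
#'   `sequence` columns, or a named character vector of sequences.
#' @param k k-mer length in nt (default 28).
#' @param both_strands If `TRUE`, each member's k-mer set also includes the
#'   reverse complements (for members whose strand is unresolved). Default
#'   `FALSE`: member sequences are already strand-resolved.
#' @return A symmetric integer matrix with locus ids as dimnames and
#'   attribute `k`. Members shorter than k are excluded with a warning.
#' @export
kmer_similarity <- function(x, k = 28, both_strands = FALSE) {
  stopifnot(k >= 1)
  seqs <- member_sequences(x)
  short <- nchar(seqs) < k
  if (any(short)) {
    warning("excluding member(s) shorter than k = ", k, ": ",
            paste(names(seqs)[short], collapse = ", "), call. = FALSE)
    seqs <- seqs[!short]
  }
  sets <- lapply(seqs, kmer_set, k = k)
  if (both_strands)
    sets <- Map(function(s, q) unique(c(s, kmer_set(revcomp(q), k))),
                sets, seqs)
  n <- length(sets)
  m <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) {
    m[i, i] <- length(sets[[i]])
    for (j in seq_len(i - 1L)) {
      m[i, j] <- m[j, i] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  attr(m, "k") <- as.integer(k)
  m
}

member_sequences <- function(x) {
  if (inherits(x, "ncrna_cluster"))
    return(setNames(x$members$sequence, x$members$locus_id))
  if (is.data.frame(x))
    return(setNames(x$sequence, x$locus_id))
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  stop("cannot extract member sequences from ", class(x)[1], call. = FALSE)
}

#' Partition cluster members into read-discriminable groups
#'
#' Builds the graph whose vertices are members and whose edges join pairs
#' sharing at least `threshold` identical k-mers, and returns its connected
#' components as groups. By construction a perfect-match read of length k can
#' align to members of at most one group, so unique reads confined to a group
#' measure that group's expression. Groups are labeled "I", "II", ... in
#' order of first member appearance, which is deterministic.
#'
#' A cluster whose components are all singletons is *member-discriminable*
#' (every member can receive member-exclusive reads); a single-component
#' cluster can only be quantified at cluster level.
#'
#' @param matrix Symmetric k-mer similarity matrix from [kmer_similarity()].
#' @param threshold Minimum shared k-mers for an edge (default 1).
#' @return `data.frame` with columns `locus_id`, `group`, plus attribute
#'   `discriminability` with value `"member"` (all singletons), `"cluster"`
#'   (one group) or `"grouped"`.
#' @export
partition_groups <- function(matrix, threshold = 1) {
  if (!isSymmetric(unclass(matrix), check.attributes = FALSE))
    stop("similarity matrix must be symmetric", call. = FALSE)
  adj <- matrix >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # relabel components by first appearance along the member order
  first_seen <- unique(comp)
  label_idx <- match(comp, first_seen)
  out <- data.frame(locus_id = rownames(matrix),
                    group = as.character(utils::as.roman(label_idx)),
                    stringsAsFactors = FALSE)
  n_groups <- length(first_seen)
  attr(out, "discriminability") <-
    if (n_groups == nrow(out)) "member"
    else if (n_groups == 1L) "cluster"
    else "grouped"
  out
}

#' Per-member count of member-exclusive k-mers
#'
#' For each cluster member, counts the k-mers found in no other member. A
#' member with zero exclusive k-mers can never receive a member-exclusive
#' read of length k, so its individual expression is unmeasurable by
#' perfect-match reads; a fully exclusive member is measurable read-by-read
#' (the member-discriminable case).
#'
#' @inheritParams kmer_similarity
#' @return `data.frame` with columns `locus_id`, `n_kmers` (distinct k-mers)
#'   and `n_unique_kmers` (k-mers exclusive to that member).
#' @export
discriminability_report <- function(x, k = 28, both_strands = FALSE) {
  seqs <- member_sequences(x)
  seqs <- seqs[nchar(seqs) >= k]
  sets <- lapply(seqs, kmer_set, k = k)
  if (both_strands)
    sets <- Map(function(s, q) unique(c(s, kmer_set(revcomp(q), k))),
                sets, seqs)
  n_unique <- vapply(seq_along(sets), function(i) {
    others <- unique(unlist(sets[-i], use.names = FALSE))
    sum(!sets[[i]] %in% others)
  }, integer(1))
  data.frame(locus_id = names(seqs),
             n_kmers = lengths(sets),
             n_unique_kmers = n_unique,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a similarity matrix as TSV
#'
#' Square tab-separated table with member ids as both header row and first
#' column, mirroring how pairwise shared-28-mer tables are published.
#'
#' @param matrix Matrix from [kmer_similarity()].
#' @param path Output path.
#' @export
write_similarity <- function(matrix, path) {
  df <- data.frame(locus_id = rownames(matrix), matrix, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity matrix written by [write_similarity()]
#'
#' @param path TSV path.
#' @param k k-mer length to record on the matrix attribute (default 28).
#' @return Integer matrix with `k` attribute.
#' @export
read_similarity <- function(path, k = 28) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  attr(m, "k") <- as.integer(k)
  m
}
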
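#' Read a genome FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that truncates FASTA
#' headers at the first whitespace so sequence names match annotation
#' chromosome names.
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Load a feature annotation table and attach genomic sequences
#'
#' Reads a tab-separated annotation with header columns `locus_id`, `name`,
#' `chrom`, `start`, `end`, `strand`, `rna_class` and (optionally) `cluster`,
#' extracts each locus sequence from the genome and reverse-complements it for
#' minus-strand loci. Coordinates are held internally as 0-based half-open;
#' browser-style 1-based inclusive input is converted with `coords =
#' "browser"`.
#'
#' @param path Path to the annotation TSV.
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param coords Coordinate convention of the file: `"bed"` (0-based
#'   half-open, the default) or `"browser"` (1-based inclusive).
#' @return A `data.frame` of loci with columns `locus_id`, `name`, `chrom`,
#'   `start`, `end`, `strand`, `rna_class`, `cluster`, `sequence`; one row per
#'   genomic locus, coordinates 0-based half-open.
#' @export
load_annotation <- function(path, genome, coords = c("bed", "browser")) {
  coords <- match.arg(coords)
  if (is.character(genome)) genome <- read_genome(genome)
  ann <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = list(chrom = "character"))
  required <- c("locus_id", "name", "chrom", "start", "end", "strand",
                "rna_class")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols) > 0)
    stop("annotation is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"cluster" %in% names(ann)) ann$cluster <- ann$name
  if (coords == "browser") ann$start <- ann$start - 1L
  ann$start <- as.integer(ann$start)
  ann$end <- as.integer(ann$end)
  validate_loci(ann, genome)
  ann$rna_class <- canonical_class(ann$rna_class)
  ann$sequence <- extract_sequences(ann, genome)
  ann[c("locus_id", "name", "chrom", "start", "end", "strand", "rna_class",
        "cluster", "sequence")]
}

validate_loci <- function(ann, genome = NULL) {
  if (anyDuplicated(ann$locus_id))
    stop("duplicate locus_id: ",
         paste(unique(ann$locus_id[duplicated(ann$locus_id)]), collapse = ", "),
         call. = FALSE)
  check_strand(ann$strand)
  bad <- ann$end <= ann$start | ann$start < 0
  if (any(bad))
    stop("invalid interval (need end > start >= 0) at row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  if (!is.null(genome)) {
    absent <- !ann$chrom %in% names(genome)
    if (any(absent)) {
      i <- which(absent)[1]
      stop("chromosome '", ann$chrom[i], "' (row ", i,
           ", locus ", ann$locus_id[i], ") not present in genome", call. = FALSE)
    }
    too_long <- ann$end > Biostrings::width(genome)[match(ann$chrom,
                                                          names(genome))]
    if (any(too_long))
      stop("locus extends past chromosome end at row(s): ",
           paste(which(too_long), collapse = ", "), call. = FALSE)
  }
  invisible(ann)
}

# strand-resolved sequence of each locus (reverse complement on minus strand)
extract_sequences <- function(ann, genome) {
  vapply(seq_len(nrow(ann)), function(i) {
    s <- Biostrings::subseq(genome[[ann$chrom[i]]],
                            start = ann$start[i] + 1L, end = ann$end[i])
    if (ann$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1))
}

#' Write an annotation table
#'
#' Inverse of [load_annotation()]: writes the tabular columns (sequences are
#' re-extracted from the genome on reload, so they are not stored).
#'
#' @param loci Locus `data.frame` as returned by [load_annotation()].
#' @param path Output path.
#' @param coords Coordinate convention to write (`"bed"` or `"browser"`).
#' @export
write_annotation <- function(loci, path, coords = c("bed", "browser")) {
  coords <- match.arg(coords)
  out <- loci[c("locus_id", "name", "chrom", "start", "end", "strand",
                "rna_class", "cluster")]
  if (coords == "browser") out$start <- out$start + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop loci of excluded RNA classes
#'
#' Removes feature classes that should not enter cluster quantification.
#' The default exclusion set (pseudogenes, miRNAs, tRNAs, rRNAs) reflects
#' classes whose reads are unreliable under a polyA-neutral short-read
#' protocol or are quantified separately; pass a different set to retain
#' them (tRNA and lincRNA quantification need them kept).
#'
#' @param loci Locus `data.frame`.
#' @param excluded Character vector of `rna_class` values to remove; must be
#'   drawn from the closed class vocabulary.
#' @return The loci whose class is not excluded, original order preserved.
#' @export
filter_classes <- function(loci,
                           excluded = c("pseudogene", "miRNA", "tRNA", "rRNA")) {
  if (length(excluded) > 0) excluded <- canonical_class(excluded)
  loci[!loci$rna_class %in% excluded, , drop = FALSE]
}

#' Assemble ncRNA clusters from related loci
#'
#' Genes annotated as "related" copies of one RNA (for example a gene and its
#' `-related` duplicates) are combined into a single cluster while every
#' genomic location is preserved as a member. The cluster's effective length
#' for RPKM normalization is the *median* member length: a cluster expresses
#' one RNA species of roughly that length, however many genomic copies exist,
#' so normalizing by the summed copy length would dilute true expression.
#'
#' @param loci Locus `data.frame` (typically after [filter_classes()]).
#' @param relatedness Mapping from locus `name` to cluster name: a named
#'   character vector, a two-column `data.frame` (name, cluster_name), or
#'   `NULL` to use the loci's own `cluster` column. Every locus name must be
#'   mapped; identity mappings give singleton clusters.
#' @return A named list of `ncrna_cluster` objects; the number of clusters is
#'   reported as a message.
#' @export
build_clusters <- function(loci, relatedness = NULL) {
  if (anyDuplicated(loci$locus_id))
    stop("duplicate locus_id: ",
         paste(unique(loci$locus_id[duplicated(loci$locus_id)]),
               collapse = ", "), call. = FALSE)
  if (is.null(relatedness)) {
    cluster_of <- loci$cluster
    if (is.null(cluster_of))
      stop("no relatedness mapping given and loci carry no cluster column",
           call. = FALSE)
  } else {
    if (is.data.frame(relatedness))
      relatedness <- setNames(relatedness[[2]], relatedness[[1]])
    unmapped <- setdiff(unique(loci$name), names(relatedness))
    if (length(unmapped) > 0)
      stop("locus name(s) absent from relatedness mapping: ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    cluster_of <- unname(relatedness[loci$name])
  }
  ids <- unique(cluster_of)
  clusters <- lapply(ids, function(cid) {
    new_ncrna_cluster(cid, loci[cluster_of == cid, , drop = FALSE])
  })
  names(clusters) <- ids
  message("identified ", length(clusters), " ncRNA clusters")
  clusters
}

#' Construct an ncRNA cluster
#'
#' @param cluster_id Cluster name.
#' @param members Locus `data.frame` rows for all genomic copies.
#' @param effective_length Length (nt) used for RPKM; defaults to the median
#'   member length (see [build_clusters()]).
#' @param groups Optional `data.frame` (locus_id, group) partitioning the
#'   members, as returned by [partition_groups()].
#' @return An object of class `ncrna_cluster`.
#' @export
new_ncrna_cluster <- function(cluster_id, members, effective_length = NULL,
                              groups = NULL) {
  stopifnot(is.data.frame(members), nrow(members) > 0)
  if (is.null(effective_length))
    effective_length <- median(members$end - members$start)
  if (effective_length <= 0) stop("effective_length must be > 0", call. = FALSE)
  obj <- structure(list(cluster_id = cluster_id, members = members,
                        effective_length = as.numeric(effective_length),
                        groups = NULL),
                   class = "ncrna_cluster")
  if (!is.null(groups)) obj <- set_groups(obj, groups)
  obj
}

#' Attach a group partition to a cluster
#'
#' @param cluster An `ncrna_cluster`.
#' @param groups `data.frame` with columns `locus_id` and `group`; must be a
#'   partition of the cluster members (each member in exactly one group).
#' @return The cluster with groups set.
#' @export
set_groups <- function(cluster, groups) {
  stopifnot(inherits(cluster, "ncrna_cluster"))
  ids <- cluster$members$locus_id
  if (!setequal(groups$locus_id, ids) || anyDuplicated(groups$locus_id))
    stop("groups must partition the cluster members exactly", call. = FALSE)
  groups$group <- as.character(groups$group)
  cluster$groups <- groups[match(ids, groups$locus_id), , drop = FALSE]
  rownames(cluster$groups) <- NULL
  cluster
}

#' @export
print.ncrna_cluster <- function(x, ...) {
  cat("ncRNA cluster '", x$cluster_id, "': ", nrow(x$members),
      " member(s), effective length ", x$effective_length, " nt", sep = "")
  if (!is.null(x$groups)) {
    sizes <- table(x$groups$group)
    cat(", groups: ", paste(names(sizes), sizes, sep = "=", collapse = " "),
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Export cluster members as BED6
#'
#' One BED line per member locus (0-based half-open, as BED requires), named
#' `cluster_id|locus_id`, for genome-browser inspection.
#'
#' @param clusters List of `ncrna_cluster` objects.
#' @param path Output BED path.
#' @export
export_clusters_bed <- function(clusters, path) {
  rows <- do.call(rbind, lapply(clusters, function(cl) {
    data.frame(chrom = cl$members$chrom, start = cl$members$start,
               end = cl$members$end,
               name = paste(cl$cluster_id, cl$members$locus_id, sep = "|"),
               score = 0L, strand = cl$members$strand)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
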
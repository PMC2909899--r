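# Read counting at mRNA / cluster / group / member scope, RPKM with Poisson
# uncertainties. All counting is "unique read" counting: a sequenced read
# contributes at most once per feature however many placements it has.

# strand-correct overlap hits between alignments and feature rows:
# >= 1 nt intersection and matching strand
feature_hits <- function(aln, features) {
  ov <- GenomicRanges::findOverlaps(as_granges(aln), as_granges(features),
                                    ignore.strand = TRUE)
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  data.frame(aln_row = q, feat_row = s,
             read_id = aln$read_id[q],
             same_strand = aln$strand[q] == features$strand[s],
             stringsAsFactors = FALSE)
}

#' Count reads per mRNA transcript (single-gene reads only)
#'
#' A read contributes to a transcript if and only if (a) across all of its
#' genomic placements it overlaps exactly one gene, and (b) at least one
#' placement overlaps that gene in the correct orientation (same strand).
#' Reads touching two genes -- e.g. a placement inside an overlapping gene
#' pair -- are counted for neither, which keeps overlapping annotations from
#' double-claiming reads.
#'
#' @param aln Alignment `data.frame` (see [read_alignments()]).
#' @param transcripts Locus `data.frame` of transcripts.
#' @return `data.frame` with columns `locus_id`, `count`, one row per
#'   transcript (zeros included).
#' @export
count_mrna <- function(aln, transcripts) {
  counts <- integer(nrow(transcripts))
  h <- feature_hits(aln, transcripts)
  if (nrow(h) > 0) {
    genes_per_read <- tapply(h$feat_row, h$read_id,
                             function(x) length(unique(x)))
    single <- names(genes_per_read)[genes_per_read == 1L]
    hs <- h[h$read_id %in% single & h$same_strand, , drop = FALSE]
    if (nrow(hs) > 0) {
      per_feat <- tapply(hs$read_id, hs$feat_row,
                         function(x) length(unique(x)))
      counts[as.integer(names(per_feat))] <- as.integer(per_feat)
    }
  }
  data.frame(locus_id = transcripts$locus_id, count = counts,
             stringsAsFactors = FALSE)
}

# read ids contributing to a cluster; lenient keeps reads that also align
# outside the cluster (the default: merging all genomic copies into the
# cluster exists precisely so such reads stay countable), strict drops them
cluster_read_ids <- function(aln, cluster, mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  h <- feature_hits(aln, cluster$members)
  ids <- unique(h$read_id[h$same_strand])
  if (mode == "strict" && length(ids) > 0) {
    # reads with >= 1 placement that touches no cluster member at all
    outside_rows <- setdiff(seq_len(nrow(aln)), unique(h$aln_row))
    ids <- setdiff(ids, unique(aln$read_id[outside_rows]))
  }
  ids
}

#' Count unique reads mapping to any member of a cluster
#'
#' A read contributes exactly once if at least one of its placements overlaps
#' any cluster member on the correct strand; multiple placements within the
#' cluster never multiply the count.
#'
#' @param aln Alignment `data.frame`.
#' @param cluster An `ncrna_cluster`.
#' @param mode `"lenient"` (default) also counts reads that additionally
#'   align outside the cluster; `"strict"` excludes them.
#' @return Integer count.
#' @export
count_cluster <- function(aln, cluster, mode = c("lenient", "strict")) {
  length(cluster_read_ids(aln, cluster, mode))
}

#' Group-specific unique-read counts within a cluster
#'
#' Each cluster-contributing read is assigned to group g when *every* one of
#' its member-overlapping placements falls on members of g; reads whose
#' placements span two or more groups go to the ambiguous bin, never silently
#' dropped. Group counts plus the ambiguous bin always sum exactly to the
#' cluster count.
#'
#' @inheritParams count_cluster
#' @return List with `counts` (named integer vector per group label),
#'   `ambiguous` and `cluster_count`.
#' @export
count_groups <- function(aln, cluster, mode = c("lenient", "strict")) {
  if (is.null(cluster$groups))
    stop("cluster '", cluster$cluster_id, "' has no groups; run ",
         "partition_groups() and set_groups() first", call. = FALSE)
  mode <- match.arg(mode)
  labels <- unique(cluster$groups$group)
  ids <- cluster_read_ids(aln, cluster, mode)
  h <- feature_hits(aln, cluster$members)
  h <- h[h$same_strand & h$read_id %in% ids, , drop = FALSE]
  group_of_member <- cluster$groups$group
  counts <- setNames(integer(length(labels)), labels)
  ambiguous <- 0L
  if (nrow(h) > 0) {
    touched <- tapply(group_of_member[h$feat_row], h$read_id,
                      function(g) unique(g), simplify = FALSE)
    one_group <- vapply(touched, length, integer(1)) == 1L
    ambiguous <- sum(!one_group)
    tab <- table(unlist(touched[one_group], use.names = FALSE))
    counts[names(tab)] <- as.integer(tab)
  }
  list(counts = counts, ambiguous = ambiguous,
       cluster_count = length(ids))
}

#' Member-exclusive unique-read counts
#'
#' Member-level quantification implemented as group counting over singleton
#' groups: a read counts for a member only when every member-overlapping
#' placement hits that one member. In a member-discriminable cluster (no
#' shared k-mers between members) this recovers each member's expression;
#' elsewhere shared reads land in the ambiguous bin.
#'
#' @inheritParams count_cluster
#' @return As [count_groups()], with one group per member (labeled by
#'   locus_id).
#' @export
count_members <- function(aln, cluster, mode = c("lenient", "strict")) {
  singleton <- data.frame(locus_id = cluster$members$locus_id,
                          group = cluster$members$locus_id,
                          stringsAsFactors = FALSE)
  count_groups(aln, set_groups(cluster, singleton), mode)
}

#' RPKM normalization with Poisson uncertainty
#'
#' RPKM = count / (effective_length / 1000) / (aligned_total / 1e6): reads
#' per 1000 nt of transcript length per million aligned reads. The counting
#' error is modeled as Poisson, so the uncertainty is sqrt(count) put through
#' the identical normalization.
#'
#' @param count Non-negative integer read count (vectorized).
#' @param aligned_total Total distinct aligned reads in the sample.
#' @param effective_length Feature length in nt used for normalization (for a
#'   cluster, the median member length).
#' @return `data.frame` with columns `rpkm` and `rpkm_sigma`.
#' @export
rpkm_normalize <- function(count, aligned_total, effective_length) {
  if (any(aligned_total <= 0)) stop("aligned_total must be > 0", call. = FALSE)
  if (any(effective_length <= 0))
    stop("effective_length must be > 0", call. = FALSE)
  denom <- (effective_length / 1000) * (aligned_total / 1e6)
  data.frame(rpkm = count / denom, rpkm_sigma = sqrt(count) / denom)
}

# assemble ExpressionRecord rows; every row carries its own normalization
# inputs for auditability
expression_record <- function(feature_id, scope, sample, count,
                              effective_length, aligned_total) {
  stopifnot(all(count >= 0), all(count <= aligned_total))
  norm <- rpkm_normalize(count, aligned_total, effective_length)
  data.frame(feature_id = feature_id, scope = scope, sample = sample,
             count = as.integer(count), rpkm = norm$rpkm,
             rpkm_sigma = norm$rpkm_sigma,
             effective_length = effective_length,
             aligned_total = aligned_total, stringsAsFactors = FALSE)
}

#' Quantify a set of clusters in one sample
#'
#' @param aln Alignment `data.frame` for one sample.
#' @param clusters List of `ncrna_cluster` objects.
#' @param n_aligned Total distinct aligned reads in the sample (defaults to
#'   the distinct reads in `aln`; pass the genome-wide total when `aln` is a
#'   subset).
#' @param sample Sample label.
#' @param mode Unique-read mode, see [count_cluster()].
#' @return Expression `data.frame` (feature_id, scope, sample, count, rpkm,
#'   rpkm_sigma, effective_length, aligned_total), one row per cluster.
#' @export
quantify_clusters <- function(aln, clusters, n_aligned = aligned_total(aln),
                              sample = NA_character_,
                              mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  out <- do.call(rbind, lapply(clusters, function(cl) {
    expression_record(cl$cluster_id, "cluster", sample,
                      count_cluster(aln, cl, mode),
                      cl$effective_length, n_aligned)
  }))
  rownames(out) <- NULL
  out
}

#' Quantify the groups of one cluster in one sample
#'
#' Group RPKM uses the cluster's effective length (one RNA species of that
#' length underlies every group). The ambiguous bin is returned as its own
#' record (feature `<cluster>:ambiguous`) so that conservation -- group
#' counts plus ambiguous equal the cluster count -- is checkable from the
#' output alone.
#'
#' @inheritParams quantify_clusters
#' @param cluster An `ncrna_cluster` with groups.
#' @return Expression `data.frame` with one row per group plus the ambiguous
#'   row, scope `"group"`.
#' @export
quantify_groups <- function(aln, cluster, n_aligned = aligned_total(aln),
                            sample = NA_character_,
                            mode = c("lenient", "strict")) {
  gc <- count_groups(aln, cluster, match.arg(mode))
  expression_record(
    feature_id = paste(cluster$cluster_id,
                       c(names(gc$counts), "ambiguous"), sep = ":"),
    scope = "group", sample = sample,
    count = c(unname(gc$counts), gc$ambiguous),
    effective_length = cluster$effective_length, aligned_total = n_aligned)
}

#' Quantify simple single-copy features (tRNA / lincRNA modes)
#'
#' Unique strand-correct overlap counts per feature. tRNA mode applies full
#' RPKM (per 1000 nt of the feature's own length per million aligned);
#' lincRNA mode reports reads per million aligned only -- lincRNA spans vary
#' over orders of magnitude and length normalization is not wanted --
#' implemented as a fixed 1000-nt normalization length so the value equals
#' reads-per-million and the rpkm/rpkm_sigma algebra still holds row-wise.
#'
#' @inheritParams quantify_clusters
#' @param features Locus `data.frame` of the features.
#' @param norm_mode `"rpkm"` (tRNA-style) or `"rpm"` (lincRNA-style).
#' @param scope Scope label stamped on the records (default `"region"`).
#' @return Expression `data.frame`, one row per feature.
#' @export
count_simple_features <- function(aln, features,
                                  norm_mode = c("rpkm", "rpm"),
                                  n_aligned = aligned_total(aln),
                                  sample = NA_character_, scope = "region") {
  norm_mode <- match.arg(norm_mode)
  counts <- integer(nrow(features))
  h <- feature_hits(aln, features)
  h <- h[h$same_strand, , drop = FALSE]
  if (nrow(h) > 0) {
    per_feat <- tapply(h$read_id, h$feat_row, function(x) length(unique(x)))
    counts[as.integer(names(per_feat))] <- as.integer(per_feat)
  }
  eff_len <- if (norm_mode == "rpkm") features$end - features$start
             else rep(1000, nrow(features))
  expression_record(features$locus_id, scope, sample, counts, eff_len,
                    n_aligned)
}

#' Tissue-enrichment tally of features above an expression threshold
#'
#' A feature is "above threshold" when its maximum RPKM over samples exceeds
#' `threshold` (strictly); its max-tissue is the sample attaining that
#' maximum. Ties are resolved to the first sample in `sample_order` and
#' flagged, never silently broken. The tally cross-tabulates RNA class
#' against max-tissue for above-threshold features (e.g. how many H/ACA box
#' snoRNAs peak in testes).
#'
#' @param records Expression `data.frame` with at least `feature_id`,
#'   `sample`, `rpkm`.
#' @param classes Named character vector mapping feature_id to rna_class.
#' @param threshold RPKM threshold (default 10, strict inequality).
#' @param sample_order Fixed sample ordering used for deterministic argmax
#'   tie-breaks; defaults to first appearance in `records`.
#' @return List with `assignments` (per above-threshold feature: class,
#'   max_sample, max_rpkm, tie flag) and `tally` (class x max-tissue count
#'   table).
#' @export
enrichment_tally <- function(records, classes, threshold = 10,
                             sample_order = unique(records$sample)) {
  records$sample <- factor(records$sample, levels = sample_order)
  per_feat <- split(records, records$feature_id)
  rows <- lapply(per_feat, function(df) {
    df <- df[order(df$sample), , drop = FALSE]
    mx <- max(df$rpkm)
    if (mx <= threshold) return(NULL)
    at_max <- which(df$rpkm == mx)
    data.frame(feature_id = df$feature_id[1],
               rna_class = unname(classes[df$feature_id[1]]),
               max_sample = as.character(df$sample[at_max[1]]),
               max_rpkm = mx, tie = length(at_max) > 1,
               stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  if (is.null(assignments))
    assignments <- data.frame(feature_id = character(0),
                              rna_class = character(0),
                              max_sample = character(0),
                              max_rpkm = numeric(0), tie = logical(0))
  rownames(assignments) <- NULL
  tally <- table(rna_class = assignments$rna_class,
                 max_sample = factor(assignments$max_sample,
                                     levels = sample_order))
  list(assignments = assignments, tally = tally)
}

#' Write expression records as TSV
#'
#' @param records Expression `data.frame`.
#' @param path Output path.
#' @export
write_expression <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
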
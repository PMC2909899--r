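# Synthetic genomes with multi-copy ncRNA families of controlled 28-mer
# sharing, a Poisson read simulator, and FASTA/FASTQ writers. Together with
# toy_align() this lets the whole pipeline run against known truth.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute n_subs distinct positions, each to a different base
mutate_seq <- function(seq, n_subs) {
  if (n_subs == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), min(n_subs, length(chars)))
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Specify a multi-copy ncRNA family for simulation
#'
#' Members are generated from a common family ancestor: each group gets its
#' own ancestor carrying `between_group_divergence` substitutions, and each
#' member carries `within_group_divergence` further substitutions. Between-
#' group divergence defaults to one substitution per half read length, enough
#' to break every shared 28-mer with high probability; the generator verifies
#' zero cross-group sharing after the fact and redraws on failure.
#'
#' @param family_id Family/cluster name.
#' @param n_members Number of genomic copies.
#' @param member_length Member length in nt (default 81, a typical C/D box
#'   snoRNA length).
#' @param group_sizes Integer vector of group sizes summing to `n_members`
#'   (default: one group of all members).
#' @param within_group_divergence Substitutions per member relative to its
#'   group ancestor (default 2; 0 gives identical members).
#' @param between_group_divergence Substitutions per group ancestor; default
#'   `ceiling(member_length / 14)`.
#' @param strand_rule `"alternate"` (default), `"plus"` or `"minus"` genomic
#'   placement of members.
#' @param rna_class RNA class label for the members (default `"CD_box"`).
#' @return A `family_spec` list.
#' @export
family_spec <- function(family_id, n_members, member_length = 81,
                        group_sizes = n_members,
                        within_group_divergence = 2,
                        between_group_divergence =
                          ceiling(member_length / 14),
                        strand_rule = c("alternate", "plus", "minus"),
                        rna_class = "CD_box") {
  if (sum(group_sizes) != n_members)
    stop("group_sizes must sum to n_members", call. = FALSE)
  structure(list(family_id = family_id, n_members = n_members,
                 member_length = member_length, group_sizes = group_sizes,
                 within_group_divergence = within_group_divergence,
                 between_group_divergence = between_group_divergence,
                 strand_rule = match.arg(strand_rule),
                 rna_class = canonical_class(rna_class)),
            class = "family_spec")
}

# draw member sequences for one family until the intended group structure is
# exactly recovered by the similarity module (zero cross-group sharing, each
# group internally connected at threshold 1)
draw_family_sequences <- function(spec, k, max_retries = 25) {
  n_groups <- length(spec$group_sizes)
  group_of <- rep(seq_len(n_groups), spec$group_sizes)
  for (attempt in seq_len(max_retries)) {
    ancestor <- rand_dna(spec$member_length)
    group_anc <- vapply(seq_len(n_groups), function(g) {
      if (n_groups == 1) ancestor
      else mutate_seq(ancestor, spec$between_group_divergence)
    }, character(1))
    seqs <- vapply(seq_len(spec$n_members), function(i) {
      mutate_seq(group_anc[group_of[i]], spec$within_group_divergence)
    }, character(1))
    names(seqs) <- sprintf("%s_m%02d", spec$family_id,
                           seq_len(spec$n_members))
    if (spec$n_members == 1) return(list(seqs = seqs, group_of = group_of))
    sim <- kmer_similarity(seqs, k = k)
    got <- partition_groups(sim, threshold = 1)
    comp <- as.integer(factor(got$group, levels = unique(got$group)))
    if (identical(comp, group_of)) {
      return(list(seqs = seqs, group_of = group_of))
    }
  }
  stop("could not realize the requested group structure for family '",
       spec$family_id, "' after ", max_retries,
       " attempts (zero cross-group ", k, "-mer sharing unsatisfiable ",
       "with these divergence settings)", call. = FALSE)
}

#' Generate a toy genome with multi-copy ncRNA families and mRNAs
#'
#' Builds one synthetic chromosome containing the requested families (with
#' verified group structure), single-copy mRNAs, and optionally overlapping
#' mRNA pairs that exercise the single-gene read filter. Deterministic given
#' the seed.
#'
#' @param families List of [family_spec()] objects.
#' @param n_mrnas Number of non-overlapping single-copy mRNAs.
#' @param overlap_pairs Number of overlapping mRNA gene pairs (each pair
#'   shares `overlap_nt` of sequence on the same strand).
#' @param mrna_length mRNA length in nt.
#' @param overlap_nt Overlap between paired mRNAs in nt.
#' @param spacer Intergenic spacer length in nt.
#' @param chrom_name Chromosome name.
#' @param k k-mer length used to verify cross-group discriminability.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `genome` ([Biostrings::DNAStringSet]), `loci` (locus
#'   `data.frame` as from [load_annotation()]), and `groups` (named list:
#'   per family, a `data.frame` of `locus_id`, `group` giving the true
#'   partition).
#' @export
make_genome <- function(families, n_mrnas = 4, overlap_pairs = 1,
                        mrna_length = 400, overlap_nt = 60, spacer = 150,
                        chrom_name = "chrS", k = 28, seed = 1) {
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  pieces <- character(0)
  cursor <- 0L
  rows <- list()
  truth_groups <- list()
  push <- function(seq) {
    pieces[[length(pieces) + 1L]] <<- seq
    start <- cursor
    cursor <<- cursor + nchar(seq)
    start
  }
  push(rand_dna(spacer))
  for (spec in families) {
    fam <- draw_family_sequences(spec, k = k)
    strands <- switch(spec$strand_rule,
                      alternate = rep_len(c("+", "-"), spec$n_members),
                      plus = rep("+", spec$n_members),
                      minus = rep("-", spec$n_members))
    for (i in seq_along(fam$seqs)) {
      genomic <- if (strands[i] == "-") revcomp(fam$seqs[[i]])
                 else fam$seqs[[i]]
      start <- push(genomic)
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = names(fam$seqs)[i], name = spec$family_id,
        chrom = chrom_name, start = start,
        end = start + nchar(genomic), strand = strands[i],
        rna_class = spec$rna_class, cluster = spec$family_id,
        stringsAsFactors = FALSE)
      push(rand_dna(spacer))
    }
    truth_groups[[spec$family_id]] <- data.frame(
      locus_id = names(fam$seqs),
      group = as.character(utils::as.roman(fam$group_of)),
      stringsAsFactors = FALSE)
  }
  add_mrna <- function(id, seq_len_nt) {
    start <- push(rand_dna(seq_len_nt))
    rows[[length(rows) + 1L]] <<- data.frame(
      locus_id = id, name = id, chrom = chrom_name, start = start,
      end = start + seq_len_nt, strand = "+", rna_class = "mRNA",
      cluster = id, stringsAsFactors = FALSE)
    push(rand_dna(spacer))
  }
  for (i in seq_len(n_mrnas)) add_mrna(sprintf("mrna%02d", i), mrna_length)
  for (p in seq_len(overlap_pairs)) {
    # two same-strand genes sharing overlap_nt of genomic sequence
    start <- push(rand_dna(2L * mrna_length - overlap_nt))
    ids <- sprintf("ovl%02d%s", p, c("a", "b"))
    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = ids[1], name = ids[1], chrom = chrom_name, start = start,
      end = start + mrna_length, strand = "+", rna_class = "mRNA",
      cluster = ids[1], stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = ids[2], name = ids[2], chrom = chrom_name,
      start = start + mrna_length - overlap_nt,
      end = start + 2L * mrna_length - overlap_nt, strand = "+",
      rna_class = "mRNA", cluster = ids[2], stringsAsFactors = FALSE)
    push(rand_dna(spacer))
  }
  genome <- Biostrings::DNAStringSet(setNames(paste(pieces, collapse = ""),
                                              chrom_name))
  loci <- do.call(rbind, rows)
  rownames(loci) <- NULL
  loci$sequence <- extract_sequences(loci, genome)
  list(genome = genome, loci = loci, groups = truth_groups)
}

#' Simulate stranded reads at known expression with Poisson count noise
#'
#' For every expression row, the expected read count is
#' `true_rpkm * effective_length/1000 * n_aligned_total/1e6` and the realized
#' count is drawn Poisson(expected). Reads start uniformly within a member
#' chosen uniformly among the feature's loci and are emitted on the feature's
#' strand, except for a configurable antisense fraction. Background reads
#' from intergenic sequence fill the sample up to exactly `n_aligned_total`
#' aligned reads, and a configurable fraction of unalignable (random) reads
#' is appended, so alignable-fraction bookkeeping can be exercised.
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param loci Locus `data.frame` (with sequences).
#' @param expression `data.frame` with columns `feature_id` and `true_rpkm`.
#'   `feature_id` is a locus_id (member scope), a cluster name (all its
#'   loci), or `"<cluster>:<group>"` (group scope; requires `groups`).
#' @param n_aligned_total Target number of distinct aligned reads.
#' @param groups Named list of group `data.frame`s as from [make_genome()],
#'   needed for group-scope features.
#' @param read_length Read length in nt (default 28).
#' @param antisense_fraction Fraction of feature reads emitted antisense.
#' @param unalignable_fraction Fraction of *all* sequenced reads that do not
#'   align (random sequence).
#' @param sample Sample label.
#' @param seed Integer seed.
#' @return List with `reads` (named `DNAStringSet` of all sequenced reads),
#'   `truth` (truth table: feature_id, scope, sample, true_rpkm,
#'   expected_count, realized_count, effective_length, aligned_total),
#'   `aln` (exact-match alignments from [toy_align()]), `n_aligned`,
#'   `n_unaligned`.
#' @export
simulate_reads <- function(genome, loci, expression, n_aligned_total,
                           groups = NULL, read_length = 28,
                           antisense_fraction = 0, unalignable_fraction = 0,
                           sample = "sim", seed = 1) {
  stopifnot(antisense_fraction >= 0, antisense_fraction <= 1,
            unalignable_fraction >= 0, unalignable_fraction < 1)
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  resolved <- lapply(seq_len(nrow(expression)), function(i) {
    resolve_feature(expression$feature_id[i], loci, groups)
  })
  truth <- do.call(rbind, lapply(seq_len(nrow(expression)), function(i) {
    r <- resolved[[i]]
    expected <- expression$true_rpkm[i] * (r$effective_length / 1000) *
      (n_aligned_total / 1e6)
    data.frame(feature_id = expression$feature_id[i], scope = r$scope,
               sample = sample, true_rpkm = expression$true_rpkm[i],
               expected_count = expected,
               realized_count = rpois(1, expected),
               effective_length = r$effective_length,
               aligned_total = n_aligned_total, stringsAsFactors = FALSE)
  }))
  seqs <- character(0)
  for (i in seq_len(nrow(truth))) {
    n <- truth$realized_count[i]
    if (n == 0) next
    members <- resolved[[i]]$members
    lens <- nchar(members$sequence)
    if (any(lens < read_length))
      stop("member shorter than read_length in feature ",
           truth$feature_id[i], call. = FALSE)
    midx <- members$locus_id[sample.int(nrow(members), n, replace = TRUE)]
    midx <- match(midx, members$locus_id)
    starts <- floor(runif(n) * (lens[midx] - read_length + 1L)) + 1L
    rd <- substring(members$sequence[midx], starts,
                    starts + read_length - 1L)
    anti <- runif(n) < antisense_fraction
    if (any(anti)) rd[anti] <- revcomp(rd[anti])
    seqs <- c(seqs, rd)
  }
  n_feature_reads <- length(seqs)
  n_bg <- n_aligned_total - n_feature_reads
  if (n_bg < 0) {
    warning("realized feature reads (", n_feature_reads,
            ") exceed n_aligned_total; no background added", call. = FALSE)
    n_bg <- 0L
  }
  if (n_bg > 0)
    seqs <- c(seqs, background_reads(genome, loci, n_bg, read_length))
  n_unalign <- round(length(seqs) * unalignable_fraction /
                       (1 - unalignable_fraction))
  if (n_unalign > 0)
    seqs <- c(seqs, vapply(seq_len(n_unalign),
                           function(i) rand_dna(read_length), character(1)))
  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- sprintf("read%07d", seq_along(reads))
  ali <- toy_align(reads, genome, sample = sample)
  list(reads = reads, truth = truth, aln = ali$aln,
       n_aligned = ali$n_aligned, n_unaligned = ali$n_unaligned)
}

resolve_feature <- function(feature_id, loci, groups) {
  if (feature_id %in% loci$locus_id) {
    members <- loci[loci$locus_id == feature_id, , drop = FALSE]
    return(list(members = members, scope = "member",
                effective_length = members$end - members$start))
  }
  if (grepl(":", feature_id, fixed = TRUE)) {
    parts <- strsplit(feature_id, ":", fixed = TRUE)[[1]]
    if (is.null(groups) || is.null(groups[[parts[1]]]))
      stop("group-scope feature '", feature_id,
           "' needs a groups entry for cluster '", parts[1], "'",
           call. = FALSE)
    g <- groups[[parts[1]]]
    ids <- g$locus_id[g$group == parts[2]]
    if (length(ids) == 0)
      stop("no members in group '", feature_id, "'", call. = FALSE)
    cluster_members <- loci[loci$cluster == parts[1], , drop = FALSE]
    return(list(members = loci[loci$locus_id %in% ids, , drop = FALSE],
                scope = "group",
                effective_length =
                  median(cluster_members$end - cluster_members$start)))
  }
  members <- loci[loci$cluster == feature_id, , drop = FALSE]
  if (nrow(members) == 0)
    stop("unknown feature_id '", feature_id, "'", call. = FALSE)
  list(members = members, scope = "cluster",
       effective_length = median(members$end - members$start))
}

# reads drawn uniformly from intergenic gaps (never overlapping a feature),
# random strand, so feature truth counts stay exact
background_reads <- function(genome, loci, n, read_length) {
  gaps <- list()
  for (chrom in names(genome)) {
    len <- Biostrings::width(genome)[match(chrom, names(genome))]
    feats <- loci[loci$chrom == chrom, , drop = FALSE]
    feats <- feats[order(feats$start), , drop = FALSE]
    bounds <- c(0L, rbind(feats$start, feats$end), len)
    starts <- bounds[seq(1, length(bounds) - 1, by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    ok <- ends - starts >= read_length
    if (any(ok))
      gaps[[chrom]] <- data.frame(chrom = chrom, start = starts[ok],
                                  end = ends[ok] - read_length,
                                  stringsAsFactors = FALSE)
  }
  gaps <- do.call(rbind, gaps)
  if (is.null(gaps) || nrow(gaps) == 0)
    stop("no intergenic gap long enough for background reads", call. = FALSE)
  weights <- gaps$end - gaps$start + 1L
  gi <- sample.int(nrow(gaps), n, replace = TRUE, prob = weights)
  pos <- gaps$start[gi] + floor(runif(n) * weights[gi])
  chrom_str <- setNames(as.character(genome), names(genome))
  seqs <- substring(chrom_str[gaps$chrom[gi]], pos + 1L, pos + read_length)
  minus <- runif(n) < 0.5
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  seqs
}

#' Write a genome as FASTA
#' @param genome Named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Write reads as FASTQ (constant placeholder qualities)
#' @param reads Named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", names(reads)),
                           as.character(reads),
                           "+",
                           strrep("I", Biostrings::width(reads))))
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulation truth table as TSV
#' @param truth Truth `data.frame` from [simulate_reads()].
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
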
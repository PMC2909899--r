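# Independent brute-force oracles; deliberately written against the raw
# definitions, sharing no code path with the package implementation.

# all-pairs shared-distinct-k-mer counts by direct set enumeration
naive_kmer_sim <- function(seqs, k) {
  sets <- lapply(seqs, function(s) {
    n <- nchar(s) - k + 1
    if (n < 1) return(character(0))
    unique(vapply(seq_len(n), function(i) substr(s, i, i + k - 1),
                  character(1)))
  })
  n <- length(sets)
  m <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m[i, j] <- if (i == j) length(sets[[i]])
               else length(intersect(sets[[i]], sets[[j]]))
  }
  m
}

# O(reads x features) double loop over the counting definitions
naive_counts <- function(aln, features) {
  overlaps <- function(a, f) {
    a$chrom == f$chrom & a$start < f$end & a$end > f$start
  }
  reads <- unique(aln$read_id)
  counts <- setNames(integer(nrow(features)), features$locus_id)
  for (fi in seq_len(nrow(features))) {
    f <- features[fi, ]
    for (r in reads) {
      a <- aln[aln$read_id == r, , drop = FALSE]
      hit <- overlaps(a, f) & a$strand == f$strand
      if (any(hit)) counts[fi] <- counts[fi] + 1L
    }
  }
  counts
}

# single-gene mRNA rule, one read at a time
naive_mrna_counts <- function(aln, transcripts) {
  counts <- setNames(integer(nrow(transcripts)), transcripts$locus_id)
  for (r in unique(aln$read_id)) {
    a <- aln[aln$read_id == r, , drop = FALSE]
    touched <- c()
    sense <- c()
    for (fi in seq_len(nrow(transcripts))) {
      f <- transcripts[fi, ]
      ov <- a$chrom == f$chrom & a$start < f$end & a$end > f$start
      if (any(ov)) {
        touched <- c(touched, fi)
        if (any(ov & a$strand == f$strand)) sense <- c(sense, fi)
      }
    }
    if (length(touched) == 1 && touched %in% sense)
      counts[touched] <- counts[touched] + 1L
  }
  counts
}

# count unique strand-matched overlapping reads per feature: the same
# O(reads x features) definition as naive_counts but with the per-read
# predicate evaluated over all alignment rows at once (for large inputs)
naive_counts_vec <- function(aln, features) {
  vapply(seq_len(nrow(features)), function(fi) {
    f <- features[fi, ]
    hit <- aln$chrom == f$chrom & aln$start < f$end & aln$end > f$start &
      aln$strand == f$strand
    length(unique(aln$read_id[hit]))
  }, integer(1))
}

# every placement of every read by scanning each genomic position
naive_align <- function(reads, genome_seq, chrom = "chr") {
  k <- nchar(reads[[1]])
  n <- nchar(genome_seq) - k + 1
  kmers <- substring(genome_seq, seq_len(n), seq_len(n) + k - 1)
  pos_of <- split(seq_len(n), kmers)
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                 collapse = ""))
  out <- list()
  for (id in names(reads)) {
    for (str in c("+", "-")) {
      query <- if (str == "+") reads[[id]] else rc(reads[[id]])
      for (p in pos_of[[query]]) {
        out[[length(out) + 1]] <- data.frame(
          read_id = id, chrom = chrom, start = p - 1L, end = p - 1L + k,
          strand = str, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  do.call(rbind, out)
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
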
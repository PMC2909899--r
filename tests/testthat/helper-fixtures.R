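# Fixture builders used across test files; everything is generated in code.

# toy genome + annotation written to a temp dir; returns paths and objects
toy_annotation_fixture <- function(seed = 42) {
  set.seed(seed)
  chrom_seq <- rand_seq(400)
  dir <- tempfile("fixture_")
  dir.create(dir)
  fasta <- file.path(dir, "genome.fa")
  writeLines(c(">chrToy extra description", chrom_seq), fasta)
  ann <- data.frame(
    locus_id = c("L1", "L2", "L3"),
    name = c("7SK", "7SK-related", "ACA1"),
    chrom = "chrToy",
    start = c(10L, 120L, 250L),
    end = c(91L, 201L, 330L),
    strand = c("+", "-", "+"),
    rna_class = c("misc", "misc", "HACA_box"),
    cluster = c("7SK", "7SK", "ACA1"),
    stringsAsFactors = FALSE)
  tsv <- file.path(dir, "annotation.tsv")
  write.table(ann, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  list(dir = dir, fasta = fasta, tsv = tsv, ann = ann, chrom_seq = chrom_seq)
}

# a cluster of short "member" loci laid out on one chromosome with known
# group structure; members get arbitrary sequences (counting tests only use
# the intervals)
toy_cluster <- function(member_starts = c(0, 200, 400),
                        groups = c("I", "I", "II"),
                        len = 80, strand = "+", chrom = "chrC") {
  n <- length(member_starts)
  members <- data.frame(
    locus_id = sprintf("m%d", seq_len(n)),
    name = "fam", chrom = chrom,
    start = as.integer(member_starts),
    end = as.integer(member_starts + len),
    strand = rep_len(strand, n), rna_class = "CD_box", cluster = "fam",
    sequence = vapply(seq_len(n), function(i) rand_seq(len), character(1)),
    stringsAsFactors = FALSE)
  cl <- new_ncrna_cluster("fam", members)
  set_groups(cl, data.frame(locus_id = members$locus_id, group = groups))
}

# one alignment row
aln_row <- function(read_id, chrom, start, end, strand = "+",
                    sample = "s1") {
  data.frame(read_id = read_id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand, sample = sample,
             stringsAsFactors = FALSE)
}

# random single-placement alignments over a set of feature intervals
random_alignments <- function(n_reads, chrom_len = 2000, read_len = 28,
                              chrom = "chrC", seed = 1) {
  set.seed(seed)
  starts <- sample.int(chrom_len - read_len, n_reads, replace = TRUE)
  data.frame(read_id = sprintf("r%05d", seq_len(n_reads)), chrom = chrom,
             start = starts, end = starts + read_len,
             strand = sample(c("+", "-"), n_reads, replace = TRUE),
             sample = "s1", stringsAsFactors = FALSE)
}
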
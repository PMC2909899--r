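# internal helpers shared across modules

# closed rna_class vocabulary; input is case-normalized against it on load
RNA_CLASSES <- c("CD_box", "HACA_box", "scaRNA", "scRNA", "misc", "mRNA",
                 "tRNA", "rRNA", "miRNA", "pseudogene", "lincRNA")

canonical_class <- function(x) {
  idx <- match(tolower(x), tolower(RNA_CLASSES))
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    stop("unknown rna_class value(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(RNA_CLASSES, collapse = ", "), ")", call. = FALSE)
  }
  RNA_CLASSES[idx]
}

check_strand <- function(strand) {
  bad <- !strand %in% c("+", "-")
  if (any(bad)) {
    stop("malformed strand value(s): ",
         paste(unique(strand[bad]), collapse = ", "),
         " (must be '+' or '-')", call. = FALSE)
  }
  invisible(strand)
}

# loci/alignments use 0-based half-open coordinates internally;
# GRanges is 1-based inclusive, so shift on the way in
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand
  )
}

# distinct k-mers of a nucleotide string (set semantics)
kmer_set <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(character(0))
  unique(substring(seq, seq_len(n), seq_len(n) + k - 1L))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
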
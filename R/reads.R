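#' Trim reads to a common length
#'
#' Sequencing runs of mixed read length (e.g. 36 nt and 50 nt) are truncated
#' from the 3' end to one common length before alignment; this also removes
#' sequenced amplification primer at the 3' end of short inserts. Reads
#' already shorter than the target are dropped and counted.
#'
#' @param reads A [Biostrings::DNAStringSet], or path to a FASTQ/FASTA file.
#' @param target_length Length to keep from the 5' end, in nt (default 28).
#' @return List with `reads` (trimmed `DNAStringSet`), `n_input` and
#'   `n_dropped`.
#' @export
trim_reads <- function(reads, target_length = 28) {
  if (is.character(reads)) {
    fmt <- if (grepl("\\.(fastq|fq)$", reads)) "fastq" else "fasta"
    reads <- Biostrings::readDNAStringSet(reads, format = fmt)
  }
  n_input <- length(reads)
  keep <- Biostrings::width(reads) >= target_length
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    warning("dropped ", n_dropped, " read(s) shorter than ", target_length,
            " nt", call. = FALSE)
  trimmed <- Biostrings::subseq(reads[keep], start = 1L, end = target_length)
  list(reads = trimmed, n_input = n_input, n_dropped = n_dropped)
}

#' Read alignments from a SAM file
#'
#' Parses a SAM file (multi-mapped placements as separate lines sharing a
#' read id) into the flat alignment table used by all counting functions.
#' Conversion goes through [Rsamtools::asBam()].
#'
#' @param path Path to a SAM file.
#' @param sample Sample/tissue label attached to every alignment row.
#' @return `data.frame` with columns `read_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `sample`; unmapped records are skipped
#'   and duplicate placements collapsed.
#' @export
read_alignments <- function(path, sample = NA_character_) {
  bam <- Rsamtools::asBam(path, destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(bam))
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "qwidth")))[[1]]
  mapped <- !is.na(res$pos)
  aln <- data.frame(read_id = res$qname[mapped],
                    chrom = as.character(res$rname[mapped]),
                    start = res$pos[mapped] - 1L,
                    end = res$pos[mapped] - 1L + res$qwidth[mapped],
                    strand = as.character(res$strand[mapped]),
                    sample = sample,
                    stringsAsFactors = FALSE)
  unique(aln)
}

#' Write alignments as a SAM file
#'
#' Minimal 11-column SAM emitter for simulator output: one line per
#' placement, FLAG 0/16 for plus/minus strand, SEQ in genome-forward
#' orientation, constant placeholder qualities.
#'
#' @param aln Alignment `data.frame` (see [read_alignments()]).
#' @param read_seqs Named character vector of read sequences (5' to 3' as
#'   sequenced), indexed by `read_id`.
#' @param seqlengths Named integer vector of chromosome lengths for the
#'   `@SQ` header lines.
#' @param path Output SAM path.
#' @export
write_sam <- function(aln, read_seqs, seqlengths, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", names(seqlengths), "\tLN:", seqlengths))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(aln) > 0) {
    seqs <- unname(read_seqs[aln$read_id])
    minus <- aln$strand == "-"
    if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
    lines <- paste(aln$read_id,
                   ifelse(minus, 16L, 0L),
                   aln$chrom,
                   aln$start + 1L,
                   255L,
                   paste0(aln$end - aln$start, "M"),
                   "*", 0L, 0L,
                   seqs,
                   strrep("I", aln$end - aln$start),
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Exact-match alignment of fixed-length reads to a toy genome
#'
#' Places each read at *every* genomic position whose sequence matches it
#' exactly, on either strand (a minus-strand placement means the read equals
#' the reverse complement of the genomic slice). No mismatches are tolerated:
#' at 28 nt this is the regime where shared identical 28-mers fully determine
#' read ambiguity, so group-level counting invariants hold exactly. Matching
#' uses [Biostrings::matchPDict()].
#'
#' @param reads Named [Biostrings::DNAStringSet]; all reads must have equal
#'   width (trim first).
#' @param genome Named [Biostrings::DNAStringSet] of chromosomes.
#' @param sample Sample label stamped on the alignment rows.
#' @return List with `aln` (alignment `data.frame` as in
#'   [read_alignments()]), `n_aligned` and `n_unaligned` (distinct reads with
#'   and without at least one placement).
#' @export
toy_align <- function(reads, genome, sample = NA_character_) {
  stopifnot(length(reads) == 0 || length(unique(Biostrings::width(reads))) == 1)
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  if (length(reads) == 0) {
    return(list(aln = empty_alignments(), n_aligned = 0L, n_unaligned = 0L))
  }
  w <- Biostrings::width(reads)[1]
  pd_fwd <- Biostrings::PDict(reads)
  pd_rev <- Biostrings::PDict(Biostrings::reverseComplement(reads))
  hits <- list()
  for (chrom in names(genome)) {
    subject <- genome[[chrom]]
    for (str in c("+", "-")) {
      pd <- if (str == "+") pd_fwd else pd_rev
      m <- Biostrings::matchPDict(pd, subject)
      starts <- Biostrings::startIndex(m)
      n_hits <- lengths(starts)
      if (sum(n_hits) == 0) next
      idx <- rep.int(seq_along(reads), n_hits)
      pos <- unlist(starts, use.names = FALSE)
      hits[[length(hits) + 1L]] <-
        data.frame(read_id = names(reads)[idx], chrom = chrom,
                   start = pos - 1L, end = pos - 1L + w, strand = str,
                   sample = sample, stringsAsFactors = FALSE)
    }
  }
  aln <- if (length(hits) > 0) unique(do.call(rbind, hits))
         else empty_alignments()
  rownames(aln) <- NULL
  n_aligned <- length(unique(aln$read_id))
  list(aln = aln, n_aligned = n_aligned,
       n_unaligned = length(reads) - n_aligned)
}

empty_alignments <- function() {
  data.frame(read_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             sample = character(0), stringsAsFactors = FALSE)
}

#' Number of distinct aligned reads per sample
#'
#' The RPKM denominator: each sequenced read counts once however many
#' placements it has.
#'
#' @param aln Alignment `data.frame`.
#' @param by_sample If `TRUE`, return a named vector per sample.
#' @return Integer count, or named integer vector.
#' @export
aligned_total <- function(aln, by_sample = FALSE) {
  if (!by_sample) return(length(unique(aln$read_id)))
  vapply(split(aln$read_id, aln$sample), function(x) length(unique(x)),
         integer(1))
}
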
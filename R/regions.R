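# Strand-specific coverage and reads-per-million over arbitrary genomic
# spans, plus a window scan for unannotated transcription.

#' Strand-specific reads-per-million over a genomic span
#'
#' Counts unique reads (at least 1 nt of overlap, once per read per strand)
#' over a region, separately for the plus and minus strand, and normalizes to
#' reads per million aligned. Optionally bins the region for coverage plots:
#' each counted read is assigned to the bin containing its 5' end (clipped to
#' the region), so per-strand bin counts sum exactly to the strand count.
#'
#' @param aln Alignment `data.frame` for one sample.
#' @param region A one-row `data.frame`/list with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param n_aligned Total distinct aligned reads in the sample (the RPM
#'   denominator).
#' @param bin_width Optional bin width in nt; the last bin is truncated so
#'   bins tile the region exactly.
#' @param sample Sample label.
#' @return Object of class `region_profile`: region, per-strand counts and
#'   RPM, `aligned_total`, and a `bins` data.frame (`start`, `end`,
#'   `plus_count`, `minus_count`) when `bin_width` is given.
#' @export
region_rpm <- function(aln, region, n_aligned, bin_width = NULL,
                       sample = NA_character_) {
  if (n_aligned <= 0) stop("n_aligned must be > 0", call. = FALSE)
  if (region$end <= region$start || region$start < 0)
    stop("invalid region (need end > start >= 0)", call. = FALSE)
  ov <- aln$chrom == region$chrom & aln$start < region$end &
    aln$end > region$start
  hit <- aln[ov, , drop = FALSE]
  per_strand <- function(str) {
    sub <- hit[hit$strand == str, , drop = FALSE]
    ids <- unique(sub$read_id)
    # one placement per counted read, first by coordinate, for binning
    sub <- sub[order(sub$start), , drop = FALSE]
    sub <- sub[!duplicated(sub$read_id), , drop = FALSE]
    list(count = length(ids), placements = sub)
  }
  plus <- per_strand("+")
  minus <- per_strand("-")
  bins <- NULL
  if (!is.null(bin_width)) {
    stopifnot(bin_width > 0)
    starts <- seq(region$start, region$end - 1L, by = bin_width)
    ends <- pmin(starts + bin_width, region$end)
    bin_counts <- function(p) {
      five_prime <- ifelse(p$placements$strand == "+",
                           p$placements$start, p$placements$end - 1L)
      five_prime <- pmin(pmax(five_prime, region$start), region$end - 1L)
      tabulate(findInterval(five_prime, starts), nbins = length(starts))
    }
    bins <- data.frame(start = starts, end = ends,
                       plus_count = bin_counts(plus),
                       minus_count = bin_counts(minus))
  }
  structure(list(region = region, sample = sample,
                 plus_count = plus$count, minus_count = minus$count,
                 plus_rpm = plus$count / (n_aligned / 1e6),
                 minus_rpm = minus$count / (n_aligned / 1e6),
                 aligned_total = n_aligned, bins = bins),
            class = "region_profile")
}

#' @export
print.region_profile <- function(x, ...) {
  cat("region ", x$region$chrom, ":", x$region$start, "-", x$region$end,
      if (!is.na(x$sample)) paste0(" [", x$sample, "]"), "\n",
      "  + strand: ", x$plus_count, " reads (",
      round(x$plus_rpm, 1), " RPM)\n",
      "  - strand: ", x$minus_count, " reads (",
      round(x$minus_rpm, 1), " RPM)\n", sep = "")
  invisible(x)
}

#' Scan the genome for expressed windows and call novel regions
#'
#' Tiles each chromosome with fixed windows, computes strand-specific
#' unique-read RPM per window and sample, keeps windows reaching `min_rpm`
#' in at least one sample, merges adjacent kept windows per strand, and flags
#' merged regions as novel when they overlap no annotated locus (any
#' strand). Per-sample RPM is recomputed on each merged region so tissues
#' can be compared directly. This is a generalization of eyeballing coverage
#' tracks for broad unannotated transcription; it is deliberately simple
#' (no segmentation model).
#'
#' @param aln Alignment `data.frame`, possibly multi-sample (uses the
#'   `sample` column).
#' @param annotation Locus `data.frame` of known features (may have 0 rows).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param n_aligned Named vector of per-sample aligned totals (names =
#'   sample labels), or a single number when `aln` has one sample.
#' @param window Window width in nt (default 1000).
#' @param min_rpm RPM threshold a window must reach in >= 1 sample.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `novel`, and one `rpm_<sample>` column per sample; merged regions are
#'   disjoint (per strand) and sorted.
#' @export
scan_novel_regions <- function(aln, annotation, chrom_lengths, n_aligned,
                               window = 1000, min_rpm = 50) {
  stopifnot(window > 0)
  samples <- sort(unique(aln$sample))
  if (length(n_aligned) == 1 && is.null(names(n_aligned)))
    n_aligned <- setNames(rep(n_aligned, length(samples)), samples)
  out <- list()
  for (chrom in names(chrom_lengths)) {
    starts <- seq(0L, chrom_lengths[[chrom]] - 1L, by = window)
    ends <- pmin(starts + window, chrom_lengths[[chrom]])
    for (str in c("+", "-")) {
      sub <- aln[aln$chrom == chrom & aln$strand == str, , drop = FALSE]
      keep <- rep(FALSE, length(starts))
      for (smp in samples) {
        ssub <- sub[sub$sample == smp, , drop = FALSE]
        if (nrow(ssub) == 0) next
        cnt <- window_counts(ssub, starts, ends)
        keep <- keep | (cnt / (n_aligned[[smp]] / 1e6) >= min_rpm)
      }
      if (!any(keep)) next
      runs <- rle(keep)
      run_end <- cumsum(runs$lengths)
      run_start <- run_end - runs$lengths + 1L
      for (r in which(runs$values)) {
        reg <- list(chrom = chrom, start = starts[run_start[r]],
                    end = ends[run_end[r]])
        rpms <- vapply(samples, function(smp) {
          ssub <- sub[sub$sample == smp, , drop = FALSE]
          n_reads <- length(unique(ssub$read_id[ssub$start < reg$end &
                                                  ssub$end > reg$start]))
          n_reads / (n_aligned[[smp]] / 1e6)
        }, numeric(1))
        novel <- !any(annotation$chrom == chrom &
                        annotation$start < reg$end &
                        annotation$end > reg$start)
        row <- data.frame(chrom = chrom, start = reg$start, end = reg$end,
                          strand = str, novel = novel,
                          stringsAsFactors = FALSE)
        row[paste0("rpm_", samples)] <- as.list(rpms)
        out[[length(out) + 1L]] <- row
      }
    }
  }
  if (length(out) == 0) {
    res <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      novel = logical(0))
    res[paste0("rpm_", samples)] <- list(numeric(0))
    return(res)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# unique reads overlapping each window (>= 1 nt)
window_counts <- function(aln, starts, ends) {
  if (nrow(aln) == 0) return(integer(length(starts)))
  win <- GenomicRanges::GRanges(seqnames = "w",
                                IRanges::IRanges(starts + 1L, ends))
  rd <- GenomicRanges::GRanges(seqnames = "w",
                               IRanges::IRanges(aln$start + 1L, aln$end))
  ov <- GenomicRanges::findOverlaps(rd, win)
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  key <- paste(aln$read_id[q], s)
  tab <- table(s[!duplicated(key)])
  cnt <- integer(length(starts))
  cnt[as.integer(names(tab))] <- as.integer(tab)
  cnt
}

#' Export per-strand bin coverage as bedGraph
#'
#' @param profile A `region_profile` computed with `bin_width`.
#' @param path Output path.
#' @param strand Which strand's counts to export (`"+"` or `"-"`).
#' @export
write_bedgraph <- function(profile, path, strand = c("+", "-")) {
  strand <- match.arg(strand)
  if (is.null(profile$bins))
    stop("profile has no bins; recompute region_rpm() with bin_width",
         call. = FALSE)
  score <- if (strand == "+") profile$bins$plus_count
           else profile$bins$minus_count
  gr <- GenomicRanges::GRanges(
    seqnames = profile$region$chrom,
    IRanges::IRanges(profile$bins$start + 1L, profile$bins$end),
    score = score)
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

#' Export scanned regions as BED6
#'
#' Score is max per-sample RPM times 10, rounded and capped at 1000 (BED
#' convention); name encodes novelty.
#'
#' @param regions `data.frame` from [scan_novel_regions()].
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  rpm_cols <- grep("^rpm_", names(regions), value = TRUE)
  max_rpm <- if (length(rpm_cols) > 0 && nrow(regions) > 0)
    do.call(pmax, regions[rpm_cols]) else numeric(nrow(regions))
  bed <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end,
                    name = ifelse(regions$novel, "novel", "annotated"),
                    score = pmin(round(max_rpm * 10), 1000),
                    strand = regions$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
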
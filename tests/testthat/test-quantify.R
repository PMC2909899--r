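test_that("trim_reads keeps the 5' 28 nt and drops short reads", {
  set.seed(9)
  seqs <- Biostrings::DNAStringSet(c(r36 = rand_seq(36), r50 = rand_seq(50),
                                     r20 = rand_seq(20)))
  expect_warning(tr <- trim_reads(seqs, 28), "dropped 1")
  expect_equal(length(tr$reads), 2)
  expect_equal(tr$n_dropped, 1)
  expect_true(all(Biostrings::width(tr$reads) == 28))
  expect_identical(as.character(tr$reads[["r36"]]),
                   substr(as.character(seqs[["r36"]]), 1, 28))
  expect_identical(as.character(tr$reads[["r50"]]),
                   substr(as.character(seqs[["r50"]]), 1, 28))
  # FASTQ path input
  fq <- tempfile(fileext = ".fastq")
  write_fastq(seqs, fq)
  tr2 <- suppressWarnings(trim_reads(fq, 28))
  expect_identical(as.character(tr2$reads), as.character(tr$reads))
})

test_that("single-gene mRNA counting with strand awareness", {
  tx <- data.frame(locus_id = c("A", "B", "C"), name = c("A", "B", "C"),
                   chrom = "chr1", start = c(100L, 350L, 1000L),
                   end = c(400L, 700L, 1300L), strand = c("+", "+", "-"),
                   stringsAsFactors = FALSE)
  aln <- rbind(
    aln_row("r1", "chr1", 150, 178),          # inside A, sense -> A
    aln_row("r2", "chr1", 360, 388),          # overlaps A and B -> neither
    aln_row("r3", "chr1", 200, 228, "-"),     # antisense in A -> none
    aln_row("r4", "chr1", 1100, 1128, "-"),   # sense in C (minus gene)
    aln_row("r5", "chr1", 500, 528),          # inside B only -> B
    aln_row("r5", "chr1", 2000, 2028))        # second placement outside genes
  got <- count_mrna(aln, tx)
  expect_equal(got$count, c(1L, 1L, 1L))
  expect_equal(got$count, unname(naive_mrna_counts(aln, tx)))
})

test_that("cluster counting counts each read once, lenient vs strict", {
  cl <- toy_cluster(member_starts = c(0, 200, 400, 600, 800, 1000, 1200),
                    groups = rep("I", 7))
  aln <- rbind(
    aln_row("r1", "chrC", 10, 38), aln_row("r1", "chrC", 1210, 1238),
    aln_row("r2", "chrC", 210, 238), aln_row("r2", "chrC", 5000, 5028),
    aln_row("r3", "chrC", 3000, 3028))
  # r1 hits members m1 and m7: one count, not two
  expect_equal(count_cluster(aln[1:2, ], cl), 1L)
  # r2 also aligns outside: counted lenient, excluded strict
  expect_equal(count_cluster(aln, cl), 2L)
  expect_equal(count_cluster(aln, cl, mode = "strict"), 1L)
  # r3 touches nothing
  expect_equal(count_cluster(aln[5, ], cl), 0L)
})

test_that("group counts conserve the cluster count with an ambiguous bin", {
  cl <- toy_cluster(member_starts = c(0, 200, 400),
                    groups = c("I", "I", "II"))
  aln <- rbind(
    aln_row("r1", "chrC", 10, 38), aln_row("r1", "chrC", 210, 238),  # I,I
    aln_row("r2", "chrC", 20, 48), aln_row("r2", "chrC", 410, 438),  # I,II
    aln_row("r3", "chrC", 420, 448))                                 # II
  gc <- count_groups(aln, cl)
  expect_equal(unname(gc$counts["I"]), 1L)
  expect_equal(unname(gc$counts["II"]), 1L)
  expect_equal(gc$ambiguous, 1L)
  expect_equal(sum(gc$counts) + gc$ambiguous, gc$cluster_count)
  # all reads confined to one group: group count equals cluster count
  gc1 <- count_groups(aln[1:2, ], cl)
  expect_equal(unname(gc1$counts["I"]), gc1$cluster_count)
  expect_equal(unname(gc1$counts["II"]) + gc1$ambiguous, 0L)
  no_groups <- new_ncrna_cluster("x", cl$members)
  expect_error(count_groups(aln, no_groups), "no groups")
})

test_that("conservation holds on random inputs; strand flip zeroes counts", {
  cl <- toy_cluster(member_starts = seq(0, 1600, by = 200),
                    groups = rep(c("I", "II", "III"), length.out = 9),
                    strand = c("+", "-"))
  for (seed in 1:5) {
    aln <- random_alignments(300, chrom_len = 2000, seed = seed)
    gc <- count_groups(aln, cl)
    expect_equal(sum(gc$counts) + gc$ambiguous, gc$cluster_count)
    flipped <- aln
    flipped$strand <- ifelse(aln$strand == "+", "-", "+")
    sense <- count_cluster(aln, cl) ; anti <- count_cluster(flipped, cl)
    # every sense-counted read becomes non-sense after the flip and vice versa
    both <- rbind(aln, flipped)
    expect_equal(count_cluster(both, cl), sense + anti)
  }
  # all reads antisense to an all-plus cluster: zero counts
  clp <- toy_cluster(member_starts = c(0, 200), groups = c("I", "II"))
  alnm <- aln_row(c("r1", "r2"), "chrC", c(10, 210), c(38, 238), "-")
  expect_equal(count_cluster(alnm, clp), 0L)
})

test_that("counting matches the naive double-loop oracle", {
  features <- data.frame(
    locus_id = sprintf("f%02d", 1:30), name = sprintf("f%02d", 1:30),
    chrom = "chrC", start = seq(0, by = 60, length.out = 30),
    end = seq(0, by = 60, length.out = 30) + 45L,
    strand = rep(c("+", "-"), 15), stringsAsFactors = FALSE)
  aln <- random_alignments(800, chrom_len = 1900, seed = 99)
  got <- count_simple_features(aln, features, norm_mode = "rpkm",
                               n_aligned = 1e6)
  expect_equal(got$count, unname(naive_counts(aln, features)))
})

test_that("RPKM normalization and its Poisson uncertainty", {
  # printed worked example: 104,744 reads, 26.2M aligned, 81 nt
  r <- rpkm_normalize(104744, 26.2e6, 81)
  expect_equal(signif(r$rpkm, 2), 49000)
  expect_equal(rpkm_normalize(0, 1e6, 81), data.frame(rpkm = 0, rpkm_sigma = 0))
  expect_equal(rpkm_normalize(100, 1e6, 1000),
               data.frame(rpkm = 100, rpkm_sigma = 10))
  expect_error(rpkm_normalize(1, 0, 81), "aligned_total")
  expect_error(rpkm_normalize(1, 1e6, 0), "effective_length")
  # linearity in count and inverse linearity in depth
  base <- rpkm_normalize(50, 2e6, 200)
  expect_equal(rpkm_normalize(100, 2e6, 200)$rpkm, 2 * base$rpkm)
  expect_equal(rpkm_normalize(50, 1e6, 200)$rpkm, 2 * base$rpkm)
})

test_that("simple-feature normalization modes (tRNA RPKM, lincRNA RPM)", {
  feats <- data.frame(locus_id = "t1", name = "t1", chrom = "chr1",
                      start = 0L, end = 72L, strand = "+",
                      stringsAsFactors = FALSE)
  aln <- aln_row(sprintf("r%02d", 1:36), "chr1", 10, 38)
  trna <- count_simple_features(aln, feats, norm_mode = "rpkm",
                                n_aligned = 1e6)
  expect_equal(trna$rpkm, 36 / 0.072)
  linc <- count_simple_features(aln, feats, norm_mode = "rpm",
                                n_aligned = 1e6)
  expect_equal(linc$rpkm, 36)  # per-million only, independent of length
  # 355 counts per million aligned -> 355, whatever the feature length
  aln355 <- aln_row(sprintf("x%04d", 1:355), "chr1", 10, 38)
  expect_equal(count_simple_features(aln355, feats, norm_mode = "rpm",
                                     n_aligned = 1e6)$rpkm, 355)
  none <- count_simple_features(aln[0, ], feats, norm_mode = "rpkm",
                                n_aligned = 1e6)
  expect_equal(none$count, 0L)
})

test_that("every expression record satisfies the Poisson sigma algebra", {
  cl <- toy_cluster(member_starts = c(0, 200, 400),
                    groups = c("I", "I", "II"))
  aln <- random_alignments(500, chrom_len = 700, seed = 3)
  recs <- rbind(
    quantify_clusters(aln, list(cl), n_aligned = 1e5, sample = "s1"),
    quantify_groups(aln, cl, n_aligned = 1e5, sample = "s1"))
  denom <- (recs$effective_length / 1000) * (recs$aligned_total / 1e6)
  expect_equal(recs$rpkm, recs$count / denom)
  expect_equal(recs$rpkm_sigma, sqrt(recs$count) / denom)
  expect_true(all(recs$count <= recs$aligned_total))
})

test_that("enrichment tally assigns max-tissue above threshold", {
  # a feature at 166 in testes and 13 in hypothalamus is above 10, peaks in testes
  recs <- data.frame(
    feature_id = rep(c("HBI6like", "flat"), each = 2),
    sample = rep(c("testes", "hypothalamus"), 2),
    rpkm = c(166, 13, 4, 9), stringsAsFactors = FALSE)
  classes <- c(HBI6like = "HACA_box", flat = "CD_box")
  tl <- enrichment_tally(recs, classes, threshold = 10)
  expect_equal(nrow(tl$assignments), 1)
  expect_equal(tl$assignments$max_sample, "testes")
  expect_false(tl$assignments$tie)
  expect_equal(unname(tl$tally["HACA_box", "testes"]), 1L)

  # 6 features x 3 tissues vs independent enumeration
  set.seed(8)
  grid <- expand.grid(feature_id = sprintf("f%d", 1:6),
                      sample = c("t1", "t2", "t3"), stringsAsFactors = FALSE)
  grid$rpkm <- round(runif(nrow(grid), 0, 60), 1)
  cls <- setNames(rep(c("CD_box", "HACA_box"), 3), sprintf("f%d", 1:6))
  tl2 <- enrichment_tally(grid, cls, threshold = 10,
                          sample_order = c("t1", "t2", "t3"))
  for (f in sprintf("f%d", 1:6)) {
    sub <- grid[grid$feature_id == f, ]
    if (max(sub$rpkm) > 10) {
      expect_equal(
        tl2$assignments$max_sample[tl2$assignments$feature_id == f],
        sub$sample[which.max(sub$rpkm)])
    } else {
      expect_false(f %in% tl2$assignments$feature_id)
    }
  }
  # ties are flagged and resolved to the first sample in order
  tie <- data.frame(feature_id = "z", sample = c("b", "a"), rpkm = c(50, 50))
  tlt <- enrichment_tally(tie, c(z = "misc"), sample_order = c("a", "b"))
  expect_true(tlt$assignments$tie)
  expect_equal(tlt$assignments$max_sample, "a")
})

test_that("member-scope counting uses member-exclusive reads", {
  cl <- toy_cluster(member_starts = c(0, 200, 400),
                    groups = c("I", "I", "II"))
  aln <- rbind(
    aln_row("r1", "chrC", 10, 38),                                  # m1 only
    aln_row("r2", "chrC", 10, 38), aln_row("r2", "chrC", 210, 238), # m1+m2
    aln_row("r3", "chrC", 410, 438))                                # m3 only
  mc <- count_members(aln, cl)
  expect_equal(unname(mc$counts[c("m1", "m2", "m3")]), c(1L, 0L, 1L))
  expect_equal(mc$ambiguous, 1L)
  expect_equal(sum(mc$counts) + mc$ambiguous, mc$cluster_count)
})
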
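test_that("make_genome is deterministic and realizes the group structure", {
  fams <- list(family_spec("hb85", n_members = 29, group_sizes = c(9, 15, 5)))
  g1 <- make_genome(fams, seed = 7)
  g2 <- make_genome(fams, seed = 7)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$loci, g2$loci)
  g3 <- make_genome(fams, seed = 8)
  expect_false(identical(as.character(g1$genome), as.character(g3$genome)))

  # similarity-derived partition reproduces the intended 9/15/5 groups
  members <- g1$loci[g1$loci$cluster == "hb85", ]
  sim <- kmer_similarity(setNames(members$sequence, members$locus_id), k = 28)
  grp <- partition_groups(sim, threshold = 1)
  expect_equal(unname(table(grp$group)[c("I", "II", "III")]), c(9L, 15L, 5L),
               ignore_attr = TRUE)
  expect_identical(grp$group, g1$groups$hb85$group)
  # zero cross-group sharing, block by block
  for (ga in c("I", "II", "III")) for (gb in setdiff(c("I", "II", "III"), ga)) {
    ia <- grp$locus_id[grp$group == ga]
    ib <- grp$locus_id[grp$group == gb]
    expect_true(all(sim[ia, ib] == 0))
  }
  # loaded sequences agree with re-extraction (minus-strand members included)
  expect_true(any(members$strand == "-"))
  expect_identical(members$sequence,
                   snoquant:::extract_sequences(members, g1$genome))
})

test_that("degenerate family specs behave as defined", {
  single <- make_genome(list(family_spec("solo", n_members = 1)), seed = 3)
  expect_equal(nrow(single$groups$solo), 1)
  # two identical members: no exclusive k-mers for either
  twins <- make_genome(list(family_spec("twin", n_members = 2,
                                        within_group_divergence = 0,
                                        group_sizes = 2)), seed = 5)
  tw <- twins$loci[twins$loci$cluster == "twin", ]
  rep <- discriminability_report(setNames(tw$sequence, tw$locus_id), k = 28)
  expect_equal(rep$n_unique_kmers, c(0L, 0L))
  expect_error(family_spec("bad", n_members = 5, group_sizes = c(2, 2)),
               "sum")
  # unsatisfiable spec: zero divergence cannot separate two groups
  expect_error(
    make_genome(list(family_spec("ns", n_members = 4, group_sizes = c(2, 2),
                                 between_group_divergence = 0)), seed = 1),
    "unsatisfiable|could not realize")
})

test_that("toy aligner reports every exact placement on both strands", {
  set.seed(13)
  genome_seq <- rand_seq(3000)
  genome <- Biostrings::DNAStringSet(c(chr = genome_seq))
  reads <- Biostrings::DNAStringSet(c(
    hit = substr(genome_seq, 101, 128),
    rc = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(genome_seq, 501, 528)))),
    miss = strrep("AC", 14)))
  res <- toy_align(reads, genome)
  hit <- res$aln[res$aln$read_id == "hit", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 100)
  expect_equal(hit$strand, "+")
  rcrow <- res$aln[res$aln$read_id == "rc", ]
  expect_equal(rcrow$strand, "-")
  expect_equal(rcrow$start, 500)
  expect_false("miss" %in% res$aln$read_id)
  expect_equal(res$n_unaligned, 1)
  expect_equal(res$n_aligned, 2)
})

test_that("toy aligner agrees with a full genomic scan", {
  set.seed(19)
  # repetitive genome so multi-placements actually occur
  unit <- rand_seq(200)
  genome_seq <- paste0(rand_seq(300), unit, rand_seq(250), unit, rand_seq(300))
  genome <- Biostrings::DNAStringSet(c(chr = genome_seq))
  picks <- sample(nchar(genome_seq) - 27, 60)
  reads <- setNames(substring(genome_seq, picks, picks + 27),
                    sprintf("p%02d", seq_along(picks)))
  reads[1:10] <- vapply(reads[1:10], function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1))
  got <- toy_align(Biostrings::DNAStringSet(reads), genome)$aln
  want <- naive_align(as.list(reads), genome_seq, chrom = "chr")
  key <- function(df) sort(paste(df$read_id, df$start, df$strand))
  expect_identical(key(got), key(want))
  # reads from the repeated unit get both placements
  dup_reads <- got$read_id[got$start >= 300 & got$end <= 500]
  expect_true(all(table(got$read_id[got$read_id %in% dup_reads]) == 2))
})

test_that("simulated reads honor expression truth and determinism", {
  fams <- list(family_spec("fam", n_members = 2,
                           within_group_divergence = 0, group_sizes = 2))
  gen <- make_genome(fams, n_mrnas = 2, overlap_pairs = 0, seed = 21)
  expression <- data.frame(feature_id = c("fam", "mrna01", "mrna02"),
                           true_rpkm = c(5000, 400, 0))
  sim <- simulate_reads(gen$genome, gen$loci, expression,
                        n_aligned_total = 5000, seed = 11)
  # zero-expression feature contributes zero reads
  expect_equal(sim$truth$realized_count[sim$truth$feature_id == "mrna02"], 0)
  # reads from identical paralogs always carry two placements
  cl <- new_ncrna_cluster("fam", gen$loci[gen$loci$cluster == "fam", ])
  m <- cl$members
  touches <- (sim$aln$start < m$end[1] & sim$aln$end > m$start[1]) |
    (sim$aln$start < m$end[2] & sim$aln$end > m$start[2])
  fam_reads <- unique(sim$aln$read_id[touches])
  expect_gt(length(fam_reads), 0)
  placements <- table(sim$aln$read_id[sim$aln$read_id %in% fam_reads])
  expect_true(all(placements == 2))
  # realized counts are recovered exactly by cluster counting
  expect_equal(count_cluster(sim$aln, cl),
               sim$truth$realized_count[sim$truth$feature_id == "fam"])
  # byte-identical reruns
  sim2 <- simulate_reads(gen$genome, gen$loci, expression,
                         n_aligned_total = 5000, seed = 11)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(sim$reads, f1); write_fastq(sim2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(sim$truth, sim2$truth)
  # total aligned reads fill to the requested denominator
  expect_equal(sim$n_aligned, 5000)
})

test_that("unalignable fraction and antisense fraction are respected", {
  fams <- list(family_spec("fam", n_members = 3, group_sizes = 3))
  gen <- make_genome(fams, n_mrnas = 1, overlap_pairs = 0, seed = 31)
  expression <- data.frame(feature_id = "fam", true_rpkm = 20000)
  sim <- simulate_reads(gen$genome, gen$loci, expression,
                        n_aligned_total = 2000,
                        unalignable_fraction = 0.2, seed = 13)
  frac <- sim$n_unaligned / (sim$n_aligned + sim$n_unaligned)
  expect_equal(frac, 0.2, tolerance = 0.01)
  # antisense reads align opposite to the member strand and escape
  # sense counting
  sim_as <- simulate_reads(gen$genome, gen$loci, expression,
                           n_aligned_total = 2000,
                           antisense_fraction = 1, seed = 13)
  cl <- new_ncrna_cluster("fam", gen$loci[gen$loci$cluster == "fam", ])
  expect_equal(count_cluster(sim_as$aln, cl), 0L)
})

test_that("pipeline closure: realized totals near expectation, invariants hold", {
  fams <- list(family_spec("famA", n_members = 9, group_sizes = c(4, 5)))
  gen <- make_genome(fams, n_mrnas = 2, overlap_pairs = 0, seed = 41)
  expression <- data.frame(
    feature_id = c("famA:I", "famA:II", "mrna01", "mrna02"),
    true_rpkm = c(8000, 2000, 500, 1500))
  sim <- simulate_reads(gen$genome, gen$loci, expression,
                        n_aligned_total = 20000, groups = gen$groups,
                        seed = 43)
  expect_true(abs(sum(sim$truth$realized_count) -
                    sum(sim$truth$expected_count)) <=
                4 * sqrt(sum(sim$truth$expected_count)))
  cl <- set_groups(new_ncrna_cluster("famA",
                                     gen$loci[gen$loci$cluster == "famA", ]),
                   gen$groups$famA)
  gc <- count_groups(sim$aln, cl)
  expect_equal(sum(gc$counts) + gc$ambiguous, gc$cluster_count)
  # groups were built discriminable, so nothing is ambiguous
  expect_equal(gc$ambiguous, 0L)
  expect_equal(unname(gc$counts[c("I", "II")]),
               sim$truth$realized_count[1:2])
})
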
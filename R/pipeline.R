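# End-to-end orchestration: simulate -> align -> similarity -> quantify ->
# regions, with a manifest written before computation and invariant checks
# that abort the run on violation.

#' Build a validated run configuration
#'
#' All pipeline parameters in one list with defaults; unknown names are
#' rejected so typos cannot silently fall back to defaults. The manifest
#' written by [run_pipeline()] echoes every value.
#'
#' @param ... Named overrides of the defaults: `out_dir`, `seed`, `sample`,
#'   `k` (k-mer/read length, 28), `read_length` (28), `group_threshold`
#'   (min shared k-mers, 1), `rpkm_threshold` (enrichment cutoff, 10),
#'   `window` (region scan window nt, 1000), `min_rpm` (50), `unique_mode`
#'   (`"lenient"`/`"strict"`), `excluded_classes`, `n_aligned_total`,
#'   `antisense_fraction`, `unalignable_fraction`, `families`, `expression`.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    out_dir = tempfile("snoquant_run_"),
    seed = 1L,
    sample = "sim",
    k = 28L,
    read_length = 28L,
    group_threshold = 1,
    rpkm_threshold = 10,
    window = 1000L,
    min_rpm = 50,
    unique_mode = "lenient",
    excluded_classes = c("pseudogene", "miRNA", "tRNA", "rRNA"),
    n_aligned_total = 20000L,
    antisense_fraction = 0,
    unalignable_fraction = 0.1,
    families = NULL,
    expression = NULL
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, overrides)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are [run_config()] parameters.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the demonstration pipeline end to end
#'
#' Simulates a genome and reads from the configured family and expression
#' specs (defaults emulate a three-group 29-member snoRNA family with group
#' sizes 9/15/5 plus a member-discriminable family and mRNAs, including an
#' overlapping pair), aligns exactly, derives groups from k-mer similarity,
#' quantifies clusters/groups/mRNAs, scans for novel regions, and writes all
#' artifacts as TSV/BED/bedGraph under `out_dir`. A manifest with every
#' parameter is written *before* computation; the run aborts with a nonzero
#' condition if the group-count conservation invariant is violated.
#'
#' @param config A `run_config` (or list of overrides passed to
#'   [run_config()]).
#' @return Invisibly, a list with the output directory, the in-memory
#'   results (`genome`, `loci`, `clusters`, `expression`, `group_counts`,
#'   `regions`) and the manifest path.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(config$out_dir, "manifest.yaml")
  manifest <- config[setdiff(names(config), c("families", "expression"))]
  manifest$package_version <- as.character(utils::packageVersion("snoquant"))
  yaml::write_yaml(manifest, manifest_path)
  log_file <- file.path(config$out_dir, "run.log")
  logmsg <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(msg)
    cat(msg, "\n", file = log_file, append = TRUE)
  }

  families <- config$families
  if (is.null(families)) {
    families <- list(
      family_spec("famA", n_members = 29, group_sizes = c(9, 15, 5)),
      family_spec("famB", n_members = 6, within_group_divergence = 30,
                  group_sizes = rep(1, 6), rna_class = "CD_box"))
  }
  logmsg("stage simulate: building genome (seed ", config$seed, ")")
  gen <- make_genome(families, k = config$k, seed = config$seed)
  write_genome_fasta(gen$genome, file.path(config$out_dir, "genome.fa"))
  write_annotation(gen$loci, file.path(config$out_dir, "annotation.tsv"))

  expression <- config$expression
  if (is.null(expression)) {
    expression <- data.frame(
      feature_id = c("famA:I", "famA:II", "famA:III", "famB",
                     grep("^mrna", unique(gen$loci$cluster), value = TRUE)),
      true_rpkm = c(14439, 635, 242, 800,
                    seq(50, length.out =
                          length(grep("^mrna", unique(gen$loci$cluster))),
                        by = 150)),
      stringsAsFactors = FALSE)
  }
  sim <- simulate_reads(gen$genome, gen$loci, expression,
                        n_aligned_total = config$n_aligned_total,
                        groups = gen$groups,
                        read_length = config$read_length,
                        antisense_fraction = config$antisense_fraction,
                        unalignable_fraction = config$unalignable_fraction,
                        sample = config$sample, seed = config$seed)
  write_fastq(sim$reads, file.path(config$out_dir, "reads.fastq"))
  write_truth(sim$truth, file.path(config$out_dir, "truth.tsv"))
  seqlens <- setNames(Biostrings::width(gen$genome), names(gen$genome))
  read_seqs <- setNames(as.character(sim$reads), names(sim$reads))
  write_sam(sim$aln, read_seqs, seqlens,
            file.path(config$out_dir, "alignments.sam"))
  logmsg("stage align: ", sim$n_aligned, " aligned / ", sim$n_unaligned,
         " unaligned reads (",
         round(100 * sim$n_aligned / (sim$n_aligned + sim$n_unaligned)),
         "% alignable)")

  ncrna <- filter_classes(gen$loci, config$excluded_classes)
  ncrna <- ncrna[ncrna$rna_class != "mRNA", , drop = FALSE]
  clusters <- build_clusters(ncrna)
  export_clusters_bed(clusters, file.path(config$out_dir, "clusters.bed"))

  logmsg("stage similarity: k = ", config$k)
  for (cid in names(clusters)) {
    cl <- clusters[[cid]]
    if (nrow(cl$members) < 2) next
    sim_m <- kmer_similarity(cl, k = config$k)
    write_similarity(sim_m, file.path(config$out_dir,
                                      paste0("similarity_", cid, ".tsv")))
    grp <- partition_groups(sim_m, threshold = config$group_threshold)
    write.table(grp, file.path(config$out_dir, paste0("groups_", cid, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    clusters[[cid]] <- set_groups(cl, grp)
  }

  logmsg("stage quantify")
  n_aligned <- sim$n_aligned
  expr_rows <- quantify_clusters(sim$aln, clusters, n_aligned = n_aligned,
                                 sample = config$sample,
                                 mode = config$unique_mode)
  group_counts <- list()
  for (cid in names(clusters)) {
    cl <- clusters[[cid]]
    if (is.null(cl$groups)) next
    gc <- count_groups(sim$aln, cl, mode = config$unique_mode)
    if (sum(gc$counts) + gc$ambiguous != gc$cluster_count)
      stop("invariant violation in stage quantify: group counts + ambiguous",
           " != cluster count for cluster ", cid, call. = FALSE)
    group_counts[[cid]] <- gc
    expr_rows <- rbind(expr_rows,
                       quantify_groups(sim$aln, cl, n_aligned = n_aligned,
                                       sample = config$sample,
                                       mode = config$unique_mode))
  }
  mrnas <- gen$loci[gen$loci$rna_class == "mRNA", , drop = FALSE]
  mcounts <- count_mrna(sim$aln, mrnas)
  expr_rows <- rbind(expr_rows,
                     expression_record(mcounts$locus_id, "mRNA",
                                       config$sample, mcounts$count,
                                       mrnas$end - mrnas$start, n_aligned))
  write_expression(expr_rows, file.path(config$out_dir, "expression.tsv"))
  write_schema(file.path(config$out_dir, "expression.schema.tsv"))

  logmsg("stage regions: window ", config$window, " nt, min_rpm ",
         config$min_rpm)
  regions <- scan_novel_regions(sim$aln, gen$loci, seqlens,
                                n_aligned = setNames(n_aligned, config$sample),
                                window = config$window,
                                min_rpm = config$min_rpm)
  write.table(regions, file.path(config$out_dir, "regions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_regions_bed(regions, file.path(config$out_dir, "regions.bed"))
  whole <- list(chrom = names(seqlens)[1], start = 0L,
                end = unname(seqlens[1]))
  prof <- region_rpm(sim$aln, whole, n_aligned = n_aligned,
                     bin_width = config$window, sample = config$sample)
  write_bedgraph(prof, file.path(config$out_dir, "coverage_plus.bedGraph"),
                 strand = "+")
  write_bedgraph(prof, file.path(config$out_dir, "coverage_minus.bedGraph"),
                 strand = "-")
  logmsg("done: ", config$out_dir)
  invisible(list(out_dir = config$out_dir, genome = gen$genome,
                 loci = gen$loci, clusters = clusters,
                 truth = sim$truth, expression = expr_rows,
                 group_counts = group_counts, regions = regions,
                 manifest = manifest_path))
}

# sidecar schema: column name, unit, meaning for every numeric output column
write_schema <- function(path) {
  schema <- data.frame(
    column = c("count", "rpkm", "rpkm_sigma", "effective_length",
               "aligned_total"),
    unit = c("reads", "reads/kb/Mread", "reads/kb/Mread", "nt", "reads"),
    meaning = c(
      "unique reads assigned to the feature",
      "count / (effective_length/1000) / (aligned_total/1e6)",
      "sqrt(count) under the same normalization (Poisson uncertainty)",
      "length used for RPKM (median member length for clusters; 1000 in rpm mode)",
      "distinct aligned reads in the sample (denominator)"))
  write.table(schema, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
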
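# Fixture builders and independent oracles shared across the suite.
# Oracles deliberately use naive enumeration, not the package's code paths.

interval_mat <- function(start, end) {
  cbind(start = as.integer(start), end = as.integer(end))
}

make_model <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                       exons, cds = NULL, utr5 = NULL, utr3 = NULL) {
  empty <- interval_mat(integer(0), integer(0))
  structure(list(gene_id = gene_id, transcript_id = paste0(gene_id, ".1"),
                 chrom = chrom, strand = strand,
                 exon_intervals = exons,
                 cds_intervals = if (is.null(cds)) empty else cds,
                 utr5_intervals = if (is.null(utr5)) empty else utr5,
                 utr3_intervals = if (is.null(utr3)) empty else utr3),
            class = "transcript_model")
}

make_track <- function(rpos, count, region_length, gene_id = "g1",
                       region = "exon", gpos = rpos, strand = "+",
                       chrom = "chr1") {
  list(sample_id = "s", gene_id = gene_id, region = region, chrom = chrom,
       strand = strand, region_length = as.integer(region_length),
       gpos = as.integer(gpos), rpos = as.integer(rpos),
       count = as.integer(count))
}

# Naive O(N^2) window-height oracle.
oracle_heights <- function(rpos, count, flank) {
  vapply(rpos, function(x) {
    sum(count[abs(rpos - x) <= flank])
  }, 0)
}

oracle_tailprob <- function(heights) {
  vapply(seq_len(max(heights)), function(h) mean(heights >= h), 0)
}

# Independent background simulator: explicit per-position loop, no shared
# code with simulate_background().
oracle_background_mu <- function(region_length, n_events, H, n_draws,
                                 flank) {
  stats <- matrix(0, n_draws, H)
  for (d in seq_len(n_draws)) {
    ev <- sample.int(region_length, n_events, replace = TRUE) - 1L
    pos <- unique(ev)
    h <- vapply(pos, function(x) sum(abs(ev - x) <= flank), 0L)
    for (k in seq_len(H)) stats[d, k] <- mean(h >= k)
  }
  colMeans(stats)
}

# Overlapping 5-mer frame frequencies, N-containing frames skipped.
oracle_pentamer_freq <- function(seqs) {
  frames <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < 5) return(character(0))
    vapply(seq_len(n - 4L), function(i) substr(s, i, i + 4L), "")
  }))
  frames <- frames[!grepl("N", frames, fixed = TRUE)]
  table(frames) / length(frames)
}

# Exhaustive Mann-Whitney U: pair count with half ties.
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

random_genome <- function(len = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
  names(g) <- "chr1"
  g
}

# Complete synthetic iCLIP run at desk scale; returns recovery measures.
run_recovery_pipeline <- function(seed, n_genes = 8, background_events = 60,
                                  n_draws = 25, n_reruns = 50) {
  set.seed(seed)
  ga <- make_genome_and_annotation(n_genes = n_genes)
  gff_path <- tempfile(fileext = ".gff3")
  write_gff3(ga$gff, gff_path)
  models <- load_transcript_models(gff_path, ga$genome)
  partitions <- lapply(models, partition_regions)
  planted <- plant_xl_sites(partitions)
  contaminated <- utils::tail(names(partitions), 2L)
  exp <- simulate_iclip_experiment(partitions, planted,
                                   contaminated_genes = contaminated,
                                   n_replicates = 5,
                                   background_events = background_events)
  rep_tracks <- lapply(exp$treatment, tracks_from_alignments,
                       partitions = partitions)
  cons <- call_consensus_sites(rep_tracks, n_draws = n_draws,
                               n_reruns = n_reruns)
  ctrl_tracks <- lapply(exp$controls, function(g) {
    lapply(g, tracks_from_alignments, partitions = partitions)
  })
  res <- subtract_controls(cons, ctrl_tracks, n_draws = n_draws,
                           n_reruns = n_reruns)
  truth <- planted[!planted$gene_id %in% contaminated, , drop = FALSE]
  hit <- merge(truth, res$sites, by = c("gene_id", "region", "gpos"))
  list(n_planted = nrow(truth), n_recovered = nrow(hit),
       removed_genes = res$removed_genes,
       contaminated = contaminated,
       surviving_contaminated = intersect(res$targets$members, contaminated),
       targets = res$targets)
}
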
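test_that("genome and annotation generation is fully seed-deterministic", {
  a <- make_genome_and_annotation(n_genes = 4, seed = 61)
  b <- make_genome_and_annotation(n_genes = 4, seed = 61)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$gff, b$gff)
  d <- tempfile()
  dir.create(d)
  write_genome_fasta(a$genome, file.path(d, "a.fa"))
  write_genome_fasta(b$genome, file.path(d, "b.fa"))
  expect_identical(readLines(file.path(d, "a.fa")),
                   readLines(file.path(d, "b.fa")))
})

test_that("generated annotation round-trips with the planned region structure", {
  ga <- make_genome_and_annotation(
    n_genes = 20, plan = list(utr5_len = 100, cds_exon_len = 200,
                              n_cds_exons = 3, intron_len = 150,
                              utr3_len = 120), seed = 62)
  path <- tempfile(fileext = ".gff3")
  write_gff3(ga$gff, path)
  models <- load_transcript_models(path, ga$genome)
  expect_length(models, 20L)
  parts <- lapply(models, partition_regions)
  n_introns <- sum(vapply(parts, function(p) nrow(p$regions$intron), 0L))
  expect_identical(n_introns, 40L)  # 2 introns per 3-exon gene
  for (p in parts[1:3]) {
    expect_identical(unname(p$region_length),
                     c(100L, 600L, 300L, 120L))
  }
  expect_setequal(unique(vapply(parts, `[[`, "", "strand")), c("+", "-"))
})

test_that("the random genome honours the requested GC content", {
  ga <- make_genome_and_annotation(
    n_genes = 40, plan = list(utr5_len = 200, cds_exon_len = 1000,
                              n_cds_exons = 2, intron_len = 200,
                              utr3_len = 200), gc = 0.5, seed = 63)
  freq <- Biostrings::letterFrequency(ga$genome[[1]], c("GC"),
                                      as.prob = TRUE)
  expect_lt(abs(freq - 0.5), 0.01)  # binomial bound at ~1e5 bases
})

test_that("simulated reads place truncation sites one base downstream of events", {
  ga <- make_genome_and_annotation(n_genes = 2, seed = 64)
  path <- tempfile(fileext = ".gff3")
  write_gff3(ga$gff, path)
  parts <- lapply(load_transcript_models(path, ga$genome), partition_regions)
  planted <- data.frame(gene_id = names(parts), region = "exon", rpos = 100L)
  planted$gpos <- vapply(seq_len(nrow(planted)), function(i) {
    region_to_genomic(parts[[planted$gene_id[i]]], "exon", 100L)
  }, 0L)
  set.seed(64)
  reps <- simulate_iclip_reads(parts, planted, n_replicates = 1,
                               background_events = 0, signal_events = 30)
  aln <- reps[[1]]
  xs <- extract_truncation_sites(aln)
  tl <- tally_crosslinks(xs$sites, parts)
  for (i in seq_len(nrow(planted))) {
    tr <- tl$tracks[[paste0(planted$gene_id[i], "|exon")]]
    expect_identical(tr$gpos, planted$gpos[i])
    expect_identical(tr$rpos, 100L)
  }
  # strand-specific read geometry: plus reads start at site+1, minus end at it
  plus <- aln[aln$strand == "+", ]
  minus <- aln[aln$strand == "-", ]
  expect_true(all(plus$start - 1L == planted$gpos[1]))
  expect_true(all(minus$end == planted$gpos[2]))
  expect_true(all(aln$end - aln$start == 30L))
})

test_that("null generator with zero signal gives statistically uniform tracks", {
  ga <- make_genome_and_annotation(n_genes = 2, seed = 65)
  path <- tempfile(fileext = ".gff3")
  write_gff3(ga$gff, path)
  parts <- lapply(load_transcript_models(path, ga$genome), partition_regions)
  set.seed(65)
  reps <- simulate_iclip_reads(
    parts, planted = data.frame(gene_id = character(0), region = character(0),
                                rpos = integer(0)),
    n_replicates = 1, background_events = 300)
  tr <- tracks_from_alignments(reps[[1]], parts)[["gene001|exon"]]
  # Poisson(0.5) per position: mean count near 0.5, no dominant position
  expect_lt(max(tr$count), 6L)
  expect_equal(sum(tr$count), 300, tolerance = 0.2)
})

test_that("dedup of simulated duplicates recovers unique molecule counts", {
  layout <- barcode_layout(0:3, 4:8, c(ACGT = "s1", TGCA = "s2"))
  set.seed(66)
  sim <- simulate_iclip_fastq(layout, n_molecules = 200, dup_rate = 0.5)
  expect_gt(nrow(sim$reads), 2 * 200)  # duplicates were injected
  out <- demultiplex_and_dedup(sim$reads, layout)
  # UMI space (4^5 = 1024) x random inserts >> 200 molecules: dedup exact
  expect_identical(nrow(out$samples$s1), 200L)
  expect_identical(nrow(out$samples$s2), 200L)
})

test_that("expression simulation plants recoverable enrichment and DEG effects", {
  skip_if_not_installed("edgeR")
  tabs <- simulate_expression_tables(n_genes = 800, n_enriched = 40,
                                     seed = 67)
  st <- suppressMessages(enrichment_stats(tabs$rip_counts,
                                          tabs$polya_counts))
  rip_tpm <- rowMeans(compute_tpm(tabs$rip_counts, tabs$gene_lengths))
  ts <- rip_enrichment_filter(st, rip_tpm)
  truth <- tabs$truth$rip_enriched_genes
  expect_gte(length(intersect(ts$members, truth)) / length(truth), 0.95)
  expect_lte(length(setdiff(ts$members, truth)), 2L)

  deg_st <- suppressMessages(enrichment_stats(tabs$rna_counts$ox,
                                              tabs$rna_counts$wt))
  tpm_geno <- cbind(
    wt = rowMeans(compute_tpm(tabs$rna_counts$wt, tabs$gene_lengths)),
    ox = rowMeans(compute_tpm(tabs$rna_counts$ox, tabs$gene_lengths)))
  degs <- deg_filter(deg_st, tpm_geno)
  deg_truth <- tabs$truth$deg$ox$gene_id
  expect_gte(length(intersect(degs$members, deg_truth)) / length(deg_truth),
             0.9)
})

test_that("a written synthetic dataset is complete and parseable", {
  d <- tempfile()
  write_synthetic_dataset(d, seed = 68, n_genes = 4, n_replicates = 2,
                          control_replicates = c(gfp = 2))
  expect_true(file.exists(file.path(d, "genome.fa")))
  genome <- load_genome(file.path(d, "genome.fa"))
  models <- load_transcript_models(file.path(d, "annotation.gff3"), genome)
  expect_length(models, 4L)
  aln <- read_alignments_tsv(file.path(d, "reads_rep1.tsv"))
  expect_gt(nrow(aln), 0L)
  expect_true(file.exists(file.path(d, "controls", "gfp", "reads_rep1.tsv")))
  expect_true(file.exists(file.path(d, "tables", "rip_counts.tsv")))
})
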
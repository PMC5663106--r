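## Deterministic synthetic-data generation with planted ground truth.
##
## The generator emulates the study design the pipeline is built for:
## five treatment iCLIP replicates against GFP-only and binding-dead
## control groups (truncation reads concentrated at planted sites over a
## uniform Poisson background), random-barcode PCR duplication, RIP versus
## poly(A) and per-genotype RNA-seq count tables with planted effects, and
## two-isoform TPM tables with planted delta-PSI shifts.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a synthetic genome and GFF3 annotation
#'
#' Builds a single random chromosome carrying `n_genes` genes on
#' alternating strands, each with a 5' UTR, `n_cds_exons` coding exons
#' separated by introns, and a 3' UTR (UTRs contiguous with their flanking
#' coding exon). The annotation round-trips through
#' [load_transcript_models()].
#'
#' @param n_genes Number of genes.
#' @param plan List of region lengths in nucleotides: `utr5_len`,
#'   `cds_exon_len`, `n_cds_exons`, `intron_len`, `utr3_len`.
#' @param gc GC fraction of the random sequence.
#' @param intergenic Gap between genes (and flanking the chromosome).
#' @param seed Optional seed for full determinism.
#' @return List with `genome` (`DNAStringSet`, one chromosome `chr1`),
#'   `gff` (data.frame of GFF3 records) and `gene_table` (gene id, strand,
#'   span).
#' @export
make_genome_and_annotation <- function(n_genes = 10,
                                       plan = list(utr5_len = 150,
                                                   cds_exon_len = 300,
                                                   n_cds_exons = 2,
                                                   intron_len = 200,
                                                   utr3_len = 200),
                                       gc = 0.5, intergenic = 300,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_genes >= 1, all(unlist(plan) > 0))
  gene_len <- plan$utr5_len + plan$utr3_len +
    plan$n_cds_exons * plan$cds_exon_len +
    (plan$n_cds_exons - 1) * plan$intron_len
  chrom_len <- n_genes * (gene_len + intergenic) + intergenic
  genome <- Biostrings::DNAStringSet(random_dna(chrom_len, gc))
  names(genome) <- "chr1"

  rows <- list()
  gene_table <- list()
  add <- function(type, start0, end0, id, parent = NULL) {
    attr <- paste0("ID=", id)
    if (!is.null(parent)) attr <- paste0(attr, ";Parent=", parent)
    rows[[length(rows) + 1L]] <<- data.frame(
      seqid = "chr1", source = "clipxl", type = type,
      start = start0 + 1L, end = end0, score = ".", strand = attr_strand,
      phase = ".", attributes = attr)
  }
  for (i in seq_len(n_genes)) {
    g <- sprintf("gene%03d", i)
    tx <- paste0(g, ".1")
    strand <- if (i %% 2L == 1L) "+" else "-"
    attr_strand <- strand
    s <- intergenic + (i - 1L) * (gene_len + intergenic)
    ## genomic blocks left -> right: terminal UTR, CDS exons with introns,
    ## terminal UTR; which terminal is the 5' UTR depends on strand
    left_utr_len <- if (strand == "+") plan$utr5_len else plan$utr3_len
    right_utr_len <- if (strand == "+") plan$utr3_len else plan$utr5_len
    cds <- list()
    pos <- s + left_utr_len
    for (e in seq_len(plan$n_cds_exons)) {
      cds[[e]] <- c(pos, pos + plan$cds_exon_len)
      pos <- pos + plan$cds_exon_len +
        if (e < plan$n_cds_exons) plan$intron_len else 0L
    }
    gene_end <- pos + right_utr_len
    add("gene", s, gene_end, g)
    add("mRNA", s, gene_end, tx, g)
    ## exon rows: first/last CDS exons merged with their adjacent UTR
    first_ex <- c(s, cds[[1L]][2L])
    last_ex <- c(cds[[length(cds)]][1L], gene_end)
    if (length(cds) == 1L) {
      add("exon", s, gene_end, paste0(tx, ".exon1"), tx)
    } else {
      add("exon", first_ex[1L], first_ex[2L], paste0(tx, ".exon1"), tx)
      if (length(cds) > 2L) {
        for (e in 2:(length(cds) - 1L)) {
          add("exon", cds[[e]][1L], cds[[e]][2L],
              paste0(tx, ".exon", e), tx)
        }
      }
      add("exon", last_ex[1L], last_ex[2L],
          paste0(tx, ".exon", length(cds)), tx)
    }
    for (e in seq_along(cds)) {
      add("CDS", cds[[e]][1L], cds[[e]][2L], paste0(tx, ".cds", e), tx)
    }
    left_type <- if (strand == "+") "five_prime_UTR" else "three_prime_UTR"
    right_type <- if (strand == "+") "three_prime_UTR" else "five_prime_UTR"
    add(left_type, s, s + left_utr_len, paste0(tx, ".utrL"), tx)
    add(right_type, gene_end - right_utr_len, gene_end,
        paste0(tx, ".utrR"), tx)
    gene_table[[i]] <- data.frame(gene_id = g, transcript_id = tx,
                                  strand = strand, start = s, end = gene_end)
  }
  list(genome = genome, gff = do.call(rbind, rows),
       gene_table = do.call(rbind, gene_table))
}

#' Write a synthetic annotation to GFF3
#'
#' @param gff data.frame from [make_genome_and_annotation()].
#' @param path Output path.
#' @export
write_gff3 <- function(gff, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(gff, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a genome to FASTA
#'
#' @param genome A `DNAStringSet`.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Overwrite the genome with a motif at planted sites
#'
#' Writes `motif` (RNA alphabet; U becomes T) centred on each planted site,
#' strand-aware, so motif-enrichment steps have a known signal to recover.
#'
#' @param genome A `DNAStringSet`.
#' @param partitions Named list of `region_partition` objects.
#' @param planted data.frame with `gene_id` and `gpos`.
#' @param motif RNA string of odd length.
#' @return The modified genome.
#' @export
plant_motif <- function(genome, partitions, planted, motif = "UCUUC") {
  stopifnot(nchar(motif) %% 2 == 1)
  half <- (nchar(motif) - 1L) / 2L
  dna <- Biostrings::DNAString(chartr("Uu", "Tt", motif))
  for (i in seq_len(nrow(planted))) {
    p <- partitions[[planted$gene_id[i]]]
    ins <- if (p$strand == "-") Biostrings::reverseComplement(dna) else dna
    at <- planted$gpos[i] - half + 1L
    Biostrings::subseq(genome[[p$chrom]], at, at + nchar(motif) - 1L) <- ins
  }
  genome
}

#' Choose planted crosslink sites
#'
#' Picks one position per gene in a cycling choice of regions, away from
#' region edges so the full height window fits.
#'
#' @param partitions Named list of `region_partition` objects.
#' @param genes Genes to plant sites in.
#' @param regions Regions cycled over the genes.
#' @param margin Distance kept from region ends (nucleotides).
#' @return data.frame with `gene_id`, `region`, `rpos`, `gpos`.
#' @export
plant_xl_sites <- function(partitions, genes = names(partitions),
                           regions = c("utr3", "exon", "utr5", "intron"),
                           margin = 20) {
  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    rg <- regions[(i - 1L) %% length(regions) + 1L]
    L <- partitions[[g]]$region_length[[rg]]
    rpos <- as.integer(sample.int(L - 2L * margin, 1L) + margin - 1L)
    data.frame(gene_id = g, region = rg, rpos = rpos,
               gpos = region_to_genomic(partitions[[g]], rg, rpos))
  })
  do.call(rbind, rows)
}

## Events (0-based region positions, one row per event) for one region of
## one gene: uniform Poisson background plus planted point signal.
region_events <- function(L, background_events, planted_rpos = integer(0),
                          signal_mean = 0) {
  counts <- stats::rpois(L, background_events / L)
  for (rp in planted_rpos) {
    counts[rp + 1L] <- counts[rp + 1L] + stats::rpois(1L, signal_mean)
  }
  rep.int(seq_len(L) - 1L, counts)
}

#' Simulate aligned iCLIP reads for one replicate set
#'
#' For every (gene, region), background truncation events are drawn
#' uniformly (Poisson per position, `background_events` expected per region)
#' and planted sites add `signal_factor` times the expected background
#' window height. Every event yields one uniquely mapped read of
#' `read_length` nucleotides starting one nucleotide downstream of the
#' crosslink on the gene strand.
#'
#' @param partitions Named list of `region_partition` objects.
#' @param planted data.frame from [plant_xl_sites()] (may be empty for a
#'   pure-background/control replicate).
#' @param n_replicates Number of replicates to simulate.
#' @param background_events Expected background events per region per
#'   replicate.
#' @param signal_factor Planted signal as a multiple of the expected
#'   background height in a `2*flank+1` window.
#' @param flank Window half-width the caller will use (sets the planted
#'   signal scale).
#' @param read_length Read length in nucleotides.
#' @param signal_events Optional fixed expected event count per planted
#'   site, overriding the `signal_factor`-derived scale.
#' @return List over replicates of alignment data.frames
#'   (see [read_alignments_tsv()]).
#' @export
simulate_iclip_reads <- function(partitions, planted, n_replicates = 5,
                                 background_events = 60, signal_factor = 10,
                                 flank = 15, read_length = 30,
                                 signal_events = NULL) {
  lapply(seq_len(n_replicates), function(rep_i) {
    rows <- list()
    for (p in partitions) {
      for (rg in REGIONS) {
        L <- p$region_length[[rg]]
        if (!L) next
        sel <- planted$gene_id == p$gene_id & planted$region == rg
        signal_mean <- if (is.null(signal_events)) {
          signal_factor * background_events * (2 * flank + 1) / L
        } else {
          signal_events
        }
        ev <- region_events(L, background_events,
                            planted_rpos = planted$rpos[sel],
                            signal_mean = signal_mean)
        if (!length(ev)) next
        gpos <- region_to_genomic(p, rg, ev)
        if (p$strand == "+") {
          start <- gpos + 1L
          end <- start + read_length
        } else {
          end <- gpos
          start <- end - read_length
        }
        ok <- start >= 0L
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = sprintf("%s_%s_r%d_%d", p$gene_id, rg, rep_i,
                            seq_along(gpos)),
          chrom = p$chrom, strand = p$strand,
          start = start, end = end,
          unique = TRUE, mismatches = 0L)[ok, , drop = FALSE]
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a full iCLIP experiment with controls
#'
#' Treatment replicates carry the planted signal; control groups (GFP-only
#' and a binding-dead variant) are background-only except for
#' `contaminated_genes`, whose planted sites also appear in the controls
#' and must be removed by control subtraction.
#'
#' @param partitions Named list of `region_partition` objects.
#' @param planted Planted sites ([plant_xl_sites()]).
#' @param contaminated_genes Genes whose sites also contaminate controls.
#' @param n_replicates Treatment replicates.
#' @param control_replicates Named integer vector: replicates per control
#'   group.
#' @param ... Passed to [simulate_iclip_reads()].
#' @return List with `treatment` (list of alignment data.frames),
#'   `controls` (named list of such lists) and `truth`.
#' @export
simulate_iclip_experiment <- function(partitions, planted,
                                      contaminated_genes = character(0),
                                      n_replicates = 5,
                                      control_replicates = c(gfp = 3, rq = 2),
                                      ...) {
  contamination <- planted[planted$gene_id %in% contaminated_genes, ,
                           drop = FALSE]
  list(treatment = simulate_iclip_reads(partitions, planted,
                                        n_replicates = n_replicates, ...),
       controls = lapply(control_replicates, function(R) {
         simulate_iclip_reads(partitions, contamination, n_replicates = R,
                              ...)
       }),
       truth = list(planted = planted,
                    contaminated_genes = contaminated_genes))
}

#' Simulate a demultiplexable FASTQ with PCR duplicates
#'
#' Unique molecules get a random insert and a random UMI; each molecule is
#' then re-emitted as a PCR duplicate with probability `dup_rate` per copy
#' (geometric copy count), producing byte-identical records. Read order is
#' shuffled.
#'
#' @param layout A [barcode_layout()].
#' @param n_molecules Unique molecules per sample.
#' @param insert_len Insert length downstream of the barcode block.
#' @param dup_rate Per-copy PCR duplication probability.
#' @return List with `reads` (data.frame for [demultiplex_and_dedup()]) and
#'   `truth` (`molecules_per_sample`).
#' @export
simulate_iclip_fastq <- function(layout, n_molecules = 100, insert_len = 30,
                                 dup_rate = 0.5) {
  umi_len <- length(layout$umi_offsets)
  recs <- list()
  for (bc in names(layout$samples)) {
    for (m in seq_len(n_molecules)) {
      block <- rep("N", layout$block_len)
      block[layout$exp_offsets + 1L] <- strsplit(bc, "")[[1L]]
      block[layout$umi_offsets + 1L] <- sample(c("A", "C", "G", "T"),
                                               umi_len, replace = TRUE)
      seq <- paste0(paste(block, collapse = ""), random_dna(insert_len))
      n_copies <- 1L + stats::rgeom(1L, 1 - dup_rate)
      recs[[length(recs) + 1L]] <- data.frame(
        id = sprintf("%s_mol%04d_c%d", layout$samples[[bc]], m,
                     seq_len(n_copies)),
        seq = seq, qual = strrep("I", nchar(seq)))
    }
  }
  reads <- do.call(rbind, recs)
  reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
  rownames(reads) <- NULL
  list(reads = reads,
       truth = list(molecules_per_sample = stats::setNames(
         rep(n_molecules, length(layout$samples)),
         unname(layout$samples))))
}

#' Simulate RIP/RNA-seq count tables and isoform TPMs with planted effects
#'
#' Gene counts are negative binomial around log-normal base means. RIP
#' libraries carry a planted log2 enrichment for `n_enriched` genes over
#' the poly(A) reference; each non-reference genotype carries planted
#' differential expression for `n_deg` genes (half up, half down). Isoform
#' TPM tables hold two isoforms per event gene with Poisson-sampled
#' inclusion at `psi_depth` and a planted delta-PSI on `n_dpsi` events in
#' the altered genotype.
#'
#' @param n_genes Genes in the count tables.
#' @param n_enriched Genes with planted RIP enrichment.
#' @param enrich_lfc Planted log2 RIP enrichment.
#' @param n_deg Planted DEGs per non-reference genotype.
#' @param deg_lfc Planted |log2FC| for DEGs.
#' @param genotypes Genotype labels; the first is the reference (wild type).
#' @param n_replicates Replicates per library type and genotype.
#' @param dispersion Negative-binomial dispersion.
#' @param n_events Event genes in the isoform table.
#' @param n_dpsi Events with a planted delta-PSI.
#' @param dpsi Planted delta-PSI effect.
#' @param psi_depth Poisson sampling depth per event gene and replicate.
#' @param seed Optional seed.
#' @return List with `rip_counts`, `polya_counts`, `rna_counts` (list per
#'   genotype), `gene_lengths`, `isoform_tpm`, `events`, `psi_groups` and
#'   `truth`.
#' @export
simulate_expression_tables <- function(n_genes = 2000, n_enriched = 100,
                                       enrich_lfc = 2, n_deg = 100,
                                       deg_lfc = 1.5,
                                       genotypes = c("wt", "ox"),
                                       n_replicates = 3, dispersion = 0.05,
                                       n_events = 100, n_dpsi = 20,
                                       dpsi = 0.3, psi_depth = 1000,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  base_mu <- stats::rlnorm(n_genes, log(200), 0.7)
  lengths <- stats::setNames(round(stats::runif(n_genes, 500, 3000)), genes)
  nb <- function(mu) stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / dispersion)
  tab <- function(mu, label) {
    m <- vapply(seq_len(n_replicates), function(r) nb(mu), numeric(n_genes))
    dimnames(m) <- list(genes, paste0(label, seq_len(n_replicates)))
    m
  }

  enriched <- sample(genes, n_enriched)
  rip_mu <- base_mu * ifelse(genes %in% enriched, 2^enrich_lfc, 1)
  rip_counts <- tab(rip_mu, "rip")
  polya_counts <- tab(base_mu, "polya")

  deg_truth <- list()
  rna_counts <- list()
  rna_counts[[genotypes[1L]]] <- tab(base_mu, paste0(genotypes[1L], "_"))
  for (g in genotypes[-1L]) {
    degs <- sample(genes, n_deg)
    sign <- rep(c(1, -1), length.out = n_deg)
    mu <- base_mu
    mu[match(degs, genes)] <- mu[match(degs, genes)] * 2^(sign * deg_lfc)
    rna_counts[[g]] <- tab(mu, paste0(g, "_"))
    deg_truth[[g]] <- data.frame(gene_id = degs, log2fc = sign * deg_lfc)
  }

  ## two-isoform event genes, sampled independently of the count tables
  ev_genes <- sprintf("ev%04d", seq_len(n_events))
  psi_wt <- stats::runif(n_events, 0.3, 0.6)
  dpsi_events <- sample(ev_genes, n_dpsi)
  psi_alt <- psi_wt + ifelse(ev_genes %in% dpsi_events, dpsi, 0)
  n_geno <- length(genotypes)
  iso_tpm <- matrix(0, nrow = 2L * n_events,
                    ncol = n_geno * n_replicates)
  rownames(iso_tpm) <- as.vector(rbind(paste0(ev_genes, ".iso1"),
                                       paste0(ev_genes, ".iso2")))
  psi_groups <- rep(genotypes, each = n_replicates)
  colnames(iso_tpm) <- paste0(psi_groups, "_s",
                              rep(seq_len(n_replicates), n_geno))
  for (j in seq_len(ncol(iso_tpm))) {
    psi <- if (psi_groups[j] == genotypes[1L]) psi_wt else psi_alt
    incl <- stats::rbinom(n_events, psi_depth, pmin(pmax(psi, 0), 1))
    iso_tpm[seq(1L, by = 2L, length.out = n_events), j] <- incl
    iso_tpm[seq(2L, by = 2L, length.out = n_events), j] <- psi_depth - incl
  }
  events <- data.frame(event_id = paste0(ev_genes, "_IR"),
                       gene_id = ev_genes,
                       inclusion = paste0(ev_genes, ".iso1"),
                       all = paste0(ev_genes, ".iso1,", ev_genes, ".iso2"))

  list(rip_counts = rip_counts, polya_counts = polya_counts,
       rna_counts = rna_counts, gene_lengths = lengths,
       isoform_tpm = iso_tpm, events = events, psi_groups = psi_groups,
       truth = list(rip_enriched_genes = enriched, enrich_lfc = enrich_lfc,
                    deg = deg_truth,
                    dpsi_events = paste0(dpsi_events, "_IR"), dpsi = dpsi,
                    psi_wt = stats::setNames(psi_wt, paste0(ev_genes, "_IR"))))
}

#' Differential statistics for simulated count tables
#'
#' Convenience wrapper producing the log2FC/p/q input table the integration
#' filters consume, using edgeR's exact negative-binomial test on two
#' count matrices (condition of interest vs reference).
#'
#' @param counts Counts for the condition of interest (genes x replicates).
#' @param ref_counts Counts for the reference condition.
#' @return data.frame with `gene_id`, `log2fc`, `pvalue`, `qvalue`.
#' @export
enrichment_stats <- function(counts, ref_counts) {
  if (!requireNamespace("edgeR", quietly = TRUE)) {
    stop("enrichment_stats requires the edgeR package")
  }
  group <- factor(c(rep("ref", ncol(ref_counts)),
                    rep("cond", ncol(counts))), levels = c("ref", "cond"))
  d <- edgeR::DGEList(cbind(ref_counts, counts), group = group)
  d <- edgeR::calcNormFactors(d)
  d <- edgeR::estimateDisp(d)
  et <- edgeR::exactTest(d, pair = c("ref", "cond"))
  data.frame(gene_id = rownames(et$table), log2fc = et$table$logFC,
             pvalue = et$table$PValue,
             qvalue = stats::p.adjust(et$table$PValue, method = "BH"))
}

#' Write a complete synthetic dataset to a directory
#'
#' Writes `genome.fa`, `annotation.gff3`, per-replicate alignment TSVs,
#' control alignments under `controls/<group>/`, expression tables under
#' `tables/`, and the planted truth as JSON.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed controlling every random choice.
#' @param n_genes Genes in the synthetic genome.
#' @param ... Passed to [simulate_iclip_experiment()].
#' @return Invisible path of `dir`.
#' @export
write_synthetic_dataset <- function(dir, seed = 1, n_genes = 10, ...) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ga <- make_genome_and_annotation(n_genes = n_genes)
  write_genome_fasta(ga$genome, file.path(dir, "genome.fa"))
  write_gff3(ga$gff, file.path(dir, "annotation.gff3"))
  models <- load_transcript_models(file.path(dir, "annotation.gff3"),
                                   ga$genome)
  partitions <- lapply(models, partition_regions)
  planted <- plant_xl_sites(partitions)
  contaminated <- utils::tail(names(partitions), 2L)
  exp <- simulate_iclip_experiment(partitions, planted,
                                   contaminated_genes = contaminated, ...)
  for (i in seq_along(exp$treatment)) {
    utils::write.table(exp$treatment[[i]],
                       file.path(dir, sprintf("reads_rep%d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (grp in names(exp$controls)) {
    gdir <- file.path(dir, "controls", grp)
    dir.create(gdir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(exp$controls[[grp]])) {
      utils::write.table(exp$controls[[grp]][[i]],
                         file.path(gdir, sprintf("reads_rep%d.tsv", i)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  tdir <- file.path(dir, "tables")
  dir.create(tdir, showWarnings = FALSE)
  tabs <- simulate_expression_tables()
  for (nm in c("rip_counts", "polya_counts")) {
    utils::write.table(tabs[[nm]], file.path(tdir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE)
  }
  truth <- list(planted = exp$truth$planted,
                contaminated_genes = exp$truth$contaminated_genes,
                rip_enriched_genes = tabs$truth$rip_enriched_genes)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA),
               file.path(dir, "truth.json"))
  } else {
    utils::write.table(exp$truth$planted, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
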
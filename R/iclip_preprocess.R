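## Raw/aligned iCLIP read handling: demultiplexing, UMI-based PCR
## deduplication, quality filtering, truncation-site extraction and
## per-region crosslink tallying.

#' Describe the barcode block at the 5' end of iCLIP reads
#'
#' The reverse-transcription primer places an experimental (sample) barcode
#' and a random barcode (UMI) at fixed 0-based offsets within the first
#' bases of every read. The layout is fully configurable because primer
#' geometries differ between library designs.
#'
#' @param exp_offsets Integer 0-based offsets of the experimental barcode
#'   bases within the read.
#' @param umi_offsets Integer 0-based offsets of the random-barcode (UMI)
#'   bases; must be disjoint from `exp_offsets`.
#' @param samples Named character vector mapping experimental barcode
#'   string to sample id.
#' @return A `barcode_layout` object.
#' @export
barcode_layout <- function(exp_offsets, umi_offsets, samples) {
  exp_offsets <- as.integer(exp_offsets)
  umi_offsets <- as.integer(umi_offsets)
  if (length(intersect(exp_offsets, umi_offsets))) {
    stop("experimental and random barcode offsets overlap")
  }
  if (length(unique(nchar(names(samples)))) > 1L) {
    stop("all experimental barcodes must have the same length")
  }
  if (any(nchar(names(samples)) != length(exp_offsets))) {
    stop("barcode length does not match the number of experimental offsets")
  }
  structure(list(exp_offsets = exp_offsets, umi_offsets = umi_offsets,
                 samples = samples,
                 block_len = max(c(exp_offsets, umi_offsets)) + 1L),
            class = "barcode_layout")
}

#' Read a FASTQ file into a data frame
#'
#' @param path FASTQ path (plain or gzip).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             row.names = NULL)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  qdna <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(reads$qual))
  names(qdna) <- reads$id
  Biostrings::writeQualityScaledXStringSet(qdna, path)
  invisible(path)
}

chars_at <- function(seq, offsets) {
  if (length(offsets) == 1L) {
    substr(seq, offsets + 1L, offsets + 1L)
  } else {
    do.call(paste0, lapply(offsets, function(o) substr(seq, o + 1L, o + 1L)))
  }
}

#' Demultiplex reads and remove PCR duplicates
#'
#' Routes reads by exact experimental-barcode match; among reads with an
#' identical full sequence and identical random barcode (UMI), only the
#' first encountered is kept — the rest are PCR duplicates. The whole
#' barcode block is trimmed from retained reads.
#'
#' Reads shorter than the barcode block go to the `rejected` bin; reads with
#' an unknown experimental barcode go to `undetermined` (both untouched).
#'
#' @param reads data.frame from [read_fastq()].
#' @param layout A [barcode_layout()].
#' @return List with `samples` (named list of trimmed read data frames),
#'   `undetermined`, `rejected`, and `duplicates_removed` (named integer,
#'   per sample).
#' @export
demultiplex_and_dedup <- function(reads, layout) {
  stopifnot(inherits(layout, "barcode_layout"))
  short <- nchar(reads$seq) <= layout$block_len
  rejected <- reads[short, , drop = FALSE]
  reads <- reads[!short, , drop = FALSE]

  exp_bc <- chars_at(reads$seq, layout$exp_offsets)
  sample_id <- layout$samples[exp_bc]
  unknown <- is.na(sample_id)
  undetermined <- reads[unknown, , drop = FALSE]
  reads <- reads[!unknown, , drop = FALSE]
  sample_id <- sample_id[!unknown]
  umi <- chars_at(reads$seq, layout$umi_offsets)

  dup <- duplicated(paste(sample_id, reads$seq, umi, sep = "\r"))
  samples <- vector("list", length(layout$samples))
  names(samples) <- unname(layout$samples)
  dup_removed <- stats::setNames(integer(length(samples)), names(samples))
  for (sm in names(samples)) {
    sel <- sample_id == sm
    keep <- sel & !dup
    dup_removed[sm] <- sum(sel & dup)
    kept <- reads[keep, , drop = FALSE]
    kept$seq <- substr(kept$seq, layout$block_len + 1L, nchar(kept$seq))
    kept$qual <- substr(kept$qual, layout$block_len + 1L, nchar(kept$qual))
    samples[[sm]] <- kept
  }
  list(samples = samples, undetermined = undetermined, rejected = rejected,
       duplicates_removed = dup_removed)
}

mean_phred <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q)) - 33, 0, USE.NAMES = FALSE)
}

#' Length/quality filter for iCLIP reads
#'
#' Removes reads shorter than `min_len` nucleotides and reads whose quality
#' fails the criterion: mean Phred below `min_q` (default), or any base
#' below `min_q` with `mode = "min"`.
#'
#' @param reads data.frame with `seq` and `qual` (Phred+33).
#' @param min_len Minimum retained read length (nucleotides).
#' @param min_q Phred quality threshold.
#' @param mode `"mean"` or `"min"` base quality interpretation.
#' @return List with `reads` (retained), `n_short`, `n_low_quality`.
#' @export
quality_filter <- function(reads, min_len = 15, min_q = 20,
                           mode = c("mean", "min")) {
  mode <- match.arg(mode)
  short <- nchar(reads$seq) < min_len
  q <- if (mode == "mean") {
    mean_phred(reads$qual)
  } else {
    vapply(reads$qual, function(x) min(utf8ToInt(x)) - 33, 0, USE.NAMES = FALSE)
  }
  lowq <- !short & q < min_q
  list(reads = reads[!short & !lowq, , drop = FALSE],
       n_short = sum(short), n_low_quality = sum(lowq))
}

#' Read a TSV alignment table
#'
#' Desk-scale alignment format with columns `read_id`, `chrom`, `strand`,
#' `start`, `end` (0-based half-open), `unique` (logical), `mismatches`.
#'
#' @param path TSV path.
#' @return Alignment data.frame.
#' @export
read_alignments_tsv <- function(path) {
  aln <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "chrom", "strand", "start", "end", "unique", "mismatches")
  if (!all(need %in% names(aln))) {
    stop("alignment TSV must have columns: ", paste(need, collapse = ", "))
  }
  aln$unique <- as.logical(aln$unique)
  stopifnot(all(aln$start < aln$end), all(aln$strand %in% c("+", "-")))
  aln
}

#' Read alignments from SAM/BAM
#'
#' Thin wrapper over Rsamtools/GenomicAlignments producing the same table
#' as [read_alignments_tsv()]. Uniqueness is taken from mapping quality
#' (`mapq >= unique_mapq`) and mismatches from the `NM` tag.
#'
#' @param path SAM or BAM path.
#' @param unique_mapq Mapping-quality cutoff treated as unique.
#' @return Alignment data.frame.
#' @export
read_alignments_sam <- function(path, unique_mapq = 255) {
  for (pkg in c("Rsamtools", "GenomicAlignments")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("package ", pkg, " is required to read SAM/BAM")
    }
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = c("qname", "mapq"),
                                         tag = "NM"))
  mc <- S4Vectors::mcols(ga)
  nm <- mc$NM
  nm[is.na(nm)] <- 0L
  data.frame(read_id = mc$qname,
             chrom = as.character(GenomicRanges::seqnames(ga)),
             strand = as.character(GenomicRanges::strand(ga)),
             start = GenomicRanges::start(ga) - 1L,
             end = GenomicRanges::end(ga),
             unique = !is.na(mc$mapq) & mc$mapq >= unique_mapq,
             mismatches = nm)
}

#' Extract crosslink (truncation) sites from alignments
#'
#' iCLIP cDNAs truncate at the crosslinked nucleotide, so the binding site
#' is the base one nucleotide upstream of the read start in transcript
#' orientation: `start - 1` for plus-strand reads and the half-open `end`
#' coordinate for minus-strand reads. Non-unique alignments and alignments
#' with more than `max_mismatches` mismatches are dropped; sites falling
#' outside the chromosome are dropped and counted.
#'
#' @param aln Alignment data.frame (see [read_alignments_tsv()]).
#' @param max_mismatches Maximum tolerated mismatches.
#' @param chrom_lengths Optional named integer vector of chromosome lengths
#'   used to drop minus-strand sites at the chromosome end.
#' @return List with `sites` (data.frame `chrom`, `strand`, `pos`) and
#'   `counters` (`n_nonunique`, `n_mismatch`, `n_boundary`).
#' @export
extract_truncation_sites <- function(aln, max_mismatches = 3,
                                     chrom_lengths = NULL) {
  nonuniq <- !aln$unique
  mm <- aln$unique & aln$mismatches > max_mismatches
  aln <- aln[!nonuniq & !mm, , drop = FALSE]
  pos <- ifelse(aln$strand == "+", aln$start - 1L, aln$end)
  bad <- pos < 0L
  if (!is.null(chrom_lengths)) {
    bad <- bad | pos >= chrom_lengths[aln$chrom]
  }
  list(sites = data.frame(chrom = aln$chrom[!bad], strand = aln$strand[!bad],
                          pos = as.integer(pos[!bad])),
       counters = c(n_nonunique = sum(nonuniq), n_mismatch = sum(mm),
                    n_boundary = sum(bad)))
}

#' Tally crosslink events into per-region tracks
#'
#' Assigns each crosslink event to the (gene, region) whose intervals
#' contain it on the matching strand; events antisense to the only
#' overlapping gene are kept in a separate bin, and events matching no
#' region are reported as unassigned. A position overlapping two same-strand
#' genes is assigned to both.
#'
#' @param sites data.frame of events (`chrom`, `strand`, `pos`), one row per
#'   event (repeated rows accumulate counts).
#' @param partitions Named list of `region_partition` objects.
#' @param sample_id Sample label stored on each track.
#' @return List with `tracks` (list of crosslink tracks: `gene_id`,
#'   `region`, `region_length`, `gpos`, `rpos`, `count`), `antisense` and
#'   `unassigned` data frames.
#' @export
tally_crosslinks <- function(sites, partitions, sample_id = "sample") {
  assigned <- rep(FALSE, nrow(sites))
  antisense <- rep(FALSE, nrow(sites))
  tracks <- list()
  for (p in partitions) {
    on_chrom <- sites$chrom == p$chrom
    for (rg in REGIONS) {
      if (!p$region_length[[rg]]) next
      rpos_all <- genomic_to_region(p, rg, sites$pos)
      inside <- on_chrom & !is.na(rpos_all)
      sense <- inside & sites$strand == p$strand
      antisense <- antisense | (inside & sites$strand != p$strand)
      if (!any(sense)) next
      assigned <- assigned | sense
      tab <- table(sites$pos[sense])
      gpos <- as.integer(names(tab))
      tracks[[paste(p$gene_id, rg, sep = "|")]] <- structure(
        list(sample_id = sample_id, gene_id = p$gene_id, region = rg,
             chrom = p$chrom, strand = p$strand,
             region_length = p$region_length[[rg]],
             gpos = gpos,
             rpos = genomic_to_region(p, rg, gpos),
             count = as.integer(tab)),
        class = "crosslink_track")
    }
  }
  list(tracks = tracks,
       antisense = sites[antisense & !assigned, , drop = FALSE],
       unassigned = sites[!assigned & !antisense, , drop = FALSE])
}

#' Crosslink tracks straight from an alignment table
#'
#' Convenience chain of [extract_truncation_sites()] and
#' [tally_crosslinks()].
#'
#' @param aln Alignment data.frame.
#' @param partitions Named list of `region_partition` objects.
#' @param sample_id Sample label.
#' @param ... Passed to [extract_truncation_sites()].
#' @return The track list of [tally_crosslinks()].
#' @export
tracks_from_alignments <- function(aln, partitions, sample_id = "sample",
                                   ...) {
  xs <- extract_truncation_sites(aln, ...)
  tally_crosslinks(xs$sites, partitions, sample_id = sample_id)$tracks
}

#' Write crosslink tracks as bedGraph
#'
#' One line per crosslinked position with its event count.
#'
#' @param tracks List of crosslink tracks from [tally_crosslinks()].
#' @param path Output path.
#' @export
write_bedgraph <- function(tracks, path) {
  rows <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(chrom = tr$chrom, start = tr$gpos, end = tr$gpos + 1L,
               count = tr$count)
  }))
  rows <- rows[order(rows$chrom, rows$start), , drop = FALSE]
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
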
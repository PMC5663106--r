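## Genome/annotation input, representative gene models, and the four-region
## transcript partition used throughout the pipeline.
##
## All internal coordinates are 0-based half-open [start, end); GFF3 input
## (1-based inclusive) is converted on read and BED output keeps the 0-based
## convention. Intervals are stored as two-column integer matrices with
## columns "start" and "end".

REGIONS <- c("utr5", "exon", "intron", "utr3")

interval_matrix <- function(start = integer(0), end = integer(0)) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  if (nrow(m)) m <- m[order(m[, "start"]), , drop = FALSE]
  m
}

interval_width <- function(m) {
  if (!nrow(m)) return(0L)
  as.integer(sum(m[, "end"] - m[, "start"]))
}

#' Read a genome FASTA
#'
#' Loads a genome as a `DNAStringSet`, keeping only the first whitespace-
#' separated token of each header as the chromosome name.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] keyed by chromosome name.
#' @export
load_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

## A GFF3 line must have 9 tab-separated fields; report the offending line
## number before handing the file to rtracklayer.
check_gff3_syntax <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad <- which(body)[which(nfield != 9L)[1L]]
    stop("malformed GFF3 record at line ", bad, " of ", path)
  }
  invisible(TRUE)
}

first_chr <- function(x) {
  vapply(x, function(v) if (length(v)) as.character(v[[1L]]) else NA_character_,
         character(1))
}

#' Load representative transcript models from GFF3
#'
#' Parses a GFF3 annotation (gene/mRNA/exon/CDS/UTR features, 1-based
#' inclusive coordinates) and returns one representative model per gene: the
#' mRNA with the largest summed exonic length, ties broken by the
#' lexicographically smallest transcript ID. Coordinates are converted to
#' 0-based half-open.
#'
#' @param gff_path Path to a GFF3 file.
#' @param genome A `DNAStringSet` as returned by [load_genome()]. Every
#'   mRNA must lie on a chromosome present in `genome`.
#' @return A named list of `transcript_model` objects (one per gene), each
#'   with fields `gene_id`, `transcript_id`, `chrom`, `strand`,
#'   `exon_intervals`, `cds_intervals`, `utr5_intervals`, `utr3_intervals`.
#' @export
load_transcript_models <- function(gff_path, genome) {
  check_gff3_syntax(gff_path)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  type <- as.character(gr$type)
  is_mrna <- type %in% c("mRNA", "transcript")
  if (!any(is_mrna)) stop("no mRNA/transcript features in ", gff_path)

  mrna <- gr[is_mrna]
  tx_id <- as.character(mrna$ID)
  tx_gene <- first_chr(mrna$Parent)
  tx_chrom <- as.character(GenomicRanges::seqnames(mrna))
  missing_chr <- !(tx_chrom %in% names(genome))
  if (any(missing_chr)) {
    stop("mRNA ", tx_id[which(missing_chr)[1L]], " references chromosome '",
         tx_chrom[which(missing_chr)[1L]], "' absent from the genome")
  }

  child <- gr[type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")]
  child_parent <- first_chr(child$Parent)
  child_type <- as.character(child$type)
  ## 1-based inclusive -> 0-based half-open
  child_start <- GenomicRanges::start(child) - 1L
  child_end <- GenomicRanges::end(child)

  intervals_for <- function(tx, want) {
    sel <- child_parent == tx & child_type == want
    interval_matrix(child_start[sel], child_end[sel])
  }

  models <- lapply(seq_along(mrna), function(i) {
    tx <- tx_id[i]
    exons <- intervals_for(tx, "exon")
    if (!nrow(exons)) stop("mRNA ", tx, " has no exon features")
    structure(
      list(gene_id = tx_gene[i],
           transcript_id = tx,
           chrom = tx_chrom[i],
           strand = as.character(GenomicRanges::strand(mrna[i])),
           exon_intervals = exons,
           cds_intervals = intervals_for(tx, "CDS"),
           utr5_intervals = intervals_for(tx, "five_prime_UTR"),
           utr3_intervals = intervals_for(tx, "three_prime_UTR")),
      class = "transcript_model")
  })

  exonic_len <- vapply(models, function(m) interval_width(m$exon_intervals), 0L)
  gene_ids <- vapply(models, `[[`, character(1), "gene_id")
  keep <- vapply(split(seq_along(models), gene_ids), function(idx) {
    idx <- idx[order(-exonic_len[idx],
                     vapply(models[idx], `[[`, character(1), "transcript_id"))]
    idx[1L]
  }, 0L)
  models <- models[keep]
  names(models) <- gene_ids[keep]
  models[order(names(models))]
}

#' Partition a transcript model into analysis regions
#'
#' Splits the representative gene model into four mutually disjoint regions:
#' `exon` (coding sequence), `utr5`, `utr3` (the annotated UTR exonic
#' intervals) and `intron` (every gap between consecutive exon intervals,
#' including introns inside UTR spans — splicing status takes precedence
#' over UTR membership).
#'
#' @param model A `transcript_model`.
#' @return A `region_partition`: list with `gene_id`, `chrom`, `strand`,
#'   `regions` (named list of interval matrices) and `region_length`
#'   (named integer vector, in nucleotides).
#' @export
partition_regions <- function(model) {
  stopifnot(inherits(model, "transcript_model"))
  ex <- model$exon_intervals
  if (nrow(ex) > 1L && any(ex[-nrow(ex), "end"] > ex[-1L, "start"])) {
    stop("overlapping exon intervals in ", model$transcript_id)
  }
  introns <- if (nrow(ex) > 1L) {
    interval_matrix(ex[-nrow(ex), "end"], ex[-1L, "start"])
  } else {
    interval_matrix()
  }
  regions <- list(utr5 = model$utr5_intervals,
                  exon = model$cds_intervals,
                  intron = introns,
                  utr3 = model$utr3_intervals)
  structure(
    list(gene_id = model$gene_id,
         chrom = model$chrom,
         strand = model$strand,
         regions = regions,
         region_length = vapply(regions, interval_width, 0L)),
    class = "region_partition")
}

#' Extract a strand-aware RNA window around a genomic position
#'
#' Returns the sequence of the `2*flank + 1` window centred on `pos`,
#' reverse-complemented for minus-strand features, clipped (not discarded)
#' at chromosome ends, with T replaced by U after strand resolution.
#'
#' @param genome A `DNAStringSet`.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param pos 0-based position; must lie inside the chromosome.
#' @param flank Non-negative number of nucleotides on each side.
#' @return List with `seq` (RNA character string) and `clipped` (logical).
#' @export
extract_window <- function(genome, chrom, strand, pos, flank) {
  stopifnot(chrom %in% names(genome), flank >= 0)
  len <- Biostrings::width(genome[chrom])
  if (pos < 0 || pos >= len) {
    stop("position ", pos, " outside chromosome ", chrom, " [0, ", len, ")")
  }
  gstart <- max(0L, as.integer(pos - flank))
  gend <- min(len, as.integer(pos + flank + 1L))
  dna <- Biostrings::subseq(genome[[chrom]], gstart + 1L, gend)
  if (strand == "-") dna <- Biostrings::reverseComplement(dna)
  list(seq = chartr("Tt", "Uu", as.character(dna)),
       clipped = (gend - gstart) < (2L * flank + 1L))
}

#' Write region partitions to BED6
#'
#' One record per region interval, named `gene_id|region`, 0-based
#' coordinates, score 0, gene strand.
#'
#' @param partitions List of `region_partition` objects.
#' @param path Output BED path.
#' @export
write_region_bed <- function(partitions, path) {
  rows <- do.call(rbind, lapply(partitions, function(p) {
    do.call(rbind, lapply(REGIONS, function(rg) {
      m <- p$regions[[rg]]
      if (!nrow(m)) return(NULL)
      data.frame(chrom = p$chrom, start = m[, "start"], end = m[, "end"],
                 name = paste0(p$gene_id, "|", rg), score = 0L,
                 strand = p$strand)
    }))
  }))
  gr <- GenomicRanges::GRanges(
    rows$chrom,
    IRanges::IRanges(rows$start + 1L, rows$end),
    strand = rows$strand, name = rows$name, score = rows$score)
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Read region partitions back from BED6
#'
#' Inverse of [write_region_bed()]; reconstructs `region_partition` objects
#' from records named `gene_id|region`.
#'
#' @param path BED path written by [write_region_bed()].
#' @return Named list of `region_partition` objects.
#' @export
read_region_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  name <- as.character(gr$name)
  gene <- sub("\\|[^|]*$", "", name)
  region <- sub("^.*\\|", "", name)
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  parts <- lapply(split(seq_along(gr), gene), function(idx) {
    regions <- lapply(REGIONS, function(rg) {
      sel <- idx[region[idx] == rg]
      interval_matrix(start0[sel], end0[sel])
    })
    names(regions) <- REGIONS
    structure(
      list(gene_id = gene[idx[1L]],
           chrom = as.character(GenomicRanges::seqnames(gr))[idx[1L]],
           strand = as.character(GenomicRanges::strand(gr))[idx[1L]],
           regions = regions,
           region_length = vapply(regions, interval_width, 0L)),
      class = "region_partition")
  })
  parts[order(names(parts))]
}

#' Map genomic positions into concatenated region coordinates
#'
#' Positions are 0-based in the concatenation (genomic order) of the
#' region's intervals; genomic positions outside the region give `NA`.
#'
#' @param partition A `region_partition`.
#' @param region Region name (`utr5`, `exon`, `intron`, `utr3`).
#' @param gpos Integer vector of genomic positions.
#' @return Integer vector of region coordinates.
#' @export
genomic_to_region <- function(partition, region, gpos) {
  m <- partition$regions[[region]]
  if (!nrow(m)) return(rep(NA_integer_, length(gpos)))
  offsets <- c(0L, cumsum(m[, "end"] - m[, "start"]))
  idx <- findInterval(gpos, m[, "start"])
  rpos <- rep(NA_integer_, length(gpos))
  ok <- idx >= 1L & idx <= nrow(m)
  okpos <- ok & gpos < m[pmax(idx, 1L), "end"]
  rpos[okpos] <- offsets[idx[okpos]] + (gpos[okpos] - m[idx[okpos], "start"])
  as.integer(rpos)
}

#' Map concatenated region coordinates back to genomic positions
#'
#' Inverse of [genomic_to_region()] for positions
#' `0 .. region_length - 1`.
#'
#' @inheritParams genomic_to_region
#' @param rpos Integer vector of region coordinates.
#' @return Integer vector of genomic positions.
#' @export
region_to_genomic <- function(partition, region, rpos) {
  m <- partition$regions[[region]]
  widths <- m[, "end"] - m[, "start"]
  offsets <- c(0L, cumsum(widths))
  idx <- findInterval(rpos, offsets, rightmost.closed = FALSE)
  idx[rpos >= offsets[length(offsets)]] <- NA_integer_
  as.integer(m[idx, "start"] + (rpos - offsets[idx]))
}
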
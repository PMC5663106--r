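## Sequence context around consensus crosslink sites: 21-nt window
## collection, pentamer Z-score enrichment against a uniform crosslink
## background, and MEME input preparation.

#' Collect RNA windows around consensus crosslink sites
#'
#' Extends each site by `flank` nucleotides in either direction and extracts
#' the strand-resolved RNA sequence (T replaced by U). Sites antisense to
#' their gene are removed by default; windows clipped at chromosome ends are
#' flagged rather than discarded.
#'
#' @param sites data.frame with `gene_id`, `region`, `gpos` and optionally
#'   `strand` (events antisense to the gene are dropped when
#'   `drop_antisense`).
#' @param genome A `DNAStringSet`.
#' @param partitions Named list of `region_partition` objects (provides the
#'   gene strand and chromosome).
#' @param flank Window half-width in nucleotides.
#' @param drop_antisense Remove sites whose strand differs from the gene's.
#' @return data.frame with `gene_id`, `region`, `gpos`, `seq`, `clipped`.
#' @export
collect_windows <- function(sites, genome, partitions, flank = 10,
                            drop_antisense = TRUE) {
  if (drop_antisense && "strand" %in% names(sites)) {
    gene_strand <- vapply(partitions[sites$gene_id], `[[`, character(1),
                          "strand")
    sites <- sites[sites$strand == gene_strand, , drop = FALSE]
  }
  if (!nrow(sites)) {
    return(data.frame(gene_id = character(0), region = character(0),
                      gpos = integer(0), seq = character(0),
                      clipped = logical(0)))
  }
  win <- lapply(seq_len(nrow(sites)), function(i) {
    p <- partitions[[sites$gene_id[i]]]
    extract_window(genome, p$chrom, p$strand, sites$gpos[i], flank)
  })
  data.frame(gene_id = sites$gene_id, region = sites$region,
             gpos = sites$gpos,
             seq = vapply(win, `[[`, character(1), "seq"),
             clipped = vapply(win, `[[`, logical(1), "clipped"))
}

## k-mer frame counts over a set of windows; frames containing N are skipped
## in both numerator and denominator.
kmer_counts <- function(seqs, k = 5) {
  counts <- new.env(parent = emptyenv())
  total <- 0L
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    frames <- substring(s, seq_len(n - k + 1L), k:n)
    frames <- frames[!grepl("N", frames, fixed = TRUE)]
    total <- total + length(frames)
    for (f in frames) {
      counts[[f]] <- (if (is.null(counts[[f]])) 0L else counts[[f]]) + 1L
    }
  }
  list(counts = counts, total = total)
}

kmer_freq_vector <- function(seqs, kmers, k = 5) {
  kc <- kmer_counts(seqs, k)
  if (kc$total == 0L) return(stats::setNames(numeric(length(kmers)), kmers))
  f <- vapply(kmers, function(p) {
    v <- kc$counts[[p]]
    if (is.null(v)) 0 else v / kc$total
  }, 0)
  f
}

#' Draw uniform background windows for one region
#'
#' Simulates `n` crosslink positions uniformly over the concatenated region
#' of the given genes and extracts their windows by the same path as the
#' observed windows (strand resolution and T to U included).
#'
#' @param genes Gene ids providing the region pool.
#' @param region Region name.
#' @param genome,partitions As in [collect_windows()].
#' @param n Number of windows.
#' @param flank Window half-width.
#' @return Character vector of RNA windows.
#' @export
sample_background_windows <- function(genes, region, genome, partitions,
                                      n, flank = 10) {
  pool <- lapply(genes, function(g) {
    L <- partitions[[g]]$region_length[[region]]
    if (L > 0) data.frame(gene_id = g, rpos_max = L) else NULL
  })
  pool <- do.call(rbind, pool)
  if (is.null(pool)) stop("no positions available in region ", region)
  lens <- pool$rpos_max
  gene_idx <- sample.int(nrow(pool), n, replace = TRUE, prob = lens)
  rpos <- floor(stats::runif(n) * lens[gene_idx])
  seqs <- character(n)
  for (i in seq_len(n)) {
    g <- pool$gene_id[gene_idx[i]]
    p <- partitions[[g]]
    gpos <- region_to_genomic(p, region, as.integer(rpos[i]))
    seqs[i] <- extract_window(genome, p$chrom, p$strand, gpos, flank)$seq
  }
  seqs
}

#' Pentamer Z-score enrichment around crosslink sites
#'
#' Slides a 5-nt frame along every observed window and along `n_background`
#' sets of windows around uniformly simulated crosslinks in the same
#' region, and computes per pentamer
#' `Z(P) = (f_exp(P) - mu_f(P)) / sigma_f(P)`, where `mu_f`/`sigma_f` are
#' the mean and standard deviation of the pentamer's frequency across the
#' background draws. Pentamers absent from both observed and background
#' windows are omitted; pentamers with zero background variance are
#' reported as `Inf`/`-Inf` (flagged) and rank top.
#'
#' @param windows Observed window data.frame from [collect_windows()] (one
#'   region at a time).
#' @param genome,partitions Needed to extract background windows.
#' @param region Region name; defaults to the windows' region.
#' @param n_background Number of background draws.
#' @param flank Window half-width used for the background windows.
#' @param background_seqs Optional list of `n_background` character vectors
#'   of pre-drawn background windows (replaces the uniform simulation; used
#'   for controlled comparisons).
#' @return data.frame sorted by decreasing `z`: `pentamer`, `f_exp`,
#'   `mu_f`, `sigma_f`, `z`, `zero_variance`.
#' @export
pentamer_zscores <- function(windows, genome, partitions, region = NULL,
                             n_background = 100, flank = 10,
                             background_seqs = NULL) {
  if (!is.null(background_seqs)) n_background <- length(background_seqs)
  if (is.null(region)) region <- unique(windows$region)
  stopifnot(length(region) == 1L)
  if (!nrow(windows) || all(nchar(windows$seq) < 5L)) {
    stop("pentamer analysis needs at least one window of length >= 5")
  }
  kmers <- apply(expand.grid(rep(list(c("A", "C", "G", "U")), 5))[, 5:1],
                 1, paste0, collapse = "")
  kmers <- sort(kmers)
  f_exp <- kmer_freq_vector(windows$seq, kmers)

  genes <- unique(windows$gene_id)
  bg <- matrix(0, nrow = n_background, ncol = length(kmers),
               dimnames = list(NULL, kmers))
  for (d in seq_len(n_background)) {
    seqs <- if (is.null(background_seqs)) {
      sample_background_windows(genes, region, genome, partitions,
                                nrow(windows), flank)
    } else {
      background_seqs[[d]]
    }
    bg[d, ] <- kmer_freq_vector(seqs, kmers)
  }
  mu <- colMeans(bg)
  sigma <- sqrt(pmax(colSums(bg^2) - n_background * mu^2, 0) /
                  max(n_background - 1L, 1L))
  zero_var <- sigma == 0
  z <- ifelse(zero_var,
              ifelse(f_exp > mu, Inf, ifelse(f_exp < mu, -Inf, 0)),
              (f_exp - mu) / sigma)
  out <- data.frame(pentamer = kmers, f_exp = unname(f_exp),
                    mu_f = unname(mu), sigma_f = unname(sigma),
                    z = unname(z), zero_variance = unname(zero_var))
  out <- out[out$f_exp > 0 | out$mu_f > 0, , drop = FALSE]  # absent everywhere
  out[order(-out$z, out$pentamer), , drop = FALSE]
}

#' Write observed and background FASTA inputs for MEME
#'
#' The observed file contains the RNA windows with deterministic record ids
#' `gene|region|pos`; the background file contains the same number of
#' windows per region, extracted around crosslinks simulated uniformly in
#' the same genes and regions (same extraction path, including T to U).
#' Regions without windows are omitted.
#'
#' @param windows Window data.frame from [collect_windows()] (may span
#'   regions).
#' @param genome,partitions Needed for background extraction.
#' @param observed_path,background_path Output FASTA paths.
#' @param flank Window half-width for the background windows.
#' @return Invisible list of the two paths.
#' @export
write_meme_inputs <- function(windows, genome, partitions,
                              observed_path, background_path, flank = 10) {
  obs <- stats::setNames(
    windows$seq, paste(windows$gene_id, windows$region, windows$gpos,
                       sep = "|"))
  bg <- character(0)
  for (rg in unique(windows$region)) {
    sel <- windows$region == rg
    seqs <- sample_background_windows(unique(windows$gene_id[sel]), rg,
                                      genome, partitions, sum(sel), flank)
    names(seqs) <- paste0("background|", rg, "|", seq_along(seqs))
    bg <- c(bg, seqs)
  }
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(obs), observed_path)
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(bg), background_path)
  invisible(list(observed = observed_path, background = background_path))
}
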
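## Downstream target integration: TPM computation, RIP-seq enrichment and
## DEG filtering, target-set algebra with printed-precision percentage
## summaries, direction-of-regulation comparison, and PSI/delta-PSI
## splicing quantification.

#' Create a named target set
#'
#' @param members Character vector of gene ids (deduplicated).
#' @param name Set name.
#' @param provenance Free-text origin of the set.
#' @return A `target_set`.
#' @export
target_set <- function(members, name = "targets", provenance = "") {
  structure(list(name = name, members = unique(as.character(members)),
                 provenance = provenance),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat("<target_set> ", x$name, ": ", length(x$members), " genes\n", sep = "")
  invisible(x)
}

#' Transcripts-per-million normalisation
#'
#' `TPM_i = 1e6 * (c_i / l_i) / sum_j (c_j / l_j)` per sample column.
#'
#' @param counts Numeric matrix (features x samples).
#' @param effective_lengths Positive lengths, one per feature.
#' @return TPM matrix; every column sums to 1e6.
#' @export
compute_tpm <- function(counts, effective_lengths) {
  counts <- as.matrix(counts)
  stopifnot(length(effective_lengths) == nrow(counts),
            all(effective_lengths > 0))
  rate <- counts / effective_lengths
  tot <- colSums(rate)
  if (any(tot == 0)) stop("all-zero counts column: TPM undefined")
  sweep(rate, 2, tot, "/") * 1e6
}

## Half-away-from-zero rounding at the precision of printed values
## (base round() rounds half to even).
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

ensure_qvalue <- function(stats_df) {
  if (!("qvalue" %in% names(stats_df)) || all(is.na(stats_df$qvalue))) {
    if (!("pvalue" %in% names(stats_df))) {
      stop("need a qvalue column, or a pvalue column to BH-adjust")
    }
    stats_df$qvalue <- stats::p.adjust(stats_df$pvalue, method = "BH")
  }
  stats_df
}

#' RIP-seq enrichment filter
#'
#' Keeps genes expressed in the RIP libraries (TPM at least `min_tpm`;
#' lower-expressed genes are excluded regardless of fold change), enriched
#' over the poly(A) RNA reference (`log2fc >= min_log2fc`, or strictly
#' greater with `strict = TRUE`) at `qvalue < max_q`.
#'
#' @param stats_df data.frame with `gene_id`, `log2fc` and `qvalue` (or
#'   `pvalue`, BH-adjusted on the fly).
#' @param rip_tpm Named vector of mean RIP TPM per gene.
#' @param min_tpm Expression gate.
#' @param min_log2fc Enrichment gate.
#' @param max_q FDR gate (strict `<`).
#' @param strict Use `log2fc > min_log2fc` instead of `>=`.
#' @return A `target_set` of RIP targets.
#' @export
rip_enrichment_filter <- function(stats_df, rip_tpm, min_tpm = 5,
                                  min_log2fc = 0.5, max_q = 0.001,
                                  strict = FALSE) {
  stats_df <- ensure_qvalue(stats_df)
  tpm <- rip_tpm[stats_df$gene_id]
  expressed <- !is.na(tpm) & tpm >= min_tpm
  enriched <- if (strict) stats_df$log2fc > min_log2fc else
    stats_df$log2fc >= min_log2fc
  keep <- expressed & enriched & stats_df$qvalue < max_q
  target_set(stats_df$gene_id[keep], name = "RIP",
             provenance = sprintf("TPM>=%g, log2FC%s%g, q<%g", min_tpm,
                                  if (strict) ">" else ">=", min_log2fc,
                                  max_q))
}

#' Differentially-expressed-gene filter
#'
#' Keeps genes with `qvalue < max_q` and TPM strictly above `min_tpm` in at
#' least one genotype.
#'
#' @param stats_df data.frame with `gene_id` and `qvalue` (or `pvalue`).
#' @param tpm_by_genotype Matrix of mean TPM (genes x genotypes) with
#'   rownames matching `gene_id`.
#' @param max_q FDR gate (strict `<`).
#' @param min_tpm Expression gate (strict `>` in at least one genotype).
#' @return A `target_set` of DEGs.
#' @export
deg_filter <- function(stats_df, tpm_by_genotype, max_q = 0.05, min_tpm = 1) {
  stats_df <- ensure_qvalue(stats_df)
  tpm <- tpm_by_genotype[stats_df$gene_id, , drop = FALSE]
  expressed <- apply(tpm > min_tpm, 1, any)
  keep <- stats_df$qvalue < max_q & expressed
  target_set(stats_df$gene_id[keep], name = "DEG",
             provenance = sprintf("q<%g, TPM>%g in >=1 genotype", max_q,
                                  min_tpm))
}

#' Overlap report for two target sets
#'
#' @param a,b `target_set` objects.
#' @param digits Decimals of the reported percentages (rounded half away
#'   from zero, matching how published percentages are printed).
#' @return List with `n_a`, `n_b`, `n_both`, `pct_of_a`, `pct_of_b`.
#' @export
intersect_targets <- function(a, b, digits = 0) {
  both <- length(intersect(a$members, b$members))
  list(n_a = length(a$members), n_b = length(b$members), n_both = both,
       pct_of_a = round_half_away(100 * both / length(a$members), digits),
       pct_of_b = round_half_away(100 * both / length(b$members), digits))
}

#' Cross-reference target sets against reference sets
#'
#' For every (target set, reference set) pair, reports the member counts,
#' the overlap, and the overlap as a percentage of the reference set at the
#' requested precision.
#'
#' @param target_sets,reference_sets Lists of `target_set` objects.
#' @param digits Decimals for percentages.
#' @return data.frame with one row per pair.
#' @export
crossref_summary <- function(target_sets, reference_sets, digits = 2) {
  rows <- list()
  for (ts in target_sets) {
    for (rs in reference_sets) {
      both <- length(intersect(ts$members, rs$members))
      rows[[length(rows) + 1L]] <- data.frame(
        target = ts$name, reference = rs$name,
        n_target = length(ts$members), n_reference = length(rs$members),
        n_overlap = both,
        pct_of_reference = round_half_away(
          100 * both / max(length(rs$members), 1L), digits))
    }
  }
  do.call(rbind, rows)
}

## Mann-Whitney U statistic of x against y (number of (x_i, y_j) pairs with
## x_i > y_j, ties counting one half).
mann_whitney_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Direction-of-regulation summary for target groups
#'
#' For each target set, counts up- and downregulated members among the DEGs
#' and compares the set's log2-fold-change distribution against the full
#' DEG distribution with a two-sided Mann-Whitney U test.
#'
#' @param deg_log2fc Named numeric vector: log2 fold change of every DEG.
#' @param target_sets List of `target_set` objects; members outside
#'   `deg_log2fc` are ignored.
#' @return data.frame with `set`, `n`, `n_up`, `n_down`, `U`, `pvalue`
#'   (`NA` with a warning for sets below two members).
#' @export
direction_summary <- function(deg_log2fc, target_sets) {
  do.call(rbind, lapply(target_sets, function(ts) {
    lfc <- deg_log2fc[intersect(ts$members, names(deg_log2fc))]
    if (length(lfc) < 2L) {
      warning("set ", ts$name, " has fewer than two DEG members; ",
              "comparison skipped")
      return(data.frame(set = ts$name, n = length(lfc),
                        n_up = sum(lfc > 0), n_down = sum(lfc < 0),
                        U = NA_real_, pvalue = NA_real_))
    }
    wt <- stats::wilcox.test(lfc, deg_log2fc, alternative = "two.sided",
                             exact = FALSE, correct = FALSE)
    data.frame(set = ts$name, n = length(lfc),
               n_up = sum(lfc > 0), n_down = sum(lfc < 0),
               U = mann_whitney_u(lfc, deg_log2fc), pvalue = wt$p.value)
  }))
}

#' Percent-spliced-in per splicing event
#'
#' PSI of an event in one sample is the TPM of the inclusion isoforms over
#' the TPM of all isoforms of the gene; per genotype the mean over
#' replicates is reported (or PSI of the pooled TPMs with
#' `mode = "pooled"`). Genes with a single annotated isoform are excluded.
#' Replicates with zero total TPM give an undefined PSI and are dropped
#' with a warning; events undefined in all replicates of a genotype are
#' dropped.
#'
#' @param isoform_tpm Matrix of isoform TPM (isoforms x samples).
#' @param events data.frame with `event_id`, `gene_id`, `inclusion`
#'   (comma-separated isoform ids) and `all` (comma-separated isoform ids).
#' @param sample_groups Character vector (length `ncol(isoform_tpm)`)
#'   assigning each sample column to a genotype.
#' @param mode `"replicate_mean"` or `"pooled"`.
#' @return List with `psi` (data.frame: `event_id`, `gene_id`, one
#'   `psi_<genotype>` column per genotype) and `replicate_psi` (matrix
#'   events x samples of per-replicate PSI).
#' @export
compute_psi <- function(isoform_tpm, events, sample_groups,
                        mode = c("replicate_mean", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(length(sample_groups) == ncol(isoform_tpm))
  split_ids <- function(x) strsplit(x, ",", fixed = TRUE)
  incl <- split_ids(events$inclusion)
  all_iso <- split_ids(events$all)
  multi <- lengths(all_iso) >= 2L
  events <- events[multi, , drop = FALSE]
  incl <- incl[multi]
  all_iso <- all_iso[multi]
  missing_iso <- setdiff(unlist(all_iso), rownames(isoform_tpm))
  if (length(missing_iso)) {
    stop("isoforms absent from the TPM table: ",
         paste(utils::head(missing_iso, 3), collapse = ", "))
  }
  stopifnot(all(mapply(function(i, a) all(i %in% a), incl, all_iso)))

  rep_psi <- t(vapply(seq_len(nrow(events)), function(i) {
    num <- colSums(isoform_tpm[incl[[i]], , drop = FALSE])
    den <- colSums(isoform_tpm[all_iso[[i]], , drop = FALSE])
    ifelse(den > 0, num / den, NA_real_)
  }, numeric(ncol(isoform_tpm))))
  rownames(rep_psi) <- events$event_id
  colnames(rep_psi) <- colnames(isoform_tpm)
  if (anyNA(rep_psi)) {
    warning(sum(is.na(rep_psi)),
            " replicate PSI values undefined (zero total TPM); excluded")
  }

  genotypes <- unique(sample_groups)
  psi <- data.frame(event_id = events$event_id, gene_id = events$gene_id)
  for (g in genotypes) {
    cols <- sample_groups == g
    psi[[paste0("psi_", g)]] <- if (mode == "replicate_mean") {
      rowMeans(rep_psi[, cols, drop = FALSE], na.rm = TRUE)
    } else {
      vapply(seq_len(nrow(events)), function(i) {
        num <- sum(isoform_tpm[incl[[i]], cols, drop = FALSE])
        den <- sum(isoform_tpm[all_iso[[i]], cols, drop = FALSE])
        if (den > 0) num / den else NaN
      }, 0)
    }
  }
  defined <- !Reduce(`|`, lapply(genotypes, function(g) {
    is.nan(psi[[paste0("psi_", g)]])
  }))
  if (!all(defined)) {
    warning(sum(!defined), " events undefined in every replicate of a ",
            "genotype; dropped")
  }
  list(psi = psi[defined, , drop = FALSE],
       replicate_psi = rep_psi[defined, , drop = FALSE])
}

#' Delta-PSI between a genotype and the reference
#'
#' @param psi PSI data.frame from [compute_psi()].
#' @param genotype,reference Genotype column suffixes.
#' @return `psi` with an added `delta_psi` column
#'   (`psi_<genotype> - psi_<reference>`).
#' @export
delta_psi <- function(psi, genotype, reference = "wt") {
  psi$delta_psi <- psi[[paste0("psi_", genotype)]] -
    psi[[paste0("psi_", reference)]]
  psi
}

#' Replicate-permutation p-value for delta-PSI
#'
#' Exact test over all reassignments of the replicate labels between the
#' two genotypes: the p-value of an event is the fraction of permutations
#' whose |delta-PSI| is at least the observed one (the identity permutation
#' included, so p is never 0).
#'
#' @param replicate_psi Matrix (events x samples) of per-replicate PSI.
#' @param sample_groups Genotype per sample column.
#' @param genotype,reference The two genotypes to compare.
#' @return Numeric vector of p-values, one per event.
#' @export
psi_permutation_pvalue <- function(replicate_psi, sample_groups,
                                   genotype, reference = "wt") {
  cols <- which(sample_groups %in% c(genotype, reference))
  m <- replicate_psi[, cols, drop = FALSE]
  n1 <- sum(sample_groups[cols] == genotype)
  combs <- utils::combn(length(cols), n1)
  obs_idx <- which(sample_groups[cols] == genotype)
  d <- apply(combs, 2, function(idx) {
    rowMeans(m[, idx, drop = FALSE], na.rm = TRUE) -
      rowMeans(m[, -idx, drop = FALSE], na.rm = TRUE)
  })
  d <- matrix(d, nrow = nrow(m))
  obs_col <- which(apply(combs, 2, function(idx) identical(idx, obs_idx)))
  obs <- d[, obs_col]
  rowMeans(abs(d) >= abs(obs) - 1e-12)
}

#' Filter splicing events on effect size and significance
#'
#' Keeps events with `|delta_psi| > min_abs_dpsi` and `pvalue < max_p`
#' (both strict).
#'
#' @param psi data.frame with `delta_psi` and `pvalue` columns.
#' @param min_abs_dpsi Effect-size gate.
#' @param max_p Significance gate.
#' @return The significant subset of `psi`.
#' @export
delta_psi_filter <- function(psi, min_abs_dpsi = 0.1, max_p = 0.01) {
  stopifnot(all(c("delta_psi", "pvalue") %in% names(psi)))
  psi[abs(psi$delta_psi) > min_abs_dpsi & psi$pvalue < max_p, , drop = FALSE]
}
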
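## Significant crosslink-site calling: window-height statistic, uniform
## permutation background, per-height FDR, rerun stability, replicate
## consensus and control-library subtraction.
##
## All of this operates per (gene, region) track in concatenated region
## coordinates, so windows never leak across genes or region types.

## Heights at the stored positions (1-based indices) given a dense count
## vector of length L: sum of counts in [pos - flank, pos + flank].
window_sums <- function(counts, pos, flank) {
  cs <- cumsum(counts)
  L <- length(counts)
  hi <- pmin(L, pos + flank)
  lo <- pos - flank - 1L  # index just before the window start
  cs[hi] - ifelse(lo < 1L, 0, cs[pmax(lo, 1L)])
}

#' Compute the height distribution of a crosslink track
#'
#' Each crosslinked position `x` is extended by `flank` nucleotides in both
#' directions (in concatenated region coordinates) and the crosslink event
#' counts in the window are summed, defining the height `h(x)`. The
#' distribution `n_h` counts crosslinked positions by height.
#'
#' @param track A crosslink track ([tally_crosslinks()]) or any list with
#'   `rpos` (0-based distinct positions), `count` and `region_length`.
#' @param flank Window half-width in nucleotides.
#' @return A `height_distribution`: `pos`, `count`, `h` (per position),
#'   `n_h` (heights `1..H`), `H`, `N` (distinct crosslinked positions),
#'   `n_events` (total events), `region_length`, `flank`.
#' @export
compute_heights <- function(track, flank = 15) {
  L <- as.integer(track$region_length)
  pos <- as.integer(track$rpos)
  count <- as.integer(track$count)
  if (!length(pos)) {
    return(structure(list(pos = integer(0), count = integer(0),
                          h = integer(0), n_h = integer(0), H = 0L, N = 0L,
                          n_events = 0L, region_length = L, flank = flank),
                     class = "height_distribution"))
  }
  stopifnot(all(pos >= 0L & pos < L), all(count >= 1L), !anyDuplicated(pos))
  dense <- integer(L)
  dense[pos + 1L] <- count
  h <- as.integer(window_sums(dense, pos + 1L, as.integer(flank)))
  structure(list(pos = pos, count = count, h = h,
                 n_h = tabulate(h, nbins = max(h)), H = max(h),
                 N = length(pos), n_events = sum(count),
                 region_length = L, flank = flank),
            class = "height_distribution")
}

#' Observed tail probabilities of the height distribution
#'
#' `P(h) = sum_{i >= h} n_i / N` for `h = 1..H`: the probability that a
#' crosslinked position in the region has height at least `h`.
#'
#' @param dist A `height_distribution`.
#' @return Numeric vector `P[h]` for `h = 1..H` (length 0 when `N = 0`).
#' @export
tail_probability <- function(dist) {
  if (dist$N == 0L) return(numeric(0))
  rev(cumsum(rev(dist$n_h))) / dist$N
}

## One uniform background draw: n_events events with replacement over L
## positions; returns the tail counts (#positions with height >= h) for
## h = 1..H together with the draw's number of distinct positions.
draw_tail_counts <- function(L, n_events, flank, H) {
  pos <- sample.int(L, n_events, replace = TRUE)
  dense <- tabulate(pos, nbins = L)
  upos <- unique(pos)
  h <- window_sums(dense, upos, flank)
  hc <- tabulate(pmin(h, H), nbins = H)  # heights beyond H pool at H
  list(tail = rev(cumsum(rev(hc))), n = length(upos))
}

#' Simulate the uniform permutation background of a region
#'
#' Distributes the observed number of crosslink events uniformly (with
#' replacement) over the region `n_draws` times; per draw the heights and
#' tail probabilities are computed exactly as for the observed data. The
#' mean and standard deviation across draws of the random tail statistic at
#' each height `h = 1..H` are returned (0 for draws whose maximum height is
#' below `h`).
#'
#' @param region_length Region length in nucleotides.
#' @param n_events Number of events to redistribute.
#' @param H Largest height of interest (usually the observed maximum).
#' @param n_draws Number of background draws.
#' @param flank Window half-width, matching [compute_heights()].
#' @param background_stat `"tailprob"` (default): the statistic is the tail
#'   probability; `"count"`: the raw tail count of positions with height
#'   at least `h`.
#' @return List with `mu`, `sigma` (length `H`), `n_draws`,
#'   `background_stat`. Uses the current RNG state; seed with `set.seed()`
#'   for reproducibility.
#' @export
simulate_background <- function(region_length, n_events, H, n_draws = 100,
                                flank = 15,
                                background_stat = c("tailprob", "count")) {
  background_stat <- match.arg(background_stat)
  if (region_length < 1 && n_events > 0) {
    stop("cannot place ", n_events, " events in an empty region")
  }
  H <- as.integer(H)
  if (n_events == 0L || H == 0L) {
    z <- numeric(H)
    return(list(mu = z, sigma = z, n_draws = n_draws,
                background_stat = background_stat))
  }
  stat <- matrix(0, nrow = n_draws, ncol = H)
  for (d in seq_len(n_draws)) {
    dr <- draw_tail_counts(as.integer(region_length), as.integer(n_events),
                           as.integer(flank), H)
    stat[d, ] <- if (background_stat == "tailprob") dr$tail / dr$n else dr$tail
  }
  mu <- colMeans(stat)
  sigma <- sqrt(pmax(colSums(stat^2) - n_draws * mu^2, 0) /
                  max(n_draws - 1L, 1L))
  list(mu = mu, sigma = sigma, n_draws = n_draws,
       background_stat = background_stat)
}

#' Per-height false discovery rate
#'
#' `FDR(h) = (mu_h + sigma_h) / P(h)`: the background exceedance statistic
#' relative to the observed tail probability. Heights never reached in the
#' background have `mu = sigma = 0` and hence FDR 0. With the `"count"`
#' background statistic the numerator is rescaled by the observed number of
#' positions so both modes share units.
#'
#' @param P_obs Observed tail probabilities ([tail_probability()]).
#' @param background Result of [simulate_background()].
#' @param N Observed number of distinct crosslinked positions (needed for
#'   the `"count"` statistic).
#' @return Numeric vector `FDR[h]` for `h = 1..H`.
#' @export
fdr_per_height <- function(P_obs, background, N = NULL) {
  num <- background$mu + background$sigma
  if (background$background_stat == "count") {
    if (is.null(N)) stop("N is required for the count background statistic")
    num <- num / N
  }
  num / P_obs
}

#' Call significant crosslink sites in one region track
#'
#' Repeats the whole significance procedure `n_reruns` times, each with a
#' fresh uniform background of `n_draws` draws; in each rerun a crosslinked
#' position is significant iff the FDR at its height is strictly below
#' `alpha`. Positions significant in at least `stability` of the reruns are
#' retained.
#'
#' @param track A crosslink track.
#' @param alpha FDR significance level.
#' @param n_draws Background draws per rerun.
#' @param n_reruns Number of procedure reruns.
#' @param stability Minimum fraction of reruns in which a retained position
#'   must be significant.
#' @param flank Window half-width.
#' @param background_stat See [simulate_background()].
#' @return List with `sites` (data.frame of retained positions: `gene_id`,
#'   `region`, `gpos`, `rpos`, `count`, `h`, `stability`), `stability_all`
#'   (per-position fractions), `dist` and `mean_sig_fraction` (mean over
#'   reruns of the fraction of positions significant in that rerun).
#' @export
call_significant_sites <- function(track, alpha = 0.05, n_draws = 100,
                                   n_reruns = 1000, stability = 0.95,
                                   flank = 15,
                                   background_stat = c("tailprob", "count")) {
  background_stat <- match.arg(background_stat)
  dist <- compute_heights(track, flank = flank)
  empty <- data.frame(gene_id = character(0), region = character(0),
                      gpos = integer(0), rpos = integer(0),
                      count = integer(0), h = integer(0),
                      stability = numeric(0))
  if (dist$N == 0L) {
    return(list(sites = empty, stability_all = numeric(0), dist = dist,
                mean_sig_fraction = 0))
  }
  P_obs <- tail_probability(dist)
  sig_count <- integer(dist$N)
  sig_fraction <- numeric(n_reruns)
  for (r in seq_len(n_reruns)) {
    bg <- simulate_background(dist$region_length, dist$n_events, dist$H,
                              n_draws = n_draws, flank = flank,
                              background_stat = background_stat)
    fdr <- fdr_per_height(P_obs, bg, N = dist$N)
    sig <- fdr[dist$h] < alpha
    sig_count <- sig_count + sig
    sig_fraction[r] <- mean(sig)
  }
  frac <- sig_count / n_reruns
  keep <- frac >= stability
  sites <- if (any(keep)) {
    data.frame(gene_id = track$gene_id, region = track$region,
               gpos = track$gpos[keep], rpos = dist$pos[keep],
               count = dist$count[keep], h = dist$h[keep],
               stability = frac[keep])
  } else {
    empty
  }
  list(sites = sites, stability_all = frac, dist = dist,
       mean_sig_fraction = mean(sig_fraction))
}

#' Consensus positions across biological replicates
#'
#' A position is a consensus crosslink site when it is significant at the
#' identical coordinate in at least `min_support` replicates. The default
#' is "all but one" (`R - 1`), and both replicates when `R = 2`.
#'
#' @param position_sets List (one element per replicate) of integer vectors
#'   of significant positions.
#' @param min_support Minimum number of supporting replicates; default
#'   `max(R - 1, 2)`.
#' @return data.frame with `pos` and `support`, ordered by position.
#' @export
replicate_consensus <- function(position_sets, min_support = NULL) {
  R <- length(position_sets)
  if (R < 2L) stop("replicate consensus needs at least two replicates")
  if (is.null(min_support)) min_support <- max(R - 1L, 2L)
  tab <- table(unlist(lapply(position_sets, unique)))
  keep <- tab >= min_support
  data.frame(pos = as.integer(names(tab))[keep],
             support = as.integer(tab)[keep])
}

## Significant sites for every track of one replicate.
call_replicate <- function(tracks, ...) {
  out <- do.call(rbind, lapply(tracks, function(tr) {
    call_significant_sites(tr, ...)$sites
  }))
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), region = character(0),
                      gpos = integer(0), rpos = integer(0),
                      count = integer(0), h = integer(0),
                      stability = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Call consensus crosslink sites across replicate track sets
#'
#' Runs [call_significant_sites()] independently on every (gene, region)
#' track of every replicate, then applies [replicate_consensus()] per
#' (gene, region) on the genomic positions.
#'
#' @param replicate_tracks List over replicates; each element is a list of
#'   crosslink tracks as produced by [tally_crosslinks()].
#' @param min_support Replicate support threshold (see
#'   [replicate_consensus()]).
#' @param ... Passed to [call_significant_sites()].
#' @return data.frame of consensus sites: `gene_id`, `region`, `gpos`,
#'   `support`.
#' @export
call_consensus_sites <- function(replicate_tracks, min_support = NULL, ...) {
  R <- length(replicate_tracks)
  per_rep <- lapply(replicate_tracks, call_replicate, ...)
  keys <- unique(do.call(rbind, lapply(per_rep, function(d) {
    d[, c("gene_id", "region"), drop = FALSE]
  })))
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sets <- lapply(per_rep, function(d) {
      d$gpos[d$gene_id == keys$gene_id[i] & d$region == keys$region[i]]
    })
    cons <- replicate_consensus(sets, min_support = min_support)
    if (!nrow(cons)) return(NULL)
    data.frame(gene_id = keys$gene_id[i], region = keys$region[i],
               gpos = cons$pos, support = cons$support)
  }))
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0), region = character(0),
                      gpos = integer(0), support = integer(0))
  }
  out[order(out$gene_id, out$region, out$gpos), , drop = FALSE]
}

#' Remove genes with crosslink sites in control libraries
#'
#' Any gene owning a consensus crosslink site in any control group (GFP-only
#' or binding-dead libraries, each processed by the same pipeline) is
#' removed entirely from the treatment target set.
#'
#' @param treatment_sites Consensus site data.frame from
#'   [call_consensus_sites()] for the treatment group.
#' @param control_replicate_tracks List of control groups; each group is a
#'   list over replicates of track lists.
#' @param control_min_support Consensus support threshold within a control
#'   group (default 2).
#' @param ... Passed to [call_significant_sites()] for the control calls.
#' @return List with `targets` (a `target_set` of retained gene ids),
#'   `sites` (retained treatment sites) and `removed_genes`.
#' @export
subtract_controls <- function(treatment_sites, control_replicate_tracks,
                              control_min_support = 2, ...) {
  contaminated <- character(0)
  for (grp in control_replicate_tracks) {
    cons <- call_consensus_sites(grp, min_support = control_min_support, ...)
    contaminated <- union(contaminated, unique(cons$gene_id))
  }
  keep <- !(treatment_sites$gene_id %in% contaminated)
  sites <- treatment_sites[keep, , drop = FALSE]
  list(targets = target_set(unique(sites$gene_id), name = "iCLIP",
                            provenance = "consensus crosslink sites after control subtraction"),
       sites = sites,
       removed_genes = intersect(unique(treatment_sites$gene_id), contaminated))
}

#' Summarise consensus sites by transcript region
#'
#' Counts consensus crosslink sites per region, raw and normalised by the
#' summed genomic length of the region across genes, and tabulates genes by
#' the combination of regions they carry sites in.
#'
#' @param sites Consensus site data.frame.
#' @param partitions Named list of `region_partition` objects.
#' @return List with `per_region` (data.frame `region`, `n_sites`,
#'   `region_length`, `sites_per_kb`) and `gene_combinations` (table of
#'   region-combination labels).
#' @export
region_site_summary <- function(sites, partitions) {
  total_len <- vapply(REGIONS, function(rg) {
    sum(vapply(partitions, function(p) p$region_length[[rg]], 0L))
  }, 0L)
  n_sites <- vapply(REGIONS, function(rg) sum(sites$region == rg), 0L)
  combos <- vapply(split(sites$region, sites$gene_id), function(r) {
    paste(sort(unique(r)), collapse = "+")
  }, character(1))
  list(per_region = data.frame(region = REGIONS, n_sites = n_sites,
                               region_length = total_len,
                               sites_per_kb = ifelse(total_len > 0,
                                                     1000 * n_sites / total_len,
                                                     0)),
       gene_combinations = table(combos))
}
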
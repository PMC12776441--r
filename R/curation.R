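#' Curation configuration
#'
#' Bundles the thresholds of the site-curation and testing pipeline.
#' Defaults follow the study design this package implements: a +/- 40 bp
#' window for formation analysis (30 bp for repair), a binding-site span
#' of motif +/- 5 bp, retention of the top 50% of sites by motif score, a
#' 10,000-site cap for very large clusters, a minimum aggregate damage of
#' 30 at the best position, and significance thresholds of 0.05 (CPD) and
#' 0.01 (6-4 PP).
#'
#' @param window Half-width of the motif-relative analysis window (bp).
#' @param repair_window Half-width used by the repair analysis (bp).
#' @param span_pad Flank padding defining the binding-site span (bp).
#' @param top_fraction Fraction of accessible sites retained by score.
#' @param site_cap Maximum sites per cluster (`Inf` to disable).
#' @param min_aggregate Minimum aggregate damage count at the best
#'   position for a cluster to be testable.
#' @param threshold,threshold_64pp BH-adjusted significance thresholds.
#' @return List of class `uvf_curation_config`.
#' @export
curation_config <- function(window = 40L, repair_window = 30L,
                            span_pad = 5L, top_fraction = 0.5,
                            site_cap = 10000L, min_aggregate = 30L,
                            threshold = 0.05, threshold_64pp = 0.01) {
  stopifnot(window > 0, repair_window > 0, span_pad >= 0,
            top_fraction > 0, top_fraction <= 1, site_cap > 0,
            min_aggregate >= 0,
            threshold > 0, threshold < 1,
            threshold_64pp > 0, threshold_64pp < 1)
  structure(list(window = as.integer(window),
                 repair_window = as.integer(repair_window),
                 span_pad = as.integer(span_pad),
                 top_fraction = top_fraction, site_cap = site_cap,
                 min_aggregate = min_aggregate, threshold = threshold,
                 threshold_64pp = threshold_64pp),
            class = "uvf_curation_config")
}

#' Build accessible regions from peak calls
#'
#' Keeps the top fraction of peaks by signal, takes fixed-width windows
#' centered on peak summits, and subtracts genic intervals (windows may be
#' truncated or split).
#'
#' @param peaks Tibble with `chrom`, `start`, `end`, `signal` and
#'   `summit` (offset of the summit from `start`).
#' @param genic Interval table of genic regions to subtract (may be
#'   empty).
#' @param top_fraction Fraction of peaks retained, ranked by `signal`.
#' @param summit_width Width of the summit-centered window (bp).
#' @return Interval table of accessible regions.
#' @export
build_accessible_regions <- function(peaks, genic = NULL,
                                     top_fraction = 0.5,
                                     summit_width = 150L) {
  if (!"summit" %in% names(peaks)) {
    stop("peaks need a summit column (offset from start)", call. = FALSE)
  }
  if (!"signal" %in% names(peaks)) {
    stop("peaks need a signal column", call. = FALSE)
  }
  n_keep <- ceiling(nrow(peaks) * top_fraction)
  keep <- order(-peaks$signal, peaks$chrom, peaks$start)[seq_len(n_keep)]
  pk <- peaks[keep, , drop = FALSE]
  summit <- pk$start + pk$summit
  half <- floor(summit_width / 2)
  windows <- genomic_intervals(pk$chrom, pmax(summit - half, 0),
                               summit - half + summit_width)
  if (is.null(genic) || nrow(genic) == 0L) return(reduce_intervals(windows))
  subtract_intervals(windows, genic)
}

#' Curate active binding sites
#'
#' Retains sites whose motif interval overlaps the accessible regions,
#' then the top fraction by motif score (stable tie-break: score
#' descending, then chrom, then start), then applies the per-cluster site
#' cap.  The minimum-aggregate-damage filter is applied later against the
#' observed profile (see [cluster_sufficient()]), since it needs damage
#' data.
#'
#' @param sites A `uvf_sites` table.
#' @param accessible Interval table of accessible regions.
#' @param config A [curation_config()].
#' @return The curated `uvf_sites` table (possibly empty, with an
#'   `insufficient` attribute set).
#' @export
curate_active_sites <- function(sites, accessible,
                                config = curation_config()) {
  hit <- .overlaps_any(sites$chrom, sites$start, sites$end, accessible)
  s <- .keep_attrs(sites[hit, , drop = FALSE], sites)
  if (nrow(s)) {
    ord <- order(-s$score, s$chrom, s$start)
    n_keep <- min(ceiling(nrow(s) * config$top_fraction), config$site_cap)
    s <- .keep_attrs(s[ord[seq_len(n_keep)], , drop = FALSE], s)
    s <- .keep_attrs(dplyr::arrange(s, .data$chrom, .data$start), s)
  }
  if (nrow(s) == 0L) {
    uvf_inform(paste0("curate_active_sites: cluster ", cluster_id(sites),
                      " has no accessible sites"))
    attr(s, "insufficient") <- TRUE
  }
  s
}

#' Does a cluster meet the minimum aggregate damage?
#'
#' A cluster is testable only if at least one (position, strand) cell of
#' its observed profile reaches `min_aggregate` damages — the limit of
#' detection for position-level trends.
#'
#' @param observed Observed profile tibble (see [observed_profile()]).
#' @param min_aggregate Threshold count.
#' @return Logical scalar.
#' @export
cluster_sufficient <- function(observed, min_aggregate = 30L) {
  nrow(observed) > 0 && max(observed$observed) >= min_aggregate
}

#' Stratify sites into binding-strength tiers
#'
#' Splits a site set into `n_tiers` tiers of (near-)equal size by
#' descending motif score; any remainder goes to the top tiers.  Ties are
#' broken by genomic order for determinism.
#'
#' @param sites A `uvf_sites` table.
#' @param n_tiers Number of tiers.
#' @return List of `uvf_sites`, strongest tier first.
#' @export
stratify_by_strength <- function(sites, n_tiers = 3L) {
  if (nrow(sites) < n_tiers) {
    stop("need at least ", n_tiers, " sites to stratify", call. = FALSE)
  }
  ord <- order(-sites$score, sites$chrom, sites$start)
  sizes <- rep(nrow(sites) %/% n_tiers, n_tiers)
  extra <- nrow(sites) %% n_tiers
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, utils::head(stops, -1) + 1L)
  lapply(seq_len(n_tiers), function(i) {
    .keep_attrs(sites[ord[starts[i]:stops[i]], , drop = FALSE], sites)
  })
}
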
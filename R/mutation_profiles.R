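# Projected vs actual C>T mutation profiles over binding sites, the
# trinucleotide-conditioned shuffle null, and projected/actual
# concordance.

#' Project CPD damage into hypothetical C>T mutations
#'
#' Assumes every CPD-dimerized cytosine is mutated to thymine: each C
#' inside a damaged dipyrimidine contributes the lesion count as a
#' projected C>T at its own motif-relative position (a CC lesion projects
#' a tandem two-position CC>TT; a TT lesion projects nothing).  Strands
#' are aggregated.
#'
#' @param map A `uvf_damage_map` (the initial-timepoint CPD map).
#' @param genome A `uvf_genome`.
#' @param sites A `uvf_sites` table.
#' @param window Window half-width.
#' @return Tibble `position`, `projected` over the full window.
#' @export
project_mutations <- function(map, genome, sites, window = 40L) {
  grid <- tibble::tibble(position = seq(-window, window))
  if (nrow(map) == 0L || nrow(sites) == 0L) {
    grid$projected <- 0
    return(grid)
  }
  mp <- map_to_motif_coords(sites, map$chrom, map$strand, map$pos5, window)
  if (nrow(mp) == 0L) {
    grid$projected <- 0
    return(grid)
  }
  dinuc <- map$dinuc[mp$locus]
  if (anyNA(dinuc)) {
    dinuc <- .bare_dinuc(genome, map$chrom, map$strand,
                         map$pos5)[mp$locus]
  }
  count <- map$count[mp$locus]
  # base1 = 5' base on the damaged strand; it sits at the lower motif
  # coordinate when the damaged strand is the motif strand, at the higher
  # otherwise
  motif_first <- mp$profile_strand == "motif"
  pos_base1 <- ifelse(motif_first, mp$position, mp$position + 1)
  pos_base2 <- ifelse(motif_first, mp$position + 1, mp$position)
  contrib <- dplyr::bind_rows(
    tibble::tibble(position = pos_base1, count = count,
                   isC = substr(dinuc, 1, 1) == "C"),
    tibble::tibble(position = pos_base2, count = count,
                   isC = substr(dinuc, 2, 2) == "C"))
  agg <- contrib |>
    dplyr::filter(.data$isC, .data$position >= -window,
                  .data$position <= window) |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(projected = sum(.data$count), .groups = "drop")
  out <- dplyr::left_join(grid, agg, by = "position")
  out$projected <- dplyr::coalesce(out$projected, 0)
  out
}

#' Actual mutation profile over binding sites
#'
#' Maps pyrimidine-strand C>T events (reference C>T and G>A) into motif
#' coordinates and aggregates across strands and sites.  Records whose
#' reference base mismatches the genome are dropped with a logged count.
#' `substitution_filter = "all"` keeps every substitution (for
#' broad-substitution flank analyses).
#'
#' @param mutations A `uvf_mutations` table.
#' @param genome A `uvf_genome`.
#' @param sites A `uvf_sites` table.
#' @param window Window half-width.
#' @param substitution_filter `"c_to_t"` (default) or `"all"`.
#' @param unique_loci Count recurrent mutations at one locus once instead
#'   of per occurrence.
#' @return Tibble `position`, `actual`.
#' @export
actual_mutation_profile <- function(mutations, genome, sites,
                                    window = 40L,
                                    substitution_filter = c("c_to_t",
                                                            "all"),
                                    unique_loci = FALSE) {
  substitution_filter <- match.arg(substitution_filter)
  grid <- tibble::tibble(position = seq(-window, window))
  m <- mutations
  if (nrow(m)) {
    obs <- genome_base(genome, m$chrom, m$pos)
    bad <- obs != m$ref
    if (any(bad)) {
      uvf_inform(paste0("actual_mutation_profile: dropped ", sum(bad),
                        " ref-mismatching record(s)"))
      m <- m[!bad, , drop = FALSE]
    }
  }
  if (substitution_filter == "c_to_t") m <- filter_c_to_t(m)
  if (unique_loci && nrow(m)) {
    m <- m[!duplicated(paste(m$chrom, m$pos, m$ref, m$alt)), ,
           drop = FALSE]
  }
  if (nrow(m) == 0L || nrow(sites) == 0L) {
    grid$actual <- 0
    return(grid)
  }
  centers <- site_center(sites)
  q <- GenomicRanges::GRanges(m$chrom, IRanges::IRanges(m$pos + 1,
                                                        m$pos + 1))
  s <- GenomicRanges::GRanges(sites$chrom,
                              IRanges::IRanges(centers - window + 1,
                                               centers + window + 1))
  hits <- GenomicRanges::findOverlaps(q, s)
  mi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  position <- ifelse(sites$strand[si] == "+",
                     m$pos[mi] - centers[si],
                     centers[si] - m$pos[mi])
  agg <- tibble::tibble(position = position) |>
    dplyr::filter(.data$position >= -window, .data$position <= window) |>
    dplyr::count(.data$position, name = "actual")
  out <- dplyr::left_join(grid, agg, by = "position")
  out$actual <- dplyr::coalesce(out$actual, 0)
  out
}

#' Shuffle-null mutation enrichment test preserving trinucleotide context
#'
#' Reassigns every C>T mutation to a uniformly drawn cytosine of the same
#' pyrimidine-strand trinucleotide class within the background regions,
#' building an empirical null per position (strand-aggregated).  The null
#' is scaled to the average observed/null ratio in the flanking DNA per
#' motif half, then `z`, empirical one-sided p, and BH-adjusted q are
#' computed as in [shuffle_null_test()].
#'
#' @param mutations A `uvf_mutations` table.
#' @param regions Background interval table (accessible regions).
#' @param genome A `uvf_genome`.
#' @param sites A `uvf_sites` table.
#' @param window Window half-width.
#' @param n_iter Shuffle iterations.
#' @param seed Integer seed.
#' @param threshold Significance threshold on q.
#' @param span_pad Binding-site span padding for the flank definition.
#' @return Tibble of class `uvf_profile_test` keyed by `position`.
#' @export
trinucleotide_shuffle_test <- function(mutations, regions, genome, sites,
                                       window = 40L, n_iter = 1000L,
                                       seed = 1L, threshold = 0.05,
                                       span_pad = 5L) {
  loci <- enumerate_cytosine_loci(genome, regions)
  loci <- loci[!is.na(loci$ctx), , drop = FALSE]
  centers <- site_center(sites)
  # destination position of each cytosine locus (NA = outside windows)
  q <- GenomicRanges::GRanges(loci$chrom, IRanges::IRanges(loci$pos + 1,
                                                           loci$pos + 1))
  s <- GenomicRanges::GRanges(sites$chrom,
                              IRanges::IRanges(centers - window + 1,
                                               centers + window + 1))
  hits <- GenomicRanges::findOverlaps(q, s, select = "first")
  dest <- rep(0L, nrow(loci))
  hit <- !is.na(hits)
  pos_hit <- ifelse(sites$strand[hits[hit]] == "+",
                    loci$pos[hit] - centers[hits[hit]],
                    centers[hits[hit]] - loci$pos[hit])
  dest[hit] <- pos_hit + window + 1L  # cell 1..2w+1
  dest[dest < 1L | dest > 2L * window + 1L] <- 0L
  # classify observed mutations by locus
  m <- filter_c_to_t(mutations)
  key <- paste(loci$chrom, loci$strand, loci$pos)
  idx <- match(paste(m$chrom, m$pyr_strand, m$pos), key)
  if (anyNA(idx)) {
    uvf_inform(paste0("trinucleotide_shuffle_test: ", sum(is.na(idx)),
                      " mutation(s) outside classified loci skipped"))
  }
  cls <- loci$ctx[idx[!is.na(idx)]]
  per_locus <- tibble::tibble(locus = idx[!is.na(idx)], cls = cls) |>
    dplyr::count(.data$locus, .data$cls, name = "k")
  n_cells <- 2L * window + 1L
  null <- matrix(0, n_cells, n_iter)
  set.seed(substream_seed(seed, "mut_shuffle"))
  singletons <- 0L
  for (cl in sort(unique(per_locus$cls))) {
    in_cls <- which(loci$ctx == cl)
    if (length(in_cls) == 1L) singletons <- singletons + 1L
    prob <- tabulate(dest[in_cls] + 1L, nbins = n_cells + 1L)
    prob <- prob / sum(prob)
    sub <- per_locus[per_locus$cls == cl, , drop = FALSE]
    for (v in sort(unique(sub$k))) {
      n_v <- sum(sub$k == v)
      draws <- stats::rmultinom(n_iter, n_v, prob)
      null <- null + v * draws[-1L, , drop = FALSE]
    }
  }
  if (singletons > 0) {
    uvf_inform(paste0("trinucleotide_shuffle_test: ", singletons,
                      " singleton class(es); mutations stay put"))
  }
  obs_w <- numeric(n_cells)
  tmp <- tibble::tibble(cell = dest[per_locus$locus], k = per_locus$k) |>
    dplyr::filter(.data$cell > 0) |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(n = sum(.data$k), .groups = "drop")
  obs_w[tmp$cell] <- tmp$n
  out <- tibble::tibble(position = seq(-window, window),
                        observed = obs_w,
                        null_mean = rowMeans(null),
                        null_sd = apply(null, 1L, stats::sd))
  # flank scaling
  motif_len <- motif_length(sites)
  span_lo <- -floor(motif_len / 2) - span_pad
  span_hi <- motif_len - 1 - floor(motif_len / 2) + span_pad
  out$side <- .side_of(out$position)
  is_flank <- (out$position < span_lo | out$position > span_hi) &
    out$null_mean > 0
  fac <- out[is_flank, , drop = FALSE] |>
    dplyr::group_by(.data$side) |>
    dplyr::summarise(scale_factor = mean(.data$observed /
                                           .data$null_mean),
                     .groups = "drop")
  fac <- dplyr::left_join(tibble::tibble(side = c("left", "right")), fac,
                          by = "side")
  if (anyNA(fac$scale_factor)) {
    warning("trinucleotide_shuffle_test: no usable flank; factor 1",
            call. = FALSE)
    fac$scale_factor[is.na(fac$scale_factor)] <- 1
  }
  out <- dplyr::left_join(out, fac, by = "side")
  scaled_mean <- out$null_mean * out$scale_factor
  scaled_sd <- out$null_sd * out$scale_factor
  out$z <- ifelse(scaled_sd > 0, (out$observed - scaled_mean) / scaled_sd,
                  NA_real_)
  out$direction <- dplyr::case_when(
    out$observed > scaled_mean ~ "enriched",
    out$observed < scaled_mean ~ "depleted",
    TRUE ~ "none")
  p <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    scaled <- null[i, ] * out$scale_factor[i]
    p[i] <- if (out$direction[i] == "depleted") {
      (1 + sum(scaled <= out$observed[i])) / (n_iter + 1)
    } else {
      (1 + sum(scaled >= out$observed[i])) / (n_iter + 1)
    }
  }
  out$p <- p
  testable <- out$null_sd > 0 | out$observed > 0
  out$q <- NA_real_
  out$q[testable] <- stats::p.adjust(out$p[testable], method = "BH")
  out$significant <- !is.na(out$q) & out$q < threshold &
    out$direction != "none"
  structure(out, class = c("uvf_profile_test", class(tibble::tibble())),
            threshold = threshold, test = "trinuc_shuffle",
            n_iter = n_iter, null_matrix = null)
}

#' Concordance of projected and actual mutation profiles
#'
#' Pearson correlation and OLS regression of actual on projected counts
#' over window positions; residuals are standardized and positions with
#' `|z| > 2.58` flagged discordant.  A randomized baseline correlates the
#' projected profile with the actual profiles of `n_random` other
#' clusters.
#'
#' @param projected Tibble from [project_mutations()].
#' @param actual Tibble from [actual_mutation_profile()].
#' @param all_profiles Optional named list of other clusters' actual
#'   profiles for the randomized baseline.
#' @param n_random Number of random clusters in the baseline.
#' @param seed Integer seed for the baseline draw.
#' @param z_cut Discordance threshold on |residual z|.
#' @return Object of class `uvf_concordance`: list with `positions`
#'   (per-position tibble), `r`, `slope`, `intercept`, `baseline_r`,
#'   `baseline_mean`, `n_discordant`.
#' @export
concordance <- function(projected, actual, all_profiles = NULL,
                        n_random = 5L, seed = 1L, z_cut = 2.58) {
  d <- dplyr::inner_join(projected, actual, by = "position")
  if (nrow(d) < 5L) stop("need >= 5 positions", call. = FALSE)
  r <- if (stats::sd(d$projected) == 0 || stats::sd(d$actual) == 0) {
    NA_real_  # zero variance: correlation undefined
  } else {
    stats::cor(d$projected, d$actual)
  }
  fit <- stats::lm(actual ~ projected, data = d)
  res <- stats::residuals(fit)
  s <- stats::sd(res)
  d$residual <- unname(res)
  # an (numerically) exact fit has no meaningful residual scale
  tiny <- sqrt(.Machine$double.eps) * max(1, stats::sd(d$actual))
  d$residual_z <- if (s <= tiny) 0 else unname(res) / s
  d$discordant <- abs(d$residual_z) > z_cut
  baseline_r <- NULL
  baseline_mean <- NA_real_
  if (!is.null(all_profiles) && length(all_profiles) >= n_random) {
    set.seed(substream_seed(seed, "baseline"))
    pick <- sample(names(all_profiles), n_random)
    baseline_r <- vapply(pick, function(nm) {
      other <- dplyr::inner_join(projected, all_profiles[[nm]],
                                 by = "position")
      if (stats::sd(other$actual) == 0 ||
          stats::sd(other$projected) == 0) return(NA_real_)
      stats::cor(other$projected, other$actual)
    }, numeric(1))
    baseline_mean <- mean(baseline_r, na.rm = TRUE)
  }
  structure(list(positions = d, r = r,
                 slope = unname(stats::coef(fit))[2],
                 intercept = unname(stats::coef(fit))[1],
                 baseline_r = baseline_r, baseline_mean = baseline_mean,
                 n_discordant = sum(d$discordant)),
            class = "uvf_concordance")
}

#' @export
print.uvf_concordance <- function(x, ...) {
  cat("<uvf_concordance> r =", format(x$r, digits = 3),
      " slope =", format(x$slope, digits = 3),
      " discordant positions:", x$n_discordant, "\n")
  invisible(x)
}

#' Compare matched concordance to the randomized baseline across clusters
#'
#' Two-sided Mann-Whitney U test of the matched projected-vs-actual
#' correlations against the per-cluster randomized baseline means.
#'
#' @param results List of `uvf_concordance` objects.
#' @return One-row tibble `median_r`, `median_baseline`, `U`, `p`.
#' @export
concordance_group_test <- function(results) {
  r <- vapply(results, function(x) x$r, numeric(1))
  b <- vapply(results, function(x) x$baseline_mean, numeric(1))
  wt <- suppressWarnings(stats::wilcox.test(r, b, exact = FALSE))
  tibble::tibble(median_r = stats::median(r, na.rm = TRUE),
                 median_baseline = stats::median(b, na.rm = TRUE),
                 U = unname(wt$statistic), p = wt$p.value)
}
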
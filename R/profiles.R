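# Per-position damage profiles over binding-site windows and the
# enrichment/depletion tests (analytic Poisson and shuffle-null).

# full (position x strand) grid for a window half-width
.profile_grid <- function(window) {
  tidyr::expand_grid(position = seq(-window, window),
                     strand = c("motif", "complement"))
}

#' Observed per-position damage profile
#'
#' Sums lesion counts over all sites of a cluster per motif-relative
#' position and profile strand (motif / complement).  Minus-strand motif
#' sites are flipped into motif coordinates; a lesion's position is the
#' lower motif coordinate of its dipyrimidine (the "i/i+1" convention).
#'
#' @param sites A `uvf_sites` table.
#' @param map A `uvf_damage_map`.
#' @param window Window half-width (bp).
#' @return Tibble `position`, `strand`, `observed` covering the full
#'   grid.
#' @export
observed_profile <- function(sites, map, window = 40L) {
  grid <- .profile_grid(window)
  if (nrow(map) == 0L || nrow(sites) == 0L) {
    grid$observed <- 0
    return(grid)
  }
  mp <- map_to_motif_coords(sites, map$chrom, map$strand, map$pos5, window)
  agg <- tibble::tibble(position = mp$position,
                        strand = mp$profile_strand,
                        count = map$count[mp$locus]) |>
    dplyr::group_by(.data$position, .data$strand) |>
    dplyr::summarise(observed = sum(.data$count), .groups = "drop")
  out <- dplyr::left_join(grid, agg, by = c("position", "strand"))
  out$observed <- dplyr::coalesce(out$observed, 0)
  out
}

#' Expected per-position damage profile under the Poisson model
#'
#' The expectation at a cell is the sum over sites of the context rate at
#' that site/position/strand (sum of independent Poissons).  Positions
#' whose site sequence is not a dipyrimidine, or whose context is
#' unavailable, contribute 0; encountering an uncovered k-mer contributes
#' 0 and is logged.
#'
#' @param sites A `uvf_sites` table.
#' @param genome A `uvf_genome`.
#' @param rate_table A `uvf_rate_table` (see [estimate_context_rates()]).
#' @param window Window half-width (bp).
#' @return Tibble `position`, `strand`, `expected`, `n_sites`
#'   (contributing sites).
#' @export
expected_profile <- function(sites, genome, rate_table, window = 40L) {
  k_flank <- attr(rate_table, "k_flank")
  rate <- .rate_lookup(rate_table)
  uncov <- rep(FALSE, length(rate))
  uncov[rate_table$ctx[!rate_table$covered] + 1L] <- TRUE
  grid <- .profile_grid(window)
  grid$expected <- 0
  grid$n_sites <- 0L
  if (nrow(sites) == 0L) return(grid)
  centers <- site_center(sites)
  plus <- sites$strand == "+"
  n_uncov <- 0L
  for (chr in unique(sites$chrom)) {
    in_chr <- sites$chrom == chr
    code <- .encode_seq(unclass(genome)[[chr]])
    tr <- .kmer_tracks(code, k_flank)
    chr_len <- length(code)
    for (row in seq_len(nrow(grid))) {
      p <- grid$position[row]
      ps <- grid$strand[row]
      lo <- ifelse(plus, centers + p, centers - p - 1)[in_chr]
      damaged_plus <- xor(!plus[in_chr], ps == "motif")
      i <- lo + 1L
      i[i < 1L | i > chr_len] <- NA_integer_
      ok <- ifelse(damaged_plus, tr$plus_ok[i], tr$minus_ok[i])
      ctx <- ifelse(damaged_plus, tr$plus[i], tr$minus[i])
      use <- !is.na(ok) & ok & !is.na(ctx)
      ctx_use <- as.integer(round(ctx[use]))
      n_uncov <- n_uncov + sum(uncov[ctx_use + 1L])
      grid$expected[row] <- grid$expected[row] + sum(rate[ctx_use + 1L])
      grid$n_sites[row] <- grid$n_sites[row] + sum(use)
    }
  }
  if (n_uncov > 0) {
    uvf_inform(paste0("expected_profile: ", n_uncov,
                      " site-position(s) hit uncovered k-mers ",
                      "(contribute 0)"))
  }
  grid
}

# side assignment: split at the motif center, center column to the left
.side_of <- function(position) ifelse(position <= 0, "left", "right")

#' Scale the expected profile to flanking signal
#'
#' Multiplies the model expectation by the mean observed/expected ratio in
#' the flanking positions outside the binding-site span (motif +/-
#' `span_pad`), separately per profile strand and motif half, so local
#' covariates shared by a cluster's sites (chromatin, co-factors) do not
#' masquerade as binding effects.  Positions with expected 0 are skipped
#' in the factor; a strand-half with no usable flank position gets factor
#' 1 with a warning.
#'
#' @param observed,expected Profiles from [observed_profile()] /
#'   [expected_profile()] (same window).
#' @param motif_len Motif length of the cluster.
#' @param span_pad Binding-site span padding (bp beyond the motif).
#' @return Joined profile with `side`, `scale_factor` and
#'   `expected_scaled` columns.
#' @export
flank_scale <- function(observed, expected, motif_len, span_pad = 5L) {
  prof <- dplyr::inner_join(observed, expected,
                            by = c("position", "strand"))
  span_lo <- -floor(motif_len / 2) - span_pad
  span_hi <- motif_len - 1 - floor(motif_len / 2) + span_pad
  prof$side <- .side_of(prof$position)
  is_flank <- prof$position < span_lo | prof$position > span_hi
  factors <- prof[is_flank & prof$expected > 0, , drop = FALSE] |>
    dplyr::group_by(.data$strand, .data$side) |>
    dplyr::summarise(scale_factor =
                       mean(.data$observed / .data$expected),
                     .groups = "drop")
  full <- tidyr::expand_grid(strand = c("motif", "complement"),
                             side = c("left", "right"))
  factors <- dplyr::left_join(full, factors, by = c("strand", "side"))
  if (anyNA(factors$scale_factor)) {
    warning("flank_scale: no usable flank positions for some ",
            "strand-half; factor set to 1", call. = FALSE)
    factors$scale_factor[is.na(factors$scale_factor)] <- 1
  }
  prof <- dplyr::left_join(prof, factors, by = c("strand", "side"))
  prof$expected_scaled <- prof$expected * prof$scale_factor
  prof
}

#' One-sided Poisson enrichment/depletion test per position
#'
#' For each (position, strand) cell compares the observed count `X` to the
#' (scaled) expectation `lambda`: direction is the sign of `X - lambda`,
#' `z = (X - lambda) / sqrt(lambda)`, and the one-sided p-value is
#' `P(Poisson(lambda) >= X)` for enrichment or `P(<= X)` for depletion
#' (inclusive tails; anti-conservative at the `X = lambda` boundary since
#' the direction is chosen from the data).  Benjamini-Hochberg correction
#' is applied jointly over all cells of the window; cells with
#' `lambda = 0` and `X > 0` are flagged `model_gap` and excluded from the
#' correction.
#'
#' @param profile Profile tibble with `observed` and `expected_scaled`
#'   (or `expected`) columns, e.g. from [flank_scale()].
#' @param threshold Significance threshold on the BH-adjusted q-value
#'   (0.05 for CPD, 0.01 for 6-4 PP analyses).
#' @return The profile with `z`, `p`, `q`, `direction`, `significant`
#'   and `flag` columns; class `uvf_profile_test`.
#' @export
poisson_position_test <- function(profile, threshold = 0.05) {
  lam <- profile$expected_scaled %||% profile$expected
  if (is.null(lam)) stop("profile needs an expected column", call. = FALSE)
  x <- profile$observed
  out <- tibble::as_tibble(profile)
  out$z <- ifelse(lam > 0, (x - lam) / sqrt(lam), NA_real_)
  out$direction <- dplyr::case_when(
    lam > 0 & x > lam ~ "enriched",
    lam > 0 & x < lam ~ "depleted",
    TRUE ~ "none")
  out$p <- dplyr::case_when(
    out$direction == "enriched" ~ stats::ppois(x - 1, lam,
                                               lower.tail = FALSE),
    out$direction == "depleted" ~ stats::ppois(x, lam),
    TRUE ~ 1)
  out$flag <- ifelse(lam == 0 & x > 0, "model_gap", "ok")
  testable <- out$flag == "ok" & lam > 0
  out$q <- NA_real_
  out$q[testable] <- stats::p.adjust(out$p[testable], method = "BH")
  out$significant <- !is.na(out$q) & out$q < threshold &
    out$direction != "none"
  structure(out, class = c("uvf_profile_test", class(tibble::tibble())),
            threshold = threshold, test = "poisson")
}

#' Shuffle-null enrichment test preserving tetranucleotide context
#'
#' Builds an orthogonal null by reassigning every damage record (with its
#' count) to a uniformly drawn locus of the same NYYN class within the
#' background regions, and compares the observed per-cell counts to the
#' null ensemble: `z = (obs - mean) / sd` and the empirical one-sided
#' p-value is `(1 + #{null >= obs}) / (n_iter + 1)` for enrichment
#' (`<=` for depletion).  Classes with a single locus keep their damage in
#' place (logged).  BH correction as in [poisson_position_test()].
#'
#' The resampling is realised exactly but efficiently: destinations of the
#' records of one class are multinomial over that class's loci, so the
#' per-iteration window-cell counts are drawn with [stats::rmultinom()]
#' over (cells + elsewhere) rather than per record.
#'
#' @param map A `uvf_damage_map`.
#' @param regions Background interval table the shuffle lives in.
#' @param genome A `uvf_genome`.
#' @param sites A `uvf_sites` table.
#' @param window Window half-width.
#' @param n_iter Number of shuffle iterations (>= 1000 recommended).
#' @param seed Integer seed.
#' @param threshold Significance threshold on q.
#' @return A `uvf_profile_test` tibble with `observed`, `null_mean`,
#'   `null_sd`, `z`, `p`, `q`, `direction`, `significant`.
#' @export
shuffle_null_test <- function(map, regions, genome, sites, window = 40L,
                              n_iter = 1000L, seed = 1L,
                              threshold = 0.05) {
  loci <- enumerate_dipyrimidine_loci(genome, regions, k_flank = 1L)
  loci <- loci[!is.na(loci$ctx), , drop = FALSE]
  # destination cell of each locus (0 = outside all windows)
  mp <- map_to_motif_coords(sites, loci$chrom, loci$strand, loci$pos5,
                            window)
  grid <- .profile_grid(window)
  cell_of <- function(position, strand) {
    match(paste(position, strand), paste(grid$position, grid$strand))
  }
  dest <- rep(0L, nrow(loci))
  if (nrow(mp)) {
    first <- !duplicated(mp$locus)
    if (any(!first)) {
      uvf_inform(paste0("shuffle_null_test: overlapping site windows; ",
                        "each locus is assigned to its first window"))
    }
    mp <- mp[first, , drop = FALSE]
    dest[mp$locus] <- cell_of(mp$position, mp$profile_strand)
  }
  inmap <- filter_to_regions(map, regions)
  key <- paste(loci$chrom, loci$strand, loci$pos5)
  rec_idx <- match(paste(inmap$chrom, inmap$strand, inmap$pos5), key)
  if (anyNA(rec_idx)) {
    uvf_inform(paste0("shuffle_null_test: ", sum(is.na(rec_idx)),
                      " record(s) without classified locus skipped"))
  }
  rec <- tibble::tibble(cls = loci$ctx[rec_idx[!is.na(rec_idx)]],
                        count = inmap$count[!is.na(rec_idx)])
  n_cells <- nrow(grid)
  null <- matrix(0, n_cells, n_iter)
  set.seed(substream_seed(seed, "shuffle"))
  singletons <- 0L
  for (cls in sort(unique(rec$cls))) {
    in_cls <- which(loci$ctx == cls)
    if (length(in_cls) == 1L) singletons <- singletons + 1L
    prob <- tabulate(dest[in_cls] + 1L, nbins = n_cells + 1L)
    prob <- prob / sum(prob)
    sub <- rec[rec$cls == cls, , drop = FALSE]
    for (v in sort(unique(sub$count))) {
      n_v <- sum(sub$count == v)
      draws <- stats::rmultinom(n_iter, n_v, prob)
      null <- null + v * draws[-1L, , drop = FALSE]
    }
  }
  if (singletons > 0) {
    uvf_inform(paste0("shuffle_null_test: ", singletons,
                      " singleton class(es); their damages stay put"))
  }
  obs_prof <- observed_profile(sites, inmap, window)
  out <- dplyr::left_join(grid, obs_prof, by = c("position", "strand"))
  out$null_mean <- rowMeans(null)
  out$null_sd <- apply(null, 1L, stats::sd)
  out$z <- ifelse(out$null_sd > 0,
                  (out$observed - out$null_mean) / out$null_sd, NA_real_)
  out$direction <- dplyr::case_when(
    out$observed > out$null_mean ~ "enriched",
    out$observed < out$null_mean ~ "depleted",
    TRUE ~ "none")
  ge <- rowSums(null >= out$observed)
  le <- rowSums(null <= out$observed)
  out$p <- ifelse(out$direction == "depleted",
                  (1 + le) / (n_iter + 1), (1 + ge) / (n_iter + 1))
  testable <- out$null_sd > 0 | out$observed > 0
  out$q <- NA_real_
  out$q[testable] <- stats::p.adjust(out$p[testable], method = "BH")
  out$significant <- !is.na(out$q) & out$q < threshold &
    out$direction != "none"
  structure(out, class = c("uvf_profile_test", class(tibble::tibble())),
            threshold = threshold, test = "shuffle", n_iter = n_iter,
            null_matrix = null)
}

#' Demote calls that replicate in naked DNA
#'
#' Positions significant in the cellular profile that are also significant
#' at the same position and strand, in the same direction, in the naked
#' DNA profile reflect sequence-intrinsic photoreactivity rather than TF
#' binding; they are demoted (retained with label `sequence-intrinsic`,
#' `significant` set to `FALSE`).  Same-cell significance in the opposite
#' direction is kept but flagged.
#'
#' @param cell_profile,naked_profile `uvf_profile_test` tibbles on the
#'   same cluster and window.
#' @return `cell_profile` with a `label` column and demotions applied.
#' @export
naked_dna_filter <- function(cell_profile, naked_profile) {
  nk <- tibble::as_tibble(naked_profile)[
    , c("position", "strand", "direction", "significant")]
  names(nk) <- c("position", "strand", "naked_direction",
                 "naked_significant")
  out <- dplyr::left_join(tibble::as_tibble(cell_profile), nk,
                          by = c("position", "strand"))
  out$naked_significant <- dplyr::coalesce(out$naked_significant, FALSE)
  both <- out$significant & out$naked_significant
  same_dir <- both & out$direction == out$naked_direction
  out$label <- dplyr::case_when(
    same_dir ~ "sequence-intrinsic",
    both ~ "opposite-in-naked",
    out$significant ~ "significant",
    TRUE ~ "ns")
  out$significant[same_dir] <- FALSE
  .keep_attrs(out[, setdiff(names(out),
                            c("naked_direction", "naked_significant"))],
              cell_profile)
}

#' Signed maximum-|z| position summary across clusters
#'
#' For heatmap-style reporting: per cluster and position, the z-score with
#' the largest magnitude across the two strands (sign retained).
#'
#' @param tests Named list of `uvf_profile_test` tibbles.
#' @return Tibble `cluster`, `position`, `z`.
#' @export
signed_z_matrix <- function(tests) {
  purrr::imap_dfr(tests, function(tt, nm) {
    tibble::as_tibble(tt) |>
      dplyr::filter(!is.na(.data$z)) |>
      dplyr::group_by(.data$position) |>
      dplyr::summarise(z = .data$z[which.max(abs(.data$z))],
                       .groups = "drop") |>
      dplyr::mutate(cluster = nm, .before = 1)
  })
}
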
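#' Context-dependent damage rate tables
#'
#' Damage formation is modelled as a Poisson process whose rate depends on
#' the sequence context of the central dipyrimidine.  A rate table holds,
#' per pyrimidine-centered k-mer (64 NYYN or 1,024 NNYYNN), the number of
#' occurrences in a background region set, the number of damages observed
#' at those occurrences, and the per-occurrence rate `damages /
#' occurrences`.  K-mers with no occurrence are flagged uncovered, never
#' silently zero.
#'
#' @name context_rates
NULL

#' Count pyrimidine-centered k-mer occurrences in regions
#'
#' Both strands are counted; windows whose context contains N or crosses a
#' chromosome boundary are skipped (and reported).  Flanks may extend past
#' the region edge: an occurrence is counted wherever the central
#' dipyrimidine lies inside the regions.
#'
#' @inheritParams enumerate_dipyrimidine_loci
#' @param loci Optional precomputed locus table (performance cache).
#' @return Tibble `kmer`, `ctx`, `occurrences` covering all pyrimidine-
#'   centered k-mers of the width (zero-occurrence k-mers included).
#' @export
count_context_occurrences <- function(genome, regions, k_flank = 2L,
                                      loci = NULL) {
  if (is.null(loci)) {
    loci <- enumerate_dipyrimidine_loci(genome, regions, k_flank)
  }
  n_na <- sum(is.na(loci$ctx))
  if (n_na > 0) {
    uvf_inform(paste0("count_context_occurrences: ", n_na,
                      " locus/loci with unavailable context skipped"))
  }
  all_k <- all_pyrimidine_kmers(k_flank)
  tab <- tabulate(loci$ctx[!is.na(loci$ctx)] + 1L, nbins = 4^(2 * k_flank + 2))
  idx <- kmer_to_index(all_k)
  tibble::tibble(kmer = all_k, ctx = idx, occurrences = tab[idx + 1L])
}

#' Estimate per-context damage rates over a background region set
#'
#' The damage map is restricted to the regions first; rates are
#' `damages / occurrences` per k-mer.  Damages at loci whose context is
#' unavailable (N or chromosome edge) are excluded with a logged count, so
#' the table's total damages equal the mapped damages in the regions minus
#' the logged exclusions.
#'
#' @param map A `uvf_damage_map`.
#' @param genome A `uvf_genome`.
#' @param regions Background interval table (typically accessible,
#'   intergenic regions).
#' @param k_flank Context flank width (2 for formation models).
#' @param region_id Label recorded in the table metadata.
#' @param loci Optional precomputed locus table (performance cache).
#' @return Tibble of class `uvf_rate_table` with columns `kmer`, `ctx`,
#'   `occurrences`, `damages`, `rate`, `covered`.
#' @export
estimate_context_rates <- function(map, genome, regions, k_flank = 2L,
                                   region_id = "background",
                                   loci = NULL) {
  occ <- count_context_occurrences(genome, regions, k_flank, loci = loci)
  inmap <- filter_to_regions(map, regions)
  if (nrow(inmap)) {
    ctx <- extract_context(genome, inmap$chrom, inmap$strand, inmap$pos5,
                           k_flank = k_flank)
    keep <- !is.na(ctx)
    n_excl <- sum(inmap$count[!keep])
    if (n_excl > 0) {
      uvf_inform(paste0("estimate_context_rates: excluded ", n_excl,
                        " damage(s) with unavailable context"))
    }
    dmg <- tibble::tibble(ctx = kmer_to_index(ctx[keep]),
                          count = inmap$count[keep]) |>
      dplyr::group_by(.data$ctx) |>
      dplyr::summarise(damages = sum(.data$count), .groups = "drop")
  } else {
    dmg <- tibble::tibble(ctx = integer(0), damages = numeric(0))
  }
  out <- occ |>
    dplyr::left_join(dmg, by = "ctx") |>
    dplyr::mutate(damages = dplyr::coalesce(.data$damages, 0),
                  covered = .data$occurrences > 0,
                  rate = dplyr::if_else(.data$covered,
                                        .data$damages / .data$occurrences,
                                        NA_real_))
  out <- out[, c("kmer", "ctx", "occurrences", "damages", "rate", "covered")]
  structure(out, class = c("uvf_rate_table", class(tibble::tibble())),
            lesion_type = attr(map, "lesion_type"),
            timepoint = attr(map, "timepoint"),
            k_flank = as.integer(k_flank), region_id = region_id)
}

# dense rate lookup vector indexed by ctx + 1; uncovered/invalid -> 0
.rate_lookup <- function(rate_table) {
  k_flank <- attr(rate_table, "k_flank")
  v <- numeric(4^(2 * k_flank + 2))
  r <- rate_table$rate
  r[is.na(r)] <- 0
  v[rate_table$ctx + 1L] <- r
  v
}

#' Serialize a rate table as TSV
#' @param rate_table A `uvf_rate_table`.
#' @param path File path.
#' @export
write_rate_table <- function(rate_table, path) {
  readr::write_tsv(tibble::as_tibble(rate_table)[
    , c("kmer", "occurrences", "damages", "rate")], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_rate_table
#' @param k_flank Context flank width of the stored table.
#' @param lesion_type,timepoint,region_id Metadata to attach.
#' @export
read_rate_table <- function(path, k_flank = 2L, lesion_type = "CPD",
                            timepoint = "0h", region_id = "background") {
  df <- readr::read_tsv(path, col_types = "cddd", progress = FALSE)
  out <- tibble::tibble(kmer = df$kmer, ctx = kmer_to_index(df$kmer),
                        occurrences = df$occurrences,
                        damages = df$damages, rate = df$rate,
                        covered = df$occurrences > 0)
  structure(out, class = c("uvf_rate_table", class(tibble::tibble())),
            lesion_type = lesion_type, timepoint = timepoint,
            k_flank = as.integer(k_flank), region_id = region_id)
}

#' Kolmogorov-Smirnov check of the per-locus Poisson model
#'
#' Compares the empirical distribution of per-locus counts for one k-mer
#' (zero-count loci reconstructed from the occurrence enumeration, since
#' damage files omit zeros) to a Poisson with that k-mer's estimated rate.
#' The KS test is formally for continuous distributions; with discrete
#' counts the p-value is conservative, which is logged.
#'
#' @param map A `uvf_damage_map` (restricted to `regions` internally).
#' @param genome,regions Background definition as in
#'   [estimate_context_rates()].
#' @param kmer Single context string (width fixes `k_flank`).
#' @param min_loci Minimum loci required; fewer returns an
#'   "insufficient" status with `NA` statistics.
#' @return One-row tibble: `kmer`, `n_loci`, `rate`, `statistic`, `p`,
#'   `status`.
#' @export
ks_poisson_check <- function(map, genome, regions, kmer, min_loci = 100L) {
  k_flank <- (nchar(kmer) - 2L) %/% 2L
  stopifnot(k_flank %in% c(1L, 2L))
  target <- kmer_to_index(kmer)
  loci <- enumerate_dipyrimidine_loci(genome, regions, k_flank)
  loci <- loci[!is.na(loci$ctx) & loci$ctx == target, , drop = FALSE]
  if (nrow(loci) < min_loci) {
    return(tibble::tibble(kmer = kmer, n_loci = nrow(loci), rate = NA_real_,
                          statistic = NA_real_, p = NA_real_,
                          status = "insufficient"))
  }
  inmap <- filter_to_regions(map, regions)
  counts <- rep(0, nrow(loci))
  if (nrow(inmap)) {
    m <- dplyr::left_join(loci, tibble::as_tibble(inmap),
                          by = c("chrom", "strand", "pos5"))
    counts <- dplyr::coalesce(m$count, 0)
  }
  lambda <- mean(counts)
  uvf_inform("ks_poisson_check: discrete counts; KS p is conservative")
  # atom-wise discrete KS: both CDFs evaluated right-continuously at the
  # integer support (the continuous-sample formula degenerates at the
  # zero atom); Kolmogorov asymptotic p, conservative for discrete data
  grid <- 0:max(max(counts), ceiling(lambda + 10 * sqrt(lambda) + 10))
  Fn <- vapply(grid, function(k) mean(counts <= k), numeric(1))
  D <- max(abs(Fn - stats::ppois(grid, lambda)))
  t <- sqrt(length(counts)) * D
  k <- 1:100
  p <- min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
  tibble::tibble(kmer = kmer, n_loci = nrow(loci), rate = lambda,
                 statistic = D, p = p, status = "ok")
}

#' Kruskal-Wallis QC of flanking-base effects on rates
#'
#' For each dinucleotide class and each flank offset, tests whether the
#' per-k-mer rates differ by the base at that offset (standard
#' [stats::kruskal.test()] over the rate-table rows).
#'
#' @param rate_table A `uvf_rate_table`.
#' @return Tibble `dinuc`, `flank_offset`, `statistic`, `p`.
#' @export
flank_rate_qc <- function(rate_table) {
  k_flank <- attr(rate_table, "k_flank")
  tab <- tibble::as_tibble(rate_table)
  tab <- tab[tab$covered & !is.na(tab$rate), , drop = FALSE]
  tab$dinuc <- substr(tab$kmer, k_flank + 1, k_flank + 2)
  offs <- c(-(k_flank:1), seq_len(k_flank))
  res <- list()
  for (dn in sort(unique(tab$dinuc))) {
    sub <- tab[tab$dinuc == dn, , drop = FALSE]
    for (o in offs) {
      chpos <- if (o < 0) k_flank + 1 + o else k_flank + 2 + o
      g <- substr(sub$kmer, chpos, chpos)
      if (length(unique(g)) < 2) next
      kw <- stats::kruskal.test(sub$rate, factor(g))
      res[[length(res) + 1L]] <- tibble::tibble(
        dinuc = dn, flank_offset = o,
        statistic = unname(kw$statistic), p = kw$p.value)
    }
  }
  dplyr::bind_rows(res)
}
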
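# Context-dependent CPD repair efficiency and the bootstrap test for
# positions retaining significantly elevated unrepaired lesions.

#' Per-context repair efficiency between two timepoints
#'
#' For each tetranucleotide (NYYN) context, tallies damages at the initial
#' and later timepoint over the background regions (genic regions should
#' already have been subtracted to avoid transcription-coupled repair
#' confounding) and computes survival `s = t / 0h` (after applying the
#' optional library normalization) and efficiency `1 - s`.  Contexts
#' below the 0h-count floor are flagged `insufficient` and carry no
#' ratio.
#'
#' @param map0h,mapT `uvf_damage_map`s at the two timepoints.
#' @param genome A `uvf_genome`.
#' @param regions Background interval table (accessible, intergenic).
#' @param norm_factor Scalar multiplier applied to the later timepoint's
#'   counts (library-depth normalization; 1 = pre-normalized inputs).
#' @param min_0h Minimum 0h damages for a context to be usable.
#' @return Tibble of class `uvf_repair_table`: `kmer`, `ctx`,
#'   `damages_0h`, `damages_t`, `survival`, `efficiency`, `status`.
#' @export
repair_efficiency_by_context <- function(map0h, mapT, genome, regions,
                                         norm_factor = 1, min_0h = 50L) {
  tally <- function(map) {
    m <- filter_to_regions(map, regions)
    if (nrow(m) == 0L) {
      return(tibble::tibble(ctx = integer(0), n = numeric(0)))
    }
    ctx <- extract_context(genome, m$chrom, m$strand, m$pos5, k_flank = 1L)
    keep <- !is.na(ctx)
    tibble::tibble(ctx = kmer_to_index(ctx[keep]), count = m$count[keep]) |>
      dplyr::group_by(.data$ctx) |>
      dplyr::summarise(n = sum(.data$count), .groups = "drop")
  }
  t0 <- tally(map0h)
  t1 <- tally(mapT)
  kmers <- all_pyrimidine_kmers(1L)
  out <- tibble::tibble(kmer = kmers, ctx = kmer_to_index(kmers)) |>
    dplyr::left_join(t0, by = "ctx") |>
    dplyr::rename(damages_0h = "n") |>
    dplyr::left_join(t1, by = "ctx") |>
    dplyr::rename(damages_t = "n") |>
    dplyr::mutate(damages_0h = dplyr::coalesce(.data$damages_0h, 0),
                  damages_t = dplyr::coalesce(.data$damages_t, 0) *
                    norm_factor,
                  status = dplyr::if_else(.data$damages_0h >= min_0h,
                                          "ok", "insufficient"),
                  survival = dplyr::if_else(.data$status == "ok",
                                            .data$damages_t /
                                              .data$damages_0h,
                                            NA_real_),
                  efficiency = 1 - .data$survival)
  structure(out, class = c("uvf_repair_table", class(tibble::tibble())),
            norm_factor = norm_factor, min_0h = min_0h,
            timepoints = c(attr(map0h, "timepoint"),
                           attr(mapT, "timepoint")))
}

# per-cell NYYN composition (0h counts) and observed remaining counts
.repair_cell_data <- function(sites, map0h, mapT, genome, window) {
  cellify <- function(map) {
    m <- map
    if (nrow(m) == 0L) {
      return(tibble::tibble(position = numeric(0), strand = character(0),
                            ctx = integer(0), count = numeric(0)))
    }
    ctx <- extract_context(genome, m$chrom, m$strand, m$pos5, k_flank = 1L)
    mp <- map_to_motif_coords(sites, m$chrom, m$strand, m$pos5, window)
    tibble::tibble(position = mp$position, strand = mp$profile_strand,
                   ctx = kmer_to_index(ctx[mp$locus]),
                   count = m$count[mp$locus])
  }
  list(t0 = cellify(map0h), t1 = cellify(mapT))
}

#' Bootstrap test for elevated unrepaired lesions at binding sites
#'
#' For each (position, strand) cell of the window, the initial damage
#' burden is decomposed into per-NYYN counts `n_c`; a bootstrap draw of
#' the expected remaining count is `sum_c Binomial(n_c, s_c)` with `s_c`
#' the background survival of context `c` — i.e. the null is conditioned
#' on both the initial amount of damage and its NYYN composition.  The
#' null is then flank-scaled exactly as in the formation analysis (mean
#' observed-remaining / bootstrap-mean ratio over flank positions, per
#' strand and motif half).  The empirical one-sided p-value for elevated
#' remaining damage is `(1 + #{draw >= obs}) / (n_boot + 1)`; BH
#' correction is applied across the window.
#'
#' An alternative locus-resampling kernel (draw background loci of the
#' class weighted by initial counts and take their observed later-time
#' survival) is available for sensitivity analysis.
#'
#' @param sites A `uvf_sites` table.
#' @param map0h,mapT Damage maps at the two timepoints.
#' @param genome A `uvf_genome`.
#' @param regions Background regions for the survival table.
#' @param window Window half-width (30 bp by default for repair).
#' @param n_boot Bootstrap draws per cell.
#' @param seed Integer seed.
#' @param threshold Significance threshold on q.
#' @param norm_factor Library normalization (see
#'   [repair_efficiency_by_context()]).
#' @param kernel `"binomial"` (default) or `"locus"` resampling.
#' @param span_pad Binding-site span padding for the flank definition.
#' @param min_0h Context floor passed to the survival table.
#' @return Tibble of class `uvf_repair_test`: per cell the observed
#'   remaining count, initial count, bootstrap mean/sd, scale factor,
#'   `z`, `p`, `q`, `significant`, and the NYYN composition as a
#'   list-column.
#' @export
bootstrap_unrepaired_test <- function(sites, map0h, mapT, genome, regions,
                                      window = 30L, n_boot = 10000L,
                                      seed = 1L, threshold = 0.05,
                                      norm_factor = 1,
                                      kernel = c("binomial", "locus"),
                                      span_pad = 5L, min_0h = 50L) {
  kernel <- match.arg(kernel)
  eff <- repair_efficiency_by_context(map0h, mapT, genome, regions,
                                      norm_factor = norm_factor,
                                      min_0h = min_0h)
  surv <- rep(NA_real_, 256L)
  surv[eff$ctx + 1L] <- eff$survival
  cells <- .repair_cell_data(sites, map0h, mapT, genome, window)
  grid <- .profile_grid(window)
  comp0 <- cells$t0 |>
    dplyr::group_by(.data$position, .data$strand, .data$ctx) |>
    dplyr::summarise(n = sum(.data$count), .groups = "drop")
  obs_t <- cells$t1 |>
    dplyr::group_by(.data$position, .data$strand) |>
    dplyr::summarise(obs = sum(.data$count) * norm_factor,
                     .groups = "drop")
  # background per-locus survival pool for the locus-resampling kernel
  pool <- NULL
  if (kernel == "locus") {
    bg0 <- filter_to_regions(map0h, regions)
    bg1 <- filter_to_regions(mapT, regions)
    ctx0 <- extract_context(genome, bg0$chrom, bg0$strand, bg0$pos5, 1L)
    m1 <- dplyr::left_join(
      tibble::tibble(chrom = bg0$chrom, strand = bg0$strand,
                     pos5 = bg0$pos5, ctx = kmer_to_index(ctx0),
                     n0 = bg0$count),
      tibble::tibble(chrom = bg1$chrom, strand = bg1$strand,
                     pos5 = bg1$pos5, nt = bg1$count),
      by = c("chrom", "strand", "pos5"))
    m1$nt <- dplyr::coalesce(m1$nt, 0)
    pool <- m1[!is.na(m1$ctx), , drop = FALSE]
  }
  set.seed(substream_seed(seed, "bootstrap"))
  res <- grid
  res$n0h <- 0
  res$observed <- 0
  res$boot_mean <- NA_real_
  res$boot_sd <- NA_real_
  res$composition <- vector("list", nrow(grid))
  draws_mat <- matrix(NA_real_, nrow(grid), n_boot)
  n_excluded <- 0L
  for (i in seq_len(nrow(grid))) {
    cc <- comp0[comp0$position == grid$position[i] &
                  comp0$strand == grid$strand[i], , drop = FALSE]
    comp <- stats::setNames(cc$n, index_to_kmer(cc$ctx, 4L))
    res$composition[[i]] <- comp
    res$n0h[i] <- sum(cc$n)
    o <- obs_t$obs[obs_t$position == grid$position[i] &
                     obs_t$strand == grid$strand[i]]
    res$observed[i] <- if (length(o)) o else 0
    if (nrow(cc) == 0L) next
    s_c <- surv[cc$ctx + 1L]
    if (anyNA(s_c)) {
      n_excluded <- n_excluded + 1L
      next  # context without usable background survival: cell excluded
    }
    if (kernel == "binomial") {
      draws <- numeric(n_boot)
      for (j in seq_len(nrow(cc))) {
        draws <- draws + stats::rbinom(n_boot, cc$n[j], s_c[j])
      }
    } else {
      draws <- numeric(n_boot)
      for (j in seq_len(nrow(cc))) {
        pj <- pool[pool$ctx == cc$ctx[j], , drop = FALSE]
        if (nrow(pj) == 0L) next
        li <- sample.int(nrow(pj), cc$n[j] * n_boot, replace = TRUE,
                         prob = pj$n0)
        pr <- pmin(pj$nt[li] / pj$n0[li], 1)
        draws <- draws + colSums(matrix(stats::rbinom(length(li), 1L, pr),
                                        nrow = cc$n[j]))
      }
    }
    draws_mat[i, ] <- draws
    res$boot_mean[i] <- mean(draws)
    res$boot_sd[i] <- stats::sd(draws)
  }
  if (n_excluded > 0) {
    uvf_inform(paste0("bootstrap_unrepaired_test: ", n_excluded,
                      " cell(s) excluded for insufficient background ",
                      "survival"))
  }
  # flank scaling of the null, per strand and motif half
  motif_len <- motif_length(sites)
  span_lo <- -floor(motif_len / 2) - span_pad
  span_hi <- motif_len - 1 - floor(motif_len / 2) + span_pad
  res$side <- .side_of(res$position)
  is_flank <- (res$position < span_lo | res$position > span_hi) &
    !is.na(res$boot_mean) & res$boot_mean > 0
  fac <- res[is_flank, , drop = FALSE] |>
    dplyr::group_by(.data$strand, .data$side) |>
    dplyr::summarise(scale_factor = mean(.data$observed / .data$boot_mean),
                     .groups = "drop")
  full <- tidyr::expand_grid(strand = c("motif", "complement"),
                             side = c("left", "right"))
  fac <- dplyr::left_join(full, fac, by = c("strand", "side"))
  if (anyNA(fac$scale_factor)) {
    warning("bootstrap_unrepaired_test: no usable flank cells for some ",
            "strand-half; factor set to 1", call. = FALSE)
    fac$scale_factor[is.na(fac$scale_factor)] <- 1
  }
  res <- dplyr::left_join(res, fac, by = c("strand", "side"))
  res$null_mean <- res$boot_mean * res$scale_factor
  res$null_sd <- res$boot_sd * res$scale_factor
  res$z <- dplyr::case_when(
    !is.na(res$null_sd) & res$null_sd > 0 ~
      (res$observed - res$null_mean) / res$null_sd,
    # degenerate no-repair null: all draws equal the observed burden
    !is.na(res$null_sd) & res$observed == res$null_mean ~ 0,
    TRUE ~ NA_real_)
  res$p <- NA_real_
  for (i in seq_len(nrow(res))) {
    if (is.na(res$boot_mean[i])) next
    scaled <- draws_mat[i, ] * res$scale_factor[i]
    res$p[i] <- (1 + sum(scaled >= res$observed[i])) / (n_boot + 1)
  }
  testable <- !is.na(res$p)
  res$q <- NA_real_
  res$q[testable] <- stats::p.adjust(res$p[testable], method = "BH")
  res$significant <- !is.na(res$q) & res$q < threshold
  structure(res, class = c("uvf_repair_test", class(tibble::tibble())),
            threshold = threshold, n_boot = n_boot, kernel = kernel)
}

#' Compare repair efficiency of a position's contexts to the background
#'
#' Two-sided Mann-Whitney U test of per-context repair efficiencies: the
#' contexts present at a position (each context's efficiency replicated
#' by its count in the composition vector, i.e. position-weighted)
#' against all usable NYYN efficiencies.
#'
#' @param composition Named NYYN -> count vector (e.g. from
#'   [bootstrap_unrepaired_test()]'s `composition` column).
#' @param table A `uvf_repair_table`.
#' @return One-row tibble `U`, `p`, `n_position`, `n_background`.
#' @export
context_efficiency_comparison <- function(composition, table) {
  ok <- table$status == "ok" & !is.na(table$efficiency)
  all_eff <- table$efficiency[ok]
  eff_of <- stats::setNames(table$efficiency, table$kmer)
  pos_ctx <- names(composition)[names(composition) %in%
                                  table$kmer[ok]]
  pos_eff <- rep(unname(eff_of[pos_ctx]),
                 unname(composition[pos_ctx]))
  if (length(unique(pos_ctx)) < 3 || length(all_eff) < 3) {
    stop("need at least 3 contexts in each group", call. = FALSE)
  }
  if (length(unique(c(pos_eff, all_eff))) == 1L) {
    return(tibble::tibble(U = length(pos_eff) * length(all_eff) / 2,
                          p = 1, n_position = length(pos_eff),
                          n_background = length(all_eff)))
  }
  wt <- suppressWarnings(stats::wilcox.test(pos_eff, all_eff,
                                            exact = FALSE))
  tibble::tibble(U = unname(wt$statistic), p = wt$p.value,
                 n_position = length(pos_eff),
                 n_background = length(all_eff))
}
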
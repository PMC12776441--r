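# Site curation, observed/expected profiles, flank scaling, and the
# per-position tests.

test_that("PWM log-odds scoring matches hand calculations", {
  # deterministic PWM matching its consensus, uniform background
  pwm <- uvfootprint:::.as_pwm("GGAA")
  expect_equal(pwm_log_odds_score(pwm, "GGAA"), 8)  # 2 bits x length
  # a column equal to the background contributes 0
  pwm2 <- matrix(c(0.25, 0.25, 0.25, 0.25, 1, 0, 0, 0), 4, 2,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(pwm_log_odds_score(pwm2, "CA"), 2)
  expect_equal(pwm_log_odds_score(pwm2, "GA"), 2)
  # hand example: cols {A:.5, C:.5}, {G:1} on "AG" -> 1 + 2 = 3 bits
  pwm3 <- matrix(c(0.5, 0.5, 0, 0, 0, 0, 1, 0), 4, 2,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(pwm_log_odds_score(pwm3, "AG"), 3)
  # N contributes zero
  expect_equal(pwm_log_odds_score(pwm3, "NG"), 2)
  expect_error(pwm_log_odds_score(pwm3, "AGA"), "length")
})

test_that("accessible regions follow summit windows and genic subtraction", {
  peaks <- tibble::tibble(chrom = "c1",
                          start = c(900, 2000, 3000, 4000),
                          end = c(1100, 2200, 3200, 4200),
                          signal = c(9, 7, 5, 3),
                          summit = c(100, 100, 100, 100))
  acc <- build_accessible_regions(peaks, top_fraction = 0.5)
  # summit at 1000 -> window [925, 1075)
  expect_equal(acc$start, c(925, 2025))
  expect_equal(acc$end, c(1075, 2175))
  # 4 peaks, fraction 0.5 -> 2 highest-signal retained (asserted above)
  # fully genic window disappears; partial overlap truncates
  genic <- genomic_intervals("c1", c(900, 2050), c(1100, 2060))
  acc2 <- build_accessible_regions(peaks, genic, top_fraction = 0.5)
  expect_false(any(acc2$start < 1100))
  expect_equal(nrow(intersect_intervals(acc2, genic)), 0)
  expect_error(build_accessible_regions(peaks[, -5]), "summit")
})

test_that("curation keeps accessible, top-scored, capped site sets", {
  sites <- toy_sites("c1", seq(0, 900, 100), "+", 10, score = 10:1)
  acc <- genomic_intervals("c1", 0, 1000)
  cfg <- curation_config(top_fraction = 0.5)
  kept <- curate_active_sites(sites, acc, cfg)
  expect_equal(nrow(kept), 5)
  expect_true(all(kept$score >= 6))
  # cap
  cfg3 <- curation_config(top_fraction = 1, site_cap = 3)
  kept3 <- curate_active_sites(sites, acc, cfg3)
  expect_equal(sort(kept3$score, decreasing = TRUE), c(10, 9, 8))
  # only accessible sites are eligible
  acc_half <- genomic_intervals("c1", 0, 450)
  kept_h <- curate_active_sites(sites, acc_half, curation_config(
    top_fraction = 1))
  expect_equal(nrow(kept_h), 5)
  # min aggregate damage floor is checked against the observed profile
  prof29 <- tibble::tibble(position = -2:2, strand = "motif",
                           observed = c(1, 29, 0, 3, 2))
  expect_false(cluster_sufficient(prof29, 30))
  prof30 <- prof29; prof30$observed[2] <- 30
  expect_true(cluster_sufficient(prof30, 30))
})

test_that("strength tiers are equal thirds with deterministic ties", {
  sites9 <- toy_sites("c1", seq(0, 800, 100), "+", 10, score = 9:1)
  tiers <- stratify_by_strength(sites9, 3)
  expect_equal(vapply(tiers, nrow, integer(1)), c(3L, 3L, 3L))
  expect_true(all(tiers[[1]]$score >= 7))
  sites10 <- toy_sites("c1", seq(0, 900, 100), "+", 10, score = 10:1)
  tiers10 <- stratify_by_strength(sites10, 3)
  expect_equal(vapply(tiers10, nrow, integer(1)), c(4L, 3L, 3L))
  # ties broken by genomic order, reproducibly
  sites_t <- toy_sites("c1", seq(0, 500, 100), "+", 10, score = 1)
  t1 <- stratify_by_strength(sites_t, 3)
  t2 <- stratify_by_strength(sites_t, 3)
  expect_identical(lapply(t1, as.data.frame), lapply(t2, as.data.frame))
  expect_error(stratify_by_strength(sites9[1:2, ], 3), "at least")
})

test_that("observed profiles map lesions into motif coordinates", {
  # plus-strand site on c1: motif at [20, 28), center = 24
  sites <- toy_sites("c1", 20, "+", 8)
  map <- damage_map(tibble::tibble(chrom = "c1", strand = "-",
                                   pos5 = 28, count = 4))
  # complement lesion occupying motif positions 3/4 -> profile[3, comp]
  prof <- observed_profile(sites, map, 10)
  expect_equal(prof$observed[prof$position == 3 &
                               prof$strand == "complement"], 4)
  expect_equal(sum(prof$observed), 4)
  # no damage -> all zero
  expect_true(all(observed_profile(sites, map[0, ], 10)$observed == 0))
})

test_that("minus-strand motif sites flip into mirrored coordinates", {
  # 10-bp toy oracle: the same physical interval called on + and on -
  sp <- toy_sites("c1", 3, "+", 8)
  # a plus-strand TT lesion at ref 6,7 (motif positions -1/0) -> pos -1
  mp <- map_to_motif_coords(sp, "c1", "+", 6, 10)
  expect_equal(mp$position, -1)
  expect_equal(mp$profile_strand, "motif")
  # the same physical lesion under a minus-strand site call at the same
  # interval maps to the mirrored position on the complement strand
  sm <- toy_sites("c1", 3, "-", 8)
  mm <- map_to_motif_coords(sm, "c1", "+", 6, 10)
  # minus site center = end-1-4 = 6; dinuc lower coord 6 -> position
  # center - (lo+1) = -1... mirrored arithmetic, complement strand
  expect_equal(mm$profile_strand, "complement")
  expect_equal(mm$position, 6 - (6 + 1))
})

test_that("expected profiles add per-site context rates", {
  g <- toy_genome(c1 = paste0("AA", "GATTCA", "AA", "GATTCA", "AAAA"))
  # two + sites with motif GATTCA at [2,8) and [10,16): same contexts
  sites <- toy_sites("c1", c(2, 10), "+", 6)
  rt <- tibble::tibble(kmer = all_pyrimidine_kmers(1))
  rt$ctx <- kmer_to_index(rt$kmer)
  rt$occurrences <- 100; rt$damages <- 0; rt$rate <- 0; rt$covered <- TRUE
  rt$rate[rt$kmer == "ATTC"] <- 0.02
  rt <- structure(rt, class = c("uvf_rate_table", class(tibble::tibble())),
                  k_flank = 1L, lesion_type = "CPD", timepoint = "0h",
                  region_id = "toy")
  ep <- expected_profile(sites, g, rt, 3)
  # TT at motif offsets 2,3; center = floor(6/2)=3 -> position -1
  cell <- ep[ep$position == -1 & ep$strand == "motif", ]
  expect_equal(cell$expected, 0.04)  # additivity over the two sites
  expect_equal(cell$n_sites, 2L)
  # a position with no dipyrimidine contributes zero expectation
  expect_equal(ep$expected[ep$position == 0 & ep$strand == "motif"], 0)
})

test_that("flank scaling is per strand and motif half", {
  grid <- uvfootprint:::.profile_grid(10)
  obs <- grid; obs$observed <- 12
  expc <- grid; expc$expected <- 10; expc$n_sites <- 1L
  # identity when observed equals expected
  same <- flank_scale(dplyr::mutate(obs, observed = 10), expc,
                      motif_len = 4, span_pad = 1)
  expect_true(all(abs(same$scale_factor - 1) < 1e-12))
  expect_equal(same$expected_scaled, same$expected)
  # uniform 1.2 ratio scales everything by 1.2
  sc <- flank_scale(obs, expc, motif_len = 4, span_pad = 1)
  expect_true(all(abs(sc$scale_factor - 1.2) < 1e-12))
  # left flank ratio 2, right flank ratio 1 -> only left half doubled
  obs2 <- grid
  obs2$observed <- ifelse(grid$position <= 0, 20, 10)
  sc2 <- flank_scale(obs2, expc, motif_len = 4, span_pad = 1)
  left <- sc2$position <= 0
  expect_true(all(abs(sc2$expected_scaled[left] - 20) < 1e-12))
  expect_true(all(abs(sc2$expected_scaled[!left] - 10) < 1e-12))
  # no usable flank -> factor 1 with a warning
  expc0 <- expc; expc0$expected <- 0
  expc0$expected[expc0$position == 0] <- 5
  expect_warning(f0 <- flank_scale(obs, expc0, motif_len = 4,
                                   span_pad = 1), "factor")
  expect_true(all(f0$scale_factor == 1))
})

test_that("one-sided Poisson test matches the direct-summation oracle", {
  prof <- tibble::tibble(position = c(-1, 0, 1, 2), strand = "motif",
                         observed = c(9, 8, 2, 0),
                         expected_scaled = c(9, 4, 4, 0))
  t <- poisson_position_test(prof, 0.05)
  expect_equal(t$z[1], 0)
  expect_equal(t$direction[1], "none")
  # lambda 4, X 8: z = 2, enrichment p ~ 0.0511
  expect_equal(t$z[2], 2)
  expect_equal(t$p[2], pois_tail_oracle(8, 4, upper = TRUE),
               tolerance = 1e-12)
  expect_equal(round(t$p[2], 4), 0.0511)
  # depletion side uses the lower tail
  expect_equal(t$p[3], pois_tail_oracle(2, 4, upper = FALSE),
               tolerance = 1e-12)
  # lambda 0, X 0: untestable, excluded from correction
  expect_true(is.na(t$q[4]))

  # oracle agreement to 1e-10 across a lambda/X grid
  set.seed(1)
  lam <- runif(40, 0.05, 50)
  x <- rpois(40, lam) + sample(0:5, 40, replace = TRUE)
  up <- stats::ppois(x - 1, lam, lower.tail = FALSE)
  lo <- stats::ppois(x, lam)
  for (i in seq_along(lam)) {
    expect_equal(up[i], pois_tail_oracle(x[i], lam[i], TRUE),
                 tolerance = 1e-10)
    expect_equal(lo[i], pois_tail_oracle(x[i], lam[i], FALSE),
                 tolerance = 1e-10)
  }
})

test_that("BH correction reproduces the hand step-up example", {
  prof <- tibble::tibble(position = 1:3, strand = "motif",
                         observed = c(10, 10, 10),
                         expected_scaled = c(1, 1, 1))
  t <- poisson_position_test(prof)
  # override p with the classic example and re-run the adjustment
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), method = "BH"),
               c(0.03, 0.03, 0.04))
  # q is never below p
  expect_true(all(t$q >= t$p - 1e-15, na.rm = TRUE))
})

test_that("per-direction p-values are valid and z is calibrated on null", {
  # directional validity: under the null each one-sided tail exceeds its
  # nominal level at most alpha (conservative for discrete counts); the
  # direction-selected p itself doubles the exceedance, which the test
  # procedure compensates for via BH + naked-DNA filtering downstream
  st <- synthesize_study(seed = 301, n_clusters = 2, n_sites = 600,
                         background_bp = 1.5e6)
  an <- quiet(analyze_formation(st, seed = 302))
  cells <- dplyr::bind_rows(lapply(an$tests, tidy))
  cells <- cells[!is.na(cells$q), ]
  enr <- cells$direction == "enriched" & cells$p < 0.05
  dep <- cells$direction == "depleted" & cells$p < 0.05
  n <- nrow(cells)
  expect_lt(mean(enr), 0.05 + 2.58 * sqrt(0.05 * 0.95 / n))
  expect_lt(mean(dep), 0.05 + 2.58 * sqrt(0.05 * 0.95 / n))
  z <- cells$z[!is.na(cells$z)]
  expect_lt(abs(mean(z)), 0.15)
  expect_gt(sd(z), 0.8); expect_lt(sd(z), 1.25)
})

test_that("shuffle null conserves lesions and matches per-record sampling", {
  # toy: all loci of every class inside profiled windows -> totals
  # conserved each iteration
  g0 <- generate_genome(1, 2e4, 0.5, seed = 51)
  pl <- plant_sites(g0, "ACGTTAGC", 40, 220, seed = 51)
  tt <- make_truth_tables(51)
  map <- quiet(simulate_damage(pl$genome, pl$accessible, tt, seed = 52,
                               dose_scale = 3))
  # regions = only window interiors where every locus maps to a cell
  centers <- uvfootprint:::site_center(pl$sites)
  inner <- genomic_intervals(pl$sites$chrom, centers - 20, centers + 21)
  sh <- quiet(shuffle_null_test(map, inner, pl$genome, pl$sites,
                                window = 25, n_iter = 60, seed = 53))
  inmap <- filter_to_regions(map, inner)
  # every surviving record lands in some cell every iteration: the null
  # column sums all equal the observed total
  expect_equal(sum(sh$observed), sum(inmap$count))
  expect_true(all(abs(colSums(attr(sh, "null_matrix")) -
                        sum(inmap$count)) < 1e-9))

  # multinomial fast path reproduces brute-force per-record shuffling
  set.seed(99)
  loci <- enumerate_dipyrimidine_loci(pl$genome, inner, 1)
  loci <- loci[!is.na(loci$ctx), ]
  mp <- map_to_motif_coords(pl$sites, loci$chrom, loci$strand,
                            loci$pos5, 25)
  grid <- uvfootprint:::.profile_grid(25)
  dest <- rep(0L, nrow(loci))
  dest[mp$locus] <- match(paste(mp$position, mp$profile_strand),
                          paste(grid$position, grid$strand))
  key <- paste(loci$chrom, loci$strand, loci$pos5)
  rec <- match(paste(inmap$chrom, inmap$strand, inmap$pos5), key)
  brute <- matrix(0, nrow(grid), 400)
  for (it in 1:400) {
    for (r in which(!is.na(rec))) {
      cls <- loci$ctx[rec[r]]
      cand <- which(loci$ctx == cls)
      to <- dest[sample(cand, 1)]
      if (to > 0) brute[to, it] <- brute[to, it] + inmap$count[r]
    }
  }
  nm <- attr(sh, "null_matrix")
  busy <- rowMeans(nm) > 2
  expect_gt(sum(busy), 5)
  expect_lt(max(abs(rowMeans(nm)[busy] - rowMeans(brute)[busy]) /
                  (apply(brute, 1, sd)[busy] / sqrt(400) +
                     apply(nm, 1, sd)[busy] / sqrt(ncol(nm)))), 5)
})

test_that("naked DNA filtering demotes sequence-intrinsic calls", {
  mk <- function(sig, dir) {
    structure(tibble::tibble(position = c(1, 2, 3), strand = "motif",
                             observed = 1, z = 1,
                             direction = dir, significant = sig,
                             p = 0.01, q = 0.01),
              class = c("uvf_profile_test", class(tibble::tibble())),
              threshold = 0.05)
  }
  cell <- mk(c(TRUE, TRUE, TRUE),
             c("enriched", "enriched", "enriched"))
  naked <- mk(c(FALSE, TRUE, TRUE),
              c("enriched", "enriched", "depleted"))
  out <- naked_dna_filter(cell, naked)
  expect_equal(out$label,
               c("significant", "sequence-intrinsic", "opposite-in-naked"))
  expect_equal(out$significant, c(TRUE, FALSE, TRUE))
})

test_that("stronger binding tiers carry stronger planted effects", {
  # effect strength proportional to motif score: |z| at the planted cell
  # must not increase from the strongest to the weakest tier
  g0 <- generate_genome(2, c(2e6, 3.5e5), 0.4, seed = 61)
  pwm <- matrix(0.03, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  consensus <- strsplit("ACGTTAGC", "")[[1]]
  for (j in 1:8) pwm[consensus[j], j] <- 0.91
  pl <- plant_sites(g0, pwm, 1500, 200, seed = 61, chrom = "chr2")
  tt <- make_truth_tables(61)
  eff <- planted_effect(-1, "motif", "formation", 6)
  eff$score_coupled <- TRUE
  background <- genomic_intervals("chr1", 0, 2e6)
  regions <- genomic_intervals(dplyr::bind_rows(background,
                                                pl$accessible))
  map <- quiet(simulate_damage(pl$genome, regions, tt,
                               effects = eff, sites = pl$sites,
                               seed = 62, dose_scale = 2))
  # rates from the motif-free background so the cluster's own planted
  # effect cannot mask itself through the rate table
  rates <- quiet(estimate_context_rates(map, pl$genome, background, 2))
  tiers <- stratify_by_strength(pl$sites, 3)
  zs <- vapply(tiers, function(s) {
    obs <- observed_profile(s, map, 15)
    expc <- quiet(expected_profile(s, pl$genome, rates, 15))
    pt <- poisson_position_test(quiet(flank_scale(obs, expc, 8)))
    pt$z[pt$position == -1 & pt$strand == "motif"]
  }, numeric(1))
  expect_true(zs[1] >= zs[2] && zs[2] >= zs[3])
})
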
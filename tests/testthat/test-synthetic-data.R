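# Generator properties: determinism, composition, planted effects, and
# statistical agreement with the truth tables.

test_that("generate_genome is seeded, composition-true, and validated", {
  g1 <- generate_genome(1, 2e4, gc = 0.4, seed = 5)
  g2 <- generate_genome(1, 2e4, gc = 0.4, seed = 5)
  expect_identical(unclass(g1), unclass(g2))
  expect_false(identical(unclass(generate_genome(1, 2e4, 0.4, seed = 6)),
                         unclass(g1)))
  expect_error(generate_genome(1, 0, 0.4, 1), "length")
  # gc = 1 -> G/C only
  gc1 <- generate_genome(1, 2000, gc = 1, seed = 1)
  expect_false(grepl("[AT]", unclass(gc1)[[1]]))
  # empirical GC within 1% at 1 Mb (binomial concentration)
  gbig <- generate_genome(1, 1e6, gc = 0.4, seed = 2)
  gc_obs <- mean(strsplit(unclass(gbig)[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.4), 0.01)
})

test_that("plant_sites writes the motif, spaces sites, uses both strands", {
  g <- generate_genome(1, 4e4, gc = 0.4, seed = 9)
  pl <- plant_sites(g, "GGAA", n_sites = 100, spacing = 200, seed = 9)
  expect_equal(nrow(pl$sites), 100)
  # disjoint sites, each inside an accessible window
  s <- pl$sites
  expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  hit <- uvfootprint:::.overlaps_any(s$chrom, s$start, s$end,
                                     pl$accessible)
  expect_true(all(hit))
  # planted sequence equals the consensus (motif-strand orientation)
  seqs <- substring(unclass(pl$genome)[s$chrom], s$start + 1, s$end)
  seqs[s$strand == "-"] <- uvfootprint:::revcomp(seqs[s$strand == "-"])
  expect_true(all(seqs == "GGAA"))
  # strand usage within binomial(100, 0.5) 99% bounds
  n_plus <- sum(s$strand == "+")
  expect_true(n_plus >= qbinom(0.005, 100, 0.5) &&
                n_plus <= qbinom(0.995, 100, 0.5))
  # scores come from the log-odds scanner (deterministic PWM, uniform bg)
  expect_true(all(abs(s$score - 2 * 4) < 1e-9))
  expect_error(plant_sites(generate_genome(1, 500, 0.4, 1), "GGAA", 100),
               "too short")
})

test_that("simulate_damage draws context-dependent Poisson counts", {
  tt <- make_truth_tables(3)
  g <- generate_genome(1, 3e5, gc = 0.5, seed = 3)
  regions <- genomic_intervals("chr1", 10, 3e5 - 10)
  # all-zero rates -> empty map
  tt0 <- tt
  tt0$hexamer_rate[] <- 0
  expect_equal(nrow(quiet(simulate_damage(g, regions, tt0, seed = 1))), 0)

  map <- quiet(simulate_damage(g, regions, tt, seed = 4))
  loci <- enumerate_dipyrimidine_loci(g, regions, 2)
  loci <- loci[!is.na(loci$ctx), ]
  counts <- dplyr::left_join(
    loci, tibble::as_tibble(map)[, c("chrom", "strand", "pos5", "count")],
    by = c("chrom", "strand", "pos5"))
  counts$count <- dplyr::coalesce(counts$count, 0)
  # per-hexamer mean within 3 SE of the truth rate for well-covered k-mers
  agg <- counts |>
    dplyr::group_by(.data$ctx) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$count))
  agg <- agg[agg$n >= 120, ]
  expect_gt(nrow(agg), 100)
  truth <- tt$hexamer_rate[agg$ctx + 1]
  se <- sqrt(truth / agg$n)
  expect_lt(mean(abs(agg$mean - truth) > 3 * se), 0.05)
})

test_that("planted formation multipliers change only their own cell", {
  g0 <- generate_genome(1, 1e5, gc = 0.4, seed = 11)
  pl <- plant_sites(g0, "ACGTTAGC", 400, 200, seed = 11)
  tt <- make_truth_tables(11)
  eff <- planted_effect(-1, "motif", "formation", 3)
  map <- quiet(simulate_damage(pl$genome, pl$accessible, tt,
                               effects = eff, sites = pl$sites,
                               seed = 12))
  map0 <- quiet(simulate_damage(pl$genome, pl$accessible, tt, seed = 12))
  obs <- observed_profile(pl$sites, map, 10)
  obs0 <- observed_profile(pl$sites, map0, 10)
  at <- function(o, p, s) o$observed[o$position == p & o$strand == s]
  # the planted cell's per-site mean is ~3x its own baseline within 3 SE
  lam1 <- at(obs, -1, "motif"); lam0 <- at(obs0, -1, "motif")
  expect_gt(lam1, lam0)
  expect_lt(abs(lam1 - 3 * lam0), 3 * sqrt(3 * lam0) + 3 * sqrt(lam0))
  # an unplanted cell is statistically unchanged
  other1 <- at(obs, 5, "motif"); other0 <- at(obs0, 5, "motif")
  expect_lt(abs(other1 - other0),
            4 * sqrt(max(other0, 5)))
})

test_that("simulate_repair thins binomially with NYYN survival", {
  g <- generate_genome(1, 2e5, gc = 0.5, seed = 13)
  tt <- make_truth_tables(13)
  regions <- genomic_intervals("chr1", 10, 2e5 - 10)
  map0 <- quiet(simulate_damage(g, regions, tt, seed = 14,
                                dose_scale = 2))
  # survival 1 -> identical map; survival 0 -> empty
  tt1 <- tt; tt1$nyyn_survival[] <- 1
  r1 <- quiet(simulate_repair(map0, g, tt1, seed = 15))
  expect_equal(as.data.frame(r1), as.data.frame(map0),
               ignore_attr = TRUE)
  tt0 <- tt; tt0$nyyn_survival[] <- 0
  expect_equal(nrow(quiet(simulate_repair(map0, g, tt0, seed = 15))), 0)
  # one context: total remaining within 3 SE of survival * total
  tt4 <- tt; tt4$nyyn_survival[] <- 0.4
  r4 <- quiet(simulate_repair(map0, g, tt4, seed = 16))
  n0 <- sum(map0$count); n4 <- sum(r4$count)
  expect_lt(abs(n4 - 0.4 * n0), 3 * sqrt(n0 * 0.4 * 0.6))
  # clamping warns
  tteff <- tt; tteff$nyyn_survival[] <- 0.8
  pl <- plant_sites(g, "ACGTTAGC", 50, 200, seed = 17)
  m0 <- quiet(simulate_damage(pl$genome, pl$accessible, tt, seed = 18))
  expect_warning(
    quiet_messages <- suppressMessages(simulate_repair(
      m0, pl$genome, tteff,
      effects = planted_effect(-1, "motif", "survival", 2),
      sites = pl$sites, seed = 19)),
    "clamped")
})

test_that("simulate_mutations follows trinucleotide rates and hotspots", {
  g0 <- generate_genome(1, 1.5e5, gc = 0.5, seed = 21)
  pl <- plant_sites(g0, "ACGTTAGC", 500, 200, seed = 21)
  tt <- make_truth_tables(21)
  tt0 <- tt; tt0$trinuc_mut_rate[] <- 0
  expect_equal(nrow(simulate_mutations(pl$genome, pl$accessible, tt0,
                                       n_samples = 50, seed = 1)), 0)
  # empirical per-trinucleotide frequency within 3 SE
  mut <- simulate_mutations(pl$genome, pl$accessible, tt,
                            n_samples = 400, seed = 22)
  loci <- enumerate_cytosine_loci(pl$genome, pl$accessible)
  loci <- loci[!is.na(loci$ctx), ]
  cnt <- table(factor(loci$ctx[match(paste(mut$chrom, mut$pos),
                                     paste(loci$chrom, loci$pos))],
                      levels = sort(unique(loci$ctx))))
  nl <- table(factor(loci$ctx, levels = sort(unique(loci$ctx))))
  idx <- as.integer(names(nl))
  expected <- tt$trinuc_mut_rate[idx + 1] * 400 * as.numeric(nl)
  big <- expected >= 25
  dev <- abs(as.numeric(cnt)[big] - expected[big]) /
    sqrt(expected[big])
  expect_lt(mean(dev > 3), 0.1)
  # hotspot multiplier 5 at one motif position vs flank baseline
  hot <- tibble::tibble(position = -3, multiplier = 5)
  muth <- simulate_mutations(pl$genome, pl$accessible, tt, pl$sites,
                             hotspots = hot, n_samples = 400, seed = 23)
  prof <- actual_mutation_profile(muth, pl$genome, pl$sites, 40)
  base <- actual_mutation_profile(mut, pl$genome, pl$sites, 40)
  hot_obs <- prof$actual[prof$position == -3]
  hot_base <- base$actual[base$position == -3]
  expect_gt(hot_obs, hot_base)
  expect_lt(abs(hot_obs - 5 * hot_base),
            3 * sqrt(5 * hot_base) + 5 * 3 * sqrt(hot_base))
})

test_that("fixture bundles are reproducible byte for byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  m1 <- quiet(write_fixture_bundle(d1, seed = 5, n_sites = 40,
                                   genome_bp = 5e4, n_samples = 10))
  m2 <- quiet(write_fixture_bundle(d2, seed = 5, n_sites = 40,
                                   genome_bp = 5e4, n_samples = 10))
  m3 <- quiet(write_fixture_bundle(d3, seed = 6, n_sites = 40,
                                   genome_bp = 5e4, n_samples = 10))
  expect_true(all(file.exists(file.path(d1, m1$file))))
  for (f in m1$file) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # a different seed changes the damage map
  expect_false(identical(readLines(file.path(d1, "cpd_0h.bed")),
                         readLines(file.path(d3, "cpd_0h.bed"))))
})

test_that("substream seeds are stable and name-separated", {
  expect_equal(substream_seed(1, "damage"), substream_seed(1, "damage"))
  expect_false(substream_seed(1, "damage") == substream_seed(1, "repair"))
  expect_false(substream_seed(1, "damage") == substream_seed(2, "damage"))
  expect_true(substream_seed(.Machine$integer.max, "x") < 2^31)
})
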
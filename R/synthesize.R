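# Synthetic data with the statistical structure the analysis assumes:
# hexanucleotide-dependent Poisson damage, NYYN-dependent repair survival,
# trinucleotide-dependent C>T mutation, and plantable per-position effect
# multipliers at binding sites for parameter-recovery tests.

#' Synthetic truth tables
#'
#' Ground-truth parameter tables for the generator: a hexanucleotide
#' (NNYYNN) damage rate per occurrence, a tetranucleotide (NYYN) repair
#' survival probability at the simulated later timepoint, and a
#' trinucleotide (NCN) per-sample C>T mutation probability.  Hexamer rates
#' are a dinucleotide-class base rate times a seeded lognormal flank
#' modifier, giving strong flank dependence without copying any published
#' table.
#'
#' @param seed Integer seed; fixes all three tables.
#' @param base_rates Named per-dinucleotide base damage rates
#'   (TT/TC/CT/CC, damages per occurrence).
#' @param flank_sigma Lognormal sigma of the flank modifier.
#' @param survival_mean Mean repair survival (fraction of lesions
#'   remaining at the later timepoint).
#' @param survival_sigma Logit-scale spread of per-NYYN survival.
#' @param mut_base_pyr5,mut_base_other Per-sample C>T probability for
#'   cytosines with a pyrimidine vs non-pyrimidine 5' neighbour
#'   (dipyrimidine-forming contexts mutate more under UV).
#' @param mut_sigma Lognormal sigma of the trinucleotide modifier.
#' @return List of class `uvf_truth` with elements `hexamer_rate`,
#'   `nyyn_survival`, `trinuc_mut_rate` (dense vectors indexed by
#'   `ctx + 1`), plus tidy tibbles `hexamer`, `nyyn`, `trinuc`.
#' @export
make_truth_tables <- function(seed = 1L,
                              base_rates = c(TT = 0.10, TC = 0.06,
                                             CT = 0.03, CC = 0.015),
                              flank_sigma = 0.35,
                              survival_mean = 0.45, survival_sigma = 0.6,
                              mut_base_pyr5 = 4e-4, mut_base_other = 1e-4,
                              mut_sigma = 0.4) {
  stopifnot(all(c("TT", "TC", "CT", "CC") %in% names(base_rates)))
  set.seed(substream_seed(seed, "truth"))
  hex <- all_pyrimidine_kmers(2L)
  hex_idx <- kmer_to_index(hex)
  dinuc <- substr(hex, 3, 4)
  hex_rate <- unname(base_rates[dinuc]) *
    stats::rlnorm(length(hex), -flank_sigma^2 / 2, flank_sigma)
  tet <- all_pyrimidine_kmers(1L)
  tet_idx <- kmer_to_index(tet)
  surv <- stats::plogis(stats::qlogis(survival_mean) +
                          stats::rnorm(length(tet), 0, survival_sigma))
  bases <- c("A", "C", "G", "T")
  tri <- as.vector(outer(bases, paste0("C", bases), paste0))
  tri_idx <- kmer_to_index(tri)
  base_mut <- ifelse(substr(tri, 1, 1) %in% c("C", "T"),
                     mut_base_pyr5, mut_base_other)
  mut <- base_mut * stats::rlnorm(length(tri), -mut_sigma^2 / 2, mut_sigma)
  dense <- function(idx, val, width) {
    v <- numeric(4^width); v[idx + 1L] <- val; v
  }
  structure(list(
    hexamer_rate = dense(hex_idx, hex_rate, 6L),
    nyyn_survival = dense(tet_idx, surv, 4L),
    trinuc_mut_rate = dense(tri_idx, mut, 3L),
    hexamer = tibble::tibble(kmer = hex, ctx = hex_idx, rate = hex_rate),
    nyyn = tibble::tibble(kmer = tet, ctx = tet_idx, survival = surv),
    trinuc = tibble::tibble(kmer = tri, ctx = tri_idx, rate = mut)),
    class = "uvf_truth")
}

#' Planted per-position effect multipliers
#'
#' @param position Motif-relative position (5'-base convention) of the
#'   affected dipyrimidine.
#' @param strand `"motif"` or `"complement"`.
#' @param kind `"formation"` (damage-rate multiplier) or `"survival"`
#'   (repair-survival multiplier).
#' @param multiplier Positive multiplier.
#' @return Tibble with one row per effect.
#' @export
planted_effect <- function(position, strand = "motif",
                           kind = c("formation", "survival"),
                           multiplier = 3) {
  kind <- match.arg(kind)
  stopifnot(all(multiplier > 0),
            all(strand %in% c("motif", "complement")))
  tibble::tibble(position = position,
                 strand = rep_len(strand, length(position)),
                 kind = rep_len(kind, length(position)),
                 multiplier = rep_len(multiplier, length(position)))
}

#' Generate a random genome
#'
#' @param n_chroms Number of chromosomes (named `chr1`, `chr2`, ...).
#' @param length Length of each chromosome (recycled).
#' @param gc GC content in (0, 1).
#' @param seed Integer seed; fixes the output.
#' @return A `uvf_genome`.
#' @export
generate_genome <- function(n_chroms = 1L, length = 1e5, gc = 0.4,
                            seed = 1L) {
  stopifnot(gc > 0, gc <= 1)
  if (any(length < 1)) stop("chromosome length must be >= 1", call. = FALSE)
  length <- rep_len(length, n_chroms)
  set.seed(substream_seed(seed, "genome"))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n_chroms), function(i) {
    paste(sample(names(p), length[i], replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
  genome_sequence(stats::setNames(seqs, paste0("chr", seq_len(n_chroms))))
}

# normalise a motif spec (consensus string or 4 x L probability matrix
# with rownames A,C,G,T) into a probability matrix
.as_pwm <- function(motif) {
  if (is.character(motif)) {
    L <- nchar(motif)
    m <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (i in seq_len(L)) m[substr(motif, i, i), i] <- 1
    m
  } else {
    stopifnot(is.matrix(motif), nrow(motif) == 4)
    if (is.null(rownames(motif))) rownames(motif) <- c("A", "C", "G", "T")
    sweep(motif, 2, colSums(motif), "/")
  }
}

#' Plant motif-bearing binding sites in a genome
#'
#' Writes a draw from the motif model at `n_sites` non-overlapping,
#' regularly spaced loci on the given chromosome (both strands used with
#' equal probability), centers each site in a 150-bp accessible window,
#' and scores the planted sequences with the native log-odds scanner.
#'
#' @param genome A `uvf_genome`.
#' @param motif Consensus string (planted exactly) or a 4 x L probability
#'   matrix sampled per site.
#' @param n_sites Number of sites to plant.
#' @param spacing Center-to-center distance between consecutive sites;
#'   must exceed the motif length.
#' @param seed Integer seed.
#' @param chrom Chromosome to plant on (default: first).
#' @param cluster_id Cluster label for the returned site set.
#' @param window_width Accessible window width around each site center.
#' @return List with elements `genome` (mutated), `sites` (`uvf_sites`),
#'   `accessible` (interval table of the site windows).
#' @export
plant_sites <- function(genome, motif, n_sites, spacing = 200L, seed = 1L,
                        chrom = names(genome)[[1]],
                        cluster_id = "cluster", window_width = 150L) {
  pwm <- .as_pwm(motif)
  L <- ncol(pwm)
  if (spacing <= L) stop("spacing must exceed the motif length",
                         call. = FALSE)
  lens <- chrom_lengths(genome)
  margin <- max(window_width, 100L)
  need <- n_sites * spacing + 2 * margin
  if (lens[[chrom]] < need) {
    stop("genome too short: need ", need, " bp on ", chrom, call. = FALSE)
  }
  set.seed(substream_seed(seed, "plant"))
  # jitter kept small enough that neighbouring analysis windows and
  # accessible windows never overlap
  jmax <- max(2L, min(spacing - L - 2L, spacing - 175L))
  centers <- margin + spacing * (seq_len(n_sites) - 1L) +
    sample.int(jmax, n_sites, replace = TRUE)
  strand <- ifelse(stats::runif(n_sites) < 0.5, "+", "-")
  # draw a motif-strand sequence per site
  bases <- rownames(pwm)
  drawn <- vapply(seq_len(n_sites), function(i) {
    paste(vapply(seq_len(L), function(j) {
      sample(bases, 1L, prob = pwm[, j])
    }, character(1)), collapse = "")
  }, character(1))
  start <- centers - floor(L / 2)
  start[strand == "-"] <- centers[strand == "-"] - (L - 1 - floor(L / 2))
  written <- ifelse(strand == "+", drawn, revcomp(drawn))
  seqs <- unclass(genome)
  chars <- strsplit(seqs[[chrom]], "", fixed = TRUE)[[1]]
  for (i in seq_len(n_sites)) {
    chars[(start[i] + 1):(start[i] + L)] <-
      strsplit(written[i], "", fixed = TRUE)[[1]]
  }
  seqs[[chrom]] <- paste(chars, collapse = "")
  out_genome <- genome_sequence(seqs)
  score <- pwm_log_odds_score(pwm, drawn)
  sites <- binding_sites(tibble::tibble(chrom = chrom, start = start,
                                        end = start + L, strand = strand,
                                        score = score),
                         cluster_id = cluster_id)
  half <- floor(window_width / 2)
  accessible <- genomic_intervals(chrom, centers - half,
                                  centers - half + window_width)
  list(genome = out_genome, sites = sites, accessible = accessible)
}

# reference-coordinate loci of a dipyrimidine at one (position, profile
# strand) across all sites: returns chrom/strand/pos5 keys
.effect_loci <- function(sites, position, profile_strand) {
  centers <- site_center(sites)
  plus <- sites$strand == "+"
  lo <- ifelse(plus, centers + position, centers - position - 1)
  damaged <- if (profile_strand == "motif") sites$strand else
    ifelse(sites$strand == "+", "-", "+")
  tibble::tibble(chrom = sites$chrom, strand = damaged,
                 pos5 = ifelse(damaged == "+", lo, lo + 1))
}

# per-locus multipliers from planted effects of one kind; an optional
# logical `score_coupled` column scales the effect with the site's motif
# score (weakest site gets multiplier 1, strongest the full multiplier)
.effect_multipliers <- function(loci, effects, sites, kind) {
  mult <- rep(1, nrow(loci))
  if (is.null(effects) || nrow(effects) == 0L || is.null(sites)) {
    return(mult)
  }
  eff <- effects[effects$kind == kind, , drop = FALSE]
  if (nrow(eff) == 0L) return(mult)
  near <- which(loci$chrom %in% unique(sites$chrom))
  key <- paste(loci$chrom[near], loci$strand[near], loci$pos5[near])
  for (i in seq_len(nrow(eff))) {
    tgt <- .effect_loci(sites, eff$position[i], eff$strand[i])
    site_mult <- rep(eff$multiplier[i], nrow(sites))
    if ("score_coupled" %in% names(eff) && isTRUE(eff$score_coupled[i])) {
      rng <- range(sites$score)
      w <- if (diff(rng) > 0) (sites$score - rng[1]) / diff(rng) else 1
      site_mult <- 1 + (eff$multiplier[i] - 1) * w
    }
    hit <- match(key, paste(tgt$chrom, tgt$strand, tgt$pos5))
    ok <- !is.na(hit)
    mult[near[ok]] <- mult[near[ok]] * site_mult[hit[ok]]
  }
  mult
}

#' Simulate a context-dependent Poisson damage map
#'
#' Every dipyrimidine locus in `regions` (both strands) draws a count from
#' `Poisson(rate(hexamer) * dose_scale * multiplier)`, where the
#' multiplier differs from 1 only at planted (site, position, strand)
#' combinations.  Zero-count loci are omitted, matching real damage maps.
#'
#' @param genome A `uvf_genome`.
#' @param regions Interval table of loci to simulate over.
#' @param truth A `uvf_truth` table set.
#' @param effects Optional [planted_effect()] tibble (formation kind).
#' @param sites Optional `uvf_sites` the effects refer to.
#' @param seed Integer seed.
#' @param lesion_type,timepoint Damage-map metadata.
#' @param dose_scale Global rate multiplier (UV dose knob).
#' @param loci Optional precomputed [enumerate_dipyrimidine_loci()] table
#'   for `regions` (performance cache).
#' @return A `uvf_damage_map`.
#' @export
simulate_damage <- function(genome, regions, truth, effects = NULL,
                            sites = NULL, seed = 1L, lesion_type = "CPD",
                            timepoint = "0h", dose_scale = 1,
                            loci = NULL) {
  if (is.null(loci)) {
    loci <- enumerate_dipyrimidine_loci(genome, regions, k_flank = 2L)
  }
  n_na <- sum(is.na(loci$ctx))
  if (n_na > 0) {
    uvf_inform(paste0("simulate_damage: ", n_na,
                      " locus/loci with unavailable context skipped"))
  }
  loci <- loci[!is.na(loci$ctx), , drop = FALSE]
  rate <- truth$hexamer_rate[loci$ctx + 1L] * dose_scale
  rate <- rate * .effect_multipliers(loci, effects, sites, "formation")
  set.seed(substream_seed(seed, "damage"))
  counts <- stats::rpois(length(rate), rate)
  keep <- counts > 0
  damage_map(tibble::tibble(chrom = loci$chrom[keep],
                            strand = loci$strand[keep],
                            pos5 = loci$pos5[keep],
                            dinuc = dinuc_from_ctx(loci$ctx[keep], 2L),
                            count = counts[keep]),
             lesion_type = lesion_type, timepoint = timepoint)
}

#' Simulate repair of an initial damage map
#'
#' Each locus keeps `Binomial(count_0h, survival(NYYN) * multiplier)`
#' lesions, the multiplier differing from 1 only at planted survival
#' effects; `survival * multiplier` is clamped to `[0, 1]` with a warning.
#'
#' @param map0h A CPD `uvf_damage_map` at the initial timepoint.
#' @param genome A `uvf_genome`.
#' @inheritParams simulate_damage
#' @param timepoint Label of the simulated later timepoint.
#' @return A `uvf_damage_map` at `timepoint`.
#' @export
simulate_repair <- function(map0h, genome, truth, effects = NULL,
                            sites = NULL, seed = 1L, timepoint = "6h") {
  stopifnot(attr(map0h, "lesion_type") == "CPD")
  if (nrow(map0h) == 0L) return(map0h)
  ctx <- extract_context(genome, map0h$chrom, map0h$strand, map0h$pos5,
                         k_flank = 1L)
  surv <- rep(NA_real_, nrow(map0h))
  ok <- !is.na(ctx)
  surv[ok] <- truth$nyyn_survival[kmer_to_index(ctx[ok]) + 1L]
  surv[!ok] <- mean(truth$nyyn_survival[truth$nyyn_survival > 0])
  loci <- tibble::tibble(chrom = map0h$chrom, strand = map0h$strand,
                         pos5 = map0h$pos5)
  surv <- surv * .effect_multipliers(loci, effects, sites, "survival")
  if (any(surv > 1)) {
    warning("survival * multiplier > 1 at ", sum(surv > 1),
            " locus/loci; clamped to 1", call. = FALSE)
    surv <- pmin(surv, 1)
  }
  set.seed(substream_seed(seed, "repair"))
  remaining <- stats::rbinom(nrow(map0h), map0h$count, surv)
  keep <- remaining > 0
  damage_map(tibble::tibble(chrom = map0h$chrom[keep],
                            strand = map0h$strand[keep],
                            pos5 = map0h$pos5[keep],
                            dinuc = map0h$dinuc[keep],
                            count = remaining[keep]),
             lesion_type = "CPD", timepoint = timepoint)
}

#' Simulate trinucleotide-dependent C>T mutations
#'
#' Every cytosine (either strand) inside `regions` mutates independently
#' in each of `n_samples` samples with probability
#' `rate(trinucleotide) * multiplier`; minus-strand events are recorded as
#' reference G>A.  Hotspot multipliers apply at given motif-relative
#' positions of the supplied sites (either strand).
#'
#' @inheritParams simulate_damage
#' @param hotspots Optional tibble `position`, `multiplier`.
#' @param n_samples Number of simulated samples.
#' @return A `uvf_mutations` table.
#' @export
simulate_mutations <- function(genome, regions, truth, sites = NULL,
                               hotspots = NULL, n_samples = 100L,
                               seed = 1L) {
  loci <- enumerate_cytosine_loci(genome, regions)
  loci <- loci[!is.na(loci$ctx), , drop = FALSE]
  rate <- truth$trinuc_mut_rate[loci$ctx + 1L]
  if (!is.null(hotspots) && nrow(hotspots) > 0 && !is.null(sites)) {
    centers <- site_center(sites)
    for (i in seq_len(nrow(hotspots))) {
      plus <- sites$strand == "+"
      g <- ifelse(plus, centers + hotspots$position[i],
                  centers - hotspots$position[i])
      key <- paste(loci$chrom, loci$pos)
      hit <- key %in% paste(sites$chrom, g)
      rate[hit] <- rate[hit] * hotspots$multiplier[i]
    }
  }
  set.seed(substream_seed(seed, "mutations"))
  k <- stats::rbinom(nrow(loci), n_samples, pmin(rate, 1))
  hit <- which(k > 0)
  if (length(hit) == 0L) {
    return(mutation_table(tibble::tibble(chrom = character(0),
                                         pos = numeric(0),
                                         ref = character(0),
                                         alt = character(0),
                                         sample = character(0))))
  }
  idx <- rep(hit, k[hit])
  samp <- unlist(lapply(hit, function(i) {
    paste0("S", sample.int(n_samples, k[i]))
  }))
  plus <- loci$strand[idx] == "+"
  mutation_table(tibble::tibble(chrom = loci$chrom[idx],
                                pos = loci$pos[idx],
                                ref = ifelse(plus, "C", "G"),
                                alt = ifelse(plus, "T", "A"),
                                sample = samp))
}

#' Write a complete synthetic fixture bundle
#'
#' Generates a genome with planted sites, damage maps at two timepoints,
#' a 6-4 PP style map, mutations, truth tables (JSON) and a manifest TSV.
#' Re-running with the same seed reproduces byte-identical files.
#'
#' @param outdir Output directory (created if missing).
#' @param seed Master seed.
#' @param n_sites,motif,spacing,genome_bp Generator geometry.
#' @param effects Optional [planted_effect()] tibble.
#' @param n_samples Mutation samples.
#' @return Tibble manifest (file, role, seed) — also written to
#'   `manifest.tsv`.
#' @export
write_fixture_bundle <- function(outdir, seed = 1L, n_sites = 200L,
                                 motif = "ACGTTAGC", spacing = 200L,
                                 genome_bp = 2e5, effects = NULL,
                                 n_samples = 50L) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  truth <- make_truth_tables(seed)
  g0 <- generate_genome(1L, genome_bp, gc = 0.4, seed = seed)
  pl <- plant_sites(g0, motif, n_sites, spacing, seed = seed)
  regions <- pl$accessible
  d0 <- simulate_damage(pl$genome, regions, truth, effects, pl$sites,
                        seed = seed, timepoint = "0h")
  d6 <- simulate_repair(d0, pl$genome, truth, effects, pl$sites,
                        seed = seed, timepoint = "6h")
  d64 <- simulate_damage(pl$genome, regions, truth, NULL, NULL,
                         seed = seed + 1L, lesion_type = "64PP",
                         dose_scale = 0.5)
  mut <- simulate_mutations(pl$genome, regions, truth, pl$sites,
                            n_samples = n_samples, seed = seed)
  paths <- c(genome = "genome.fa", sites = "sites.bed",
             accessible = "accessible.bed", cpd_0h = "cpd_0h.bed",
             cpd_6h = "cpd_6h.bed", pp64 = "pp64_0h.bed",
             mutations = "mutations.tsv", truth = "truth.json")
  full <- file.path(outdir, paths)
  names(full) <- names(paths)
  write_genome_fasta(pl$genome, full[["genome"]])
  write_sites_bed(pl$sites, full[["sites"]])
  readr::write_tsv(tibble::tibble(chrom = regions$chrom,
                                  start = regions$start,
                                  end = regions$end),
                   full[["accessible"]], col_names = FALSE,
                   progress = FALSE)
  write_damage_bed(d0, full[["cpd_0h"]])
  write_damage_bed(d6, full[["cpd_6h"]])
  write_damage_bed(d64, full[["pp64"]])
  write_mutations_tsv(mut, full[["mutations"]])
  jsonlite::write_json(list(hexamer = truth$hexamer, nyyn = truth$nyyn,
                            trinuc = truth$trinuc),
                       full[["truth"]], digits = NA)
  manifest <- tibble::tibble(file = unname(paths), role = names(paths),
                             seed = seed)
  readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"),
                   progress = FALSE)
  manifest
}
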
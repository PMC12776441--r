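# Multi-cluster synthetic studies: one genome carrying a large accessible
# background plus per-cluster planted site sets, one shared rate table —
# the same topology as a real damage-map study, at desk scale.

#' Synthesize a multi-cluster binding-site study
#'
#' Builds one genome containing (i) accessible background chromosomes and
#' (ii) one chromosome per motif cluster with `n_sites` planted sites in
#' 150-bp accessible windows.  Each cluster gets its own consensus motif
#' (random 8-mers with a central TT by default, so every cluster has a
#' testable dipyrimidine at motif position -1), mirroring the fact that
#' context rates are estimated once over all accessible DNA while each
#' TF contributes only a small fraction of any k-mer's occurrences.
#'
#' @param seed Master seed.
#' @param n_clusters Number of motif clusters.
#' @param n_sites Sites per cluster.
#' @param motifs Optional character vector of consensus motifs (recycled);
#'   default random per cluster.
#' @param spacing Site spacing on cluster chromosomes (bp).
#' @param background_bp Total accessible background sequence (bp),
#'   split into chromosomes of at most 2 Mb.
#' @param gc GC content.
#' @param truth Optional `uvf_truth`; default [make_truth_tables()] from
#'   the seed.
#' @return List with `genome`, `truth`, `clusters` (per cluster: `sites`,
#'   `windows`, `motif`), `accessible` (background + all windows),
#'   `background` (background chromosomes only), and `loci` (the
#'   dipyrimidine locus table over `accessible`, cached for reuse).
#' @export
synthesize_study <- function(seed = 1L, n_clusters = 1L, n_sites = 2000L,
                             motifs = NULL, spacing = 200L,
                             background_bp = 6e6, gc = 0.4,
                             truth = NULL) {
  set.seed(substream_seed(seed, "study"))
  if (is.null(motifs)) {
    motifs <- vapply(seq_len(n_clusters), function(i) {
      b <- sample(c("A", "C", "G", "T"), 8L, replace = TRUE)
      b[4:5] <- c("T", "T")
      paste(b, collapse = "")
    }, character(1))
  }
  motifs <- rep_len(motifs, n_clusters)
  n_bg <- max(1L, ceiling(background_bp / 2e6))
  bg_len <- rep(floor(background_bp / n_bg), n_bg)
  margin <- 150L
  cl_len <- n_sites * spacing + 2L * margin
  genome <- generate_genome(n_bg + n_clusters,
                            c(bg_len, rep(cl_len, n_clusters)),
                            gc = gc, seed = substream_seed(seed, "geno"))
  nms <- c(paste0("bg", seq_len(n_bg)), paste0("cl", seq_len(n_clusters)))
  genome <- genome_sequence(stats::setNames(unclass(genome), nms))
  clusters <- vector("list", n_clusters)
  for (i in seq_len(n_clusters)) {
    pl <- plant_sites(genome, motifs[i], n_sites, spacing,
                      seed = substream_seed(seed, paste0("plant", i)),
                      chrom = paste0("cl", i),
                      cluster_id = paste0("cluster", i))
    genome <- pl$genome
    clusters[[i]] <- list(sites = pl$sites, windows = pl$accessible,
                          motif = motifs[i])
  }
  background <- genomic_intervals(paste0("bg", seq_len(n_bg)), 0, bg_len)
  accessible <- dplyr::bind_rows(c(list(background),
                                   lapply(clusters, `[[`, "windows")))
  accessible <- genomic_intervals(accessible)
  if (is.null(truth)) truth <- make_truth_tables(seed)
  loci <- enumerate_dipyrimidine_loci(genome, accessible, 2L)
  list(genome = genome, truth = truth, clusters = clusters,
       accessible = accessible, background = background, loci = loci)
}

#' Formation analysis of every cluster of a synthetic study
#'
#' Runs the full formation pipeline at study scale: simulates a damage
#' map over all accessible regions (planted effects applied to the
#' requested cluster), estimates the hexanucleotide rate table once from
#' all accessible DNA, and tests every cluster's per-position profile.
#'
#' @param study A [synthesize_study()] result.
#' @param effects Optional [planted_effect()] tibble.
#' @param effect_cluster Index of the cluster the effects apply to.
#' @param seed Seed for the damage simulation.
#' @param window Window half-width.
#' @param threshold Significance threshold on q.
#' @param lesion_type,dose_scale Passed to [simulate_damage()].
#' @return List with `map`, `rates`, and `tests` (one
#'   `uvf_profile_test` per cluster).
#' @export
analyze_formation <- function(study, effects = NULL, effect_cluster = 1L,
                              seed = 1L, window = 40L, threshold = 0.05,
                              lesion_type = "CPD", dose_scale = 1) {
  eff_sites <- if (!is.null(effects))
    study$clusters[[effect_cluster]]$sites else NULL
  loci <- study$loci %||%
    enumerate_dipyrimidine_loci(study$genome, study$accessible, 2L)
  map <- simulate_damage(study$genome, study$accessible, study$truth,
                         effects = effects, sites = eff_sites,
                         seed = seed, lesion_type = lesion_type,
                         dose_scale = dose_scale, loci = loci)
  rates <- estimate_context_rates(map, study$genome, study$accessible,
                                  k_flank = 2L, loci = loci)
  tests <- lapply(study$clusters, function(cl) {
    obs <- observed_profile(cl$sites, map, window)
    expc <- expected_profile(cl$sites, study$genome, rates, window)
    prof <- flank_scale(obs, expc, motif_length(cl$sites))
    poisson_position_test(prof, threshold)
  })
  names(tests) <- vapply(study$clusters,
                         function(cl) cluster_id(cl$sites), character(1))
  list(map = map, rates = rates, tests = tests)
}
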
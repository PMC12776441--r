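# Declarative end-to-end orchestration: a YAML/list config, staged
# execution with cached upstream artifacts, TSV outputs and JSON
# provenance records (inputs, parameters, seed, version — no timestamps,
# so fixed seeds give byte-identical reruns).

PIPELINE_STAGES <- c("simulate", "background", "formation", "repair",
                     "mutations", "structure", "report")

#' Validate a pipeline run configuration
#'
#' @param config A list or path to a YAML file with entries `paths`
#'   (genome, damage maps, sites, ...), `curation` (see
#'   [curation_config()]), `seed`, and optional `n_iter`, `n_boot`,
#'   `norm_factor`.
#' @return The validated config list (with `curation` instantiated).
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config needs a seed", call. = FALSE)
  cur <- do.call(curation_config, config$curation %||% list())
  config$curation <- cur
  for (p in unlist(config$paths)) {
    if (!file.exists(p)) {
      stop("configured file does not exist: ", p, call. = FALSE)
    }
  }
  config$n_iter <- config$n_iter %||% 1000L
  config$n_boot <- config$n_boot %||% 10000L
  config$norm_factor <- config$norm_factor %||% 1
  config
}

.provenance <- function(outdir, stage, inputs, params, seed) {
  rec <- list(stage = stage, inputs = inputs, params = params,
              seed = seed,
              version = as.character(utils::packageVersion("uvfootprint")))
  jsonlite::write_json(rec, file.path(outdir, paste0(stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

.need_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing upstream artifact ", path, "; run stage '", producer,
         "' first", call. = FALSE)
  }
  path
}

.write_profile_tsv <- function(profile, path) {
  readr::write_tsv(tibble::as_tibble(profile), path, progress = FALSE)
}

#' Run pipeline stages
#'
#' Executes the requested stages in canonical order, writing each
#' stage's tables and a JSON provenance record under
#' `outdir/<stage>/`.  Later stages read upstream artifacts from
#' `outdir`, so a single stage can be rerun against cached inputs; a
#' missing upstream artifact raises an error naming the stage to run
#' first.
#'
#' @param config Config list or YAML path (see [validate_run_config()]).
#' @param stages Character vector of stages among `simulate`,
#'   `background`, `formation`, `repair`, `mutations`, `structure`,
#'   `report`.
#' @param outdir Output directory.
#' @return Invisibly, a manifest tibble of written files.
#' @export
run_pipeline <- function(config, stages = PIPELINE_STAGES,
                         outdir = "uvfootprint_run") {
  config <- validate_run_config(config)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  written <- character(0)
  seed <- config$seed
  cur <- config$curation

  sd <- function(stage) file.path(outdir, stage)
  fixture_path <- function(file) {
    # prefer explicitly configured paths, else the simulate stage output
    file.path(sd("simulate"), file)
  }
  path_of <- function(key, fallback_file, producer = "simulate") {
    p <- config$paths[[key]]
    if (!is.null(p)) return(p)
    .need_artifact(fixture_path(fallback_file), producer)
  }

  for (stage in stages) {
    t0 <- Sys.time()
    message("[uvfootprint] stage ", stage, " ...")
    dir.create(sd(stage), showWarnings = FALSE)

    if (stage == "simulate") {
      man <- write_fixture_bundle(sd(stage), seed = seed,
                                  n_sites = config$simulate$n_sites %||%
                                    500L,
                                  motif = config$simulate$motif %||%
                                    "ACGTTAGC",
                                  genome_bp = config$simulate$genome_bp %||%
                                    5e5,
                                  n_samples = config$simulate$n_samples %||%
                                    100L)
      written <- c(written, file.path(sd(stage), man$file))
      .provenance(sd(stage), stage, list(), config$simulate %||% list(),
                  seed)
    }

    if (stage == "background") {
      genome <- read_genome_fasta(path_of("genome", "genome.fa"))
      acc <- .read_bed3(path_of("accessible", "accessible.bed"))
      regions <- acc
      if (!is.null(config$paths$genic)) {
        regions <- subtract_intervals(regions,
                                      .read_bed3(config$paths$genic))
      }
      map <- read_damage_bed(path_of("cpd_0h", "cpd_0h.bed"), genome,
                             "CPD", "0h")
      if (!is.null(config$paths$blacklist)) {
        map <- filter_blacklist(map, .read_bed3(config$paths$blacklist))
      }
      rates <- estimate_context_rates(map, genome, regions,
                                      k_flank = 2L)
      write_rate_table(rates, file.path(sd(stage), "rates_cpd.tsv"))
      readr::write_tsv(tibble::as_tibble(regions)[
        , c("chrom", "start", "end")],
        file.path(sd(stage), "background_regions.tsv"), progress = FALSE)
      written <- c(written, file.path(sd(stage), "rates_cpd.tsv"))
      .provenance(sd(stage), stage,
                  list(genome = basename(path_of("genome", "genome.fa"))),
                  list(k_flank = 2), seed)
    }

    if (stage == "formation") {
      genome <- read_genome_fasta(path_of("genome", "genome.fa"))
      rates <- read_rate_table(
        .need_artifact(file.path(sd("background"), "rates_cpd.tsv"),
                       "background"))
      acc <- .read_bed3(path_of("accessible", "accessible.bed"))
      sites <- read_sites_bed(path_of("sites", "sites.bed"))
      map <- read_damage_bed(path_of("cpd_0h", "cpd_0h.bed"), genome,
                             "CPD", "0h")
      sites <- curate_active_sites(sites, acc, cur)
      obs <- observed_profile(sites, map, cur$window)
      if (!cluster_sufficient(obs, cur$min_aggregate)) {
        uvf_inform("formation: cluster below the aggregate-damage floor")
      }
      exp <- expected_profile(sites, genome, rates, cur$window)
      prof <- flank_scale(obs, exp, motif_length(sites), cur$span_pad)
      test <- poisson_position_test(prof, cur$threshold)
      .write_profile_tsv(test, file.path(sd(stage), "formation_cpd.tsv"))
      written <- c(written, file.path(sd(stage), "formation_cpd.tsv"))
      .provenance(sd(stage), stage, list(sites = cluster_id(sites)),
                  list(window = cur$window,
                       threshold = cur$threshold), seed)
    }

    if (stage == "repair") {
      genome <- read_genome_fasta(path_of("genome", "genome.fa"))
      acc <- .read_bed3(path_of("accessible", "accessible.bed"))
      sites <- curate_active_sites(
        read_sites_bed(path_of("sites", "sites.bed")), acc, cur)
      map0 <- read_damage_bed(path_of("cpd_0h", "cpd_0h.bed"), genome,
                              "CPD", "0h")
      mapt <- read_damage_bed(path_of("cpd_6h", "cpd_6h.bed"), genome,
                              "CPD", "6h")
      res <- bootstrap_unrepaired_test(
        sites, map0, mapt, genome, acc, window = cur$repair_window,
        n_boot = config$n_boot, seed = substream_seed(seed, "repair"),
        norm_factor = config$norm_factor)
      out <- tibble::as_tibble(res)
      out$composition <- vapply(out$composition, function(cc) {
        paste(names(cc), cc, sep = ":", collapse = ";")
      }, character(1))
      .write_profile_tsv(out, file.path(sd(stage), "repair_cpd.tsv"))
      eff <- repair_efficiency_by_context(map0, mapt, genome, acc,
                                          norm_factor =
                                            config$norm_factor)
      .write_profile_tsv(eff, file.path(sd(stage), "efficiency.tsv"))
      written <- c(written, file.path(sd(stage), "repair_cpd.tsv"),
                   file.path(sd(stage), "efficiency.tsv"))
      .provenance(sd(stage), stage, list(),
                  list(n_boot = config$n_boot,
                       norm_factor = config$norm_factor), seed)
    }

    if (stage == "mutations") {
      genome <- read_genome_fasta(path_of("genome", "genome.fa"))
      acc <- .read_bed3(path_of("accessible", "accessible.bed"))
      sites <- curate_active_sites(
        read_sites_bed(path_of("sites", "sites.bed")), acc, cur)
      muts <- read_mutations_tsv(path_of("mutations", "mutations.tsv"),
                                 genome)
      map <- read_damage_bed(path_of("cpd_0h", "cpd_0h.bed"), genome,
                             "CPD", "0h")
      shuf <- trinucleotide_shuffle_test(muts, acc, genome, sites,
                                         window = cur$window,
                                         n_iter = config$n_iter,
                                         seed = substream_seed(seed,
                                                               "mut"))
      proj <- project_mutations(map, genome, sites, cur$window)
      act <- actual_mutation_profile(muts, genome, sites, cur$window)
      conc <- concordance(proj, act)
      .write_profile_tsv(shuf, file.path(sd(stage), "mutation_test.tsv"))
      .write_profile_tsv(
        dplyr::inner_join(proj, act, by = "position") |>
          dplyr::left_join(conc$positions[
            , c("position", "residual_z", "discordant")],
            by = "position"),
        file.path(sd(stage), "projection.tsv"))
      written <- c(written, file.path(sd(stage), "mutation_test.tsv"),
                   file.path(sd(stage), "projection.tsv"))
      .provenance(sd(stage), stage, list(),
                  list(n_iter = config$n_iter, r = conc$r,
                       slope = conc$slope), seed)
    }

    if (stage == "structure") {
      man <- config$paths$structures
      if (is.null(man)) {
        uvf_inform("structure: no structure manifest configured; skipped")
      } else {
        sm <- readr::read_tsv(man, col_types = "ccc", progress = FALSE)
        geo <- purrr::pmap_dfr(sm, function(file, state, chain, ...) {
          dipyrimidine_geometry(load_structure(file), chain,
                                state = state)
        })
        .write_profile_tsv(geo, file.path(sd(stage), "geometry.tsv"))
        cmp <- compare_states(geo[geo$state == "bound", ],
                              geo[geo$state == "unbound", ])
        .write_profile_tsv(cmp, file.path(sd(stage),
                                          "state_comparison.tsv"))
        written <- c(written, file.path(sd(stage), "geometry.tsv"))
        .provenance(sd(stage), stage, list(manifest = basename(man)),
                    list(), seed)
      }
    }

    if (stage == "report") {
      ftest <- .need_artifact(file.path(sd("formation"),
                                        "formation_cpd.tsv"), "formation")
      prof <- readr::read_tsv(ftest, col_types = readr::cols(),
                              progress = FALSE)
      zmat <- signed_z_matrix(list(cluster = prof))
      readr::write_tsv(tidyr::pivot_wider(zmat, names_from = "position",
                                          values_from = "z"),
                       file.path(sd(stage), "formation_z_matrix.tsv"),
                       progress = FALSE)
      written <- c(written,
                   file.path(sd(stage), "formation_z_matrix.tsv"))
      .provenance(sd(stage), stage,
                  list(formation = basename(ftest)), list(), seed)
    }

    message("[uvfootprint] stage ", stage, " done (",
            round(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  1), "s)")
  }
  invisible(tibble::tibble(file = written))
}

.read_bed3 <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                        col_types = readr::cols())
  genomic_intervals(df[[1]], df[[2]], df[[3]])
}
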
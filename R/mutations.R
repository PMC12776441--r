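#' Somatic mutation tables
#'
#' Single-base substitutions as a tibble with columns `chrom`, `pos`
#' (0-based), `ref`, `alt`, `sample`.  Mutations are supplied as headered
#' TSV rather than VCF; `ref` is validated against the genome on load and
#' mismatching records are dropped with a logged count.
#'
#' @param records Data frame with the five columns above.
#' @param genome Optional `uvf_genome` for reference validation.
#' @return A tibble of class `uvf_mutations`.
#' @export
mutation_table <- function(records, genome = NULL) {
  cols <- c("chrom", "pos", "ref", "alt", "sample")
  if (!all(cols %in% names(records))) {
    stop("mutation table needs columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  m <- tibble::as_tibble(records)[, cols]
  if (nrow(m)) {
    if (any(m$ref == m$alt)) stop("ref must differ from alt", call. = FALSE)
    if (!is.null(genome)) {
      obs <- genome_base(genome, m$chrom, m$pos)
      bad <- obs != m$ref
      if (any(bad)) {
        uvf_inform(paste0("mutation_table: dropped ", sum(bad),
                          " record(s) with ref mismatching the genome"))
        m <- m[!bad, , drop = FALSE]
      }
    }
    m <- dplyr::arrange(m, .data$chrom, .data$pos, .data$sample)
  }
  structure(m, class = c("uvf_mutations", class(tibble::tibble())))
}

#' Read/write mutations as headered TSV
#' @param path File path.
#' @param genome Optional `uvf_genome` for reference validation.
#' @return A `uvf_mutations` table.
#' @export
read_mutations_tsv <- function(path, genome = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_double(),
    ref = readr::col_character(), alt = readr::col_character(),
    sample = readr::col_character()), progress = FALSE)
  mutation_table(df, genome = genome)
}

#' @rdname read_mutations_tsv
#' @param mutations A `uvf_mutations` table to write.
#' @export
write_mutations_tsv <- function(mutations, path) {
  out <- dplyr::arrange(tibble::as_tibble(mutations),
                        .data$chrom, .data$pos, .data$sample)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Keep pyrimidine-strand C>T substitutions
#'
#' C>T on the plus reference strand and G>A on the minus reference strand
#' are both C>T events on the pyrimidine strand; both are retained and
#' labelled with the pyrimidine strand.
#'
#' @param mutations A `uvf_mutations` table.
#' @return The subset with an added `pyr_strand` column.
#' @export
filter_c_to_t <- function(mutations) {
  ct <- mutations$ref == "C" & mutations$alt == "T"
  ga <- mutations$ref == "G" & mutations$alt == "A"
  out <- mutations[ct | ga, , drop = FALSE]
  out$pyr_strand <- ifelse(out$ref == "C", "+", "-")
  .keep_attrs(out, mutations)
}
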
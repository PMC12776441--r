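#' Genome sequence container
#'
#' A genome is stored as a named character vector of uppercase chromosome
#' sequences over the alphabet A, C, G, T, N.  [read_genome_fasta()] and
#' [write_genome_fasta()] round-trip FASTA through Biostrings.
#'
#' @param sequences Named character vector (or named list) of sequences.
#' @return An object of class `uvf_genome`.
#' @export
genome_sequence <- function(sequences) {
  sequences <- unlist(sequences)
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == "")) {
    stop("all chromosomes must be named", call. = FALSE)
  }
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("non-IUPAC-core letters in chromosome(s): ",
         paste(names(sequences)[bad], collapse = ", "), call. = FALSE)
  }
  structure(sequences, class = "uvf_genome")
}

#' @export
print.uvf_genome <- function(x, ...) {
  cat("<uvf_genome> ", length(x), " chromosome(s), ",
      format(sum(nchar(x)), big.mark = ","), " bp total\n", sep = "")
  for (nm in utils::head(names(x), 6)) {
    cat("  ", nm, ": ", format(nchar(x[[nm]]), big.mark = ","), " bp\n",
        sep = "")
  }
  if (length(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome A `uvf_genome`.
#' @return Named integer vector of lengths.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(nchar(unclass(genome)), names(genome))
}

#' Read a genome from FASTA
#'
#' Lowercase letters are folded to uppercase; any letter outside A,C,G,T,N
#' is an error.  Parsing is delegated to [Biostrings::readDNAStringSet()].
#'
#' @param path FASTA file path.
#' @return A [genome_sequence()] object.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) {
                   stop("FASTA parse error in ", path, ": ",
                        conditionMessage(e), call. = FALSE)
                 })
  if (length(ss) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  # keep the first whitespace-delimited token of each header
  nms <- sub("\\s.*$", "", names(ss))
  genome_sequence(stats::setNames(as.character(ss), nms))
}

#' @rdname read_genome_fasta
#' @param genome A `uvf_genome`.
#' @param width Line width for sequence wrapping.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Look up bases at 0-based positions
#'
#' @param genome A `uvf_genome`.
#' @param chrom,pos Equal-length vectors of chromosome names and 0-based
#'   positions.
#' @return Character vector of single bases.
#' @export
genome_base <- function(genome, chrom, pos) {
  lens <- chrom_lengths(genome)
  if (any(!chrom %in% names(lens))) {
    stop("unknown chromosome(s): ",
         paste(unique(setdiff(chrom, names(lens))), collapse = ", "),
         call. = FALSE)
  }
  if (any(pos < 0 | pos >= lens[chrom])) stop("position out of range",
                                              call. = FALSE)
  substring(unclass(genome)[chrom], pos + 1, pos + 1)
}

#' Extract the damaged-strand sequence context around a dipyrimidine
#'
#' Returns the `2*k_flank + 2`-mer read 5'->3' on the damaged strand, whose
#' central two bases are the dipyrimidine.  `pos5` is the 0-based reference
#' coordinate of the 5'-most base of the dipyrimidine *on the damaged
#' strand*: for a minus-strand lesion this is the higher of the two
#' reference coordinates.  Windows that cross a chromosome boundary or
#' contain N return `NA` (the "unavailable" sentinel; callers skip the
#' locus).
#'
#' @param genome A `uvf_genome`.
#' @param chrom,strand,pos5 Equal-length vectors describing the loci;
#'   `strand` in `"+"`/`"-"`.
#' @param k_flank Flank width, 1 (NYYN) or 2 (NNYYNN).
#' @return Character vector of contexts (`NA` where unavailable).
#' @export
extract_context <- function(genome, chrom, strand, pos5, k_flank = 2L) {
  stopifnot(k_flank %in% c(1L, 2L), all(strand %in% c("+", "-")))
  n <- max(length(chrom), length(strand), length(pos5))
  chrom <- rep_len(chrom, n); strand <- rep_len(strand, n)
  pos5 <- rep_len(as.numeric(pos5), n)
  lens <- chrom_lengths(genome)
  if (any(!chrom %in% names(lens))) {
    stop("unknown chromosome(s): ",
         paste(unique(setdiff(chrom, names(lens))), collapse = ", "),
         call. = FALSE)
  }
  plus <- strand == "+"
  lo <- ifelse(plus, pos5 - k_flank, pos5 - 1 - k_flank)
  hi <- ifelse(plus, pos5 + 1 + k_flank, pos5 + k_flank)
  out <- rep(NA_character_, n)
  ok <- lo >= 0 & hi < lens[chrom]
  if (any(ok)) {
    raw <- substring(unclass(genome)[chrom[ok]], lo[ok] + 1, hi[ok] + 1)
    mi <- !plus[ok]
    raw[mi] <- revcomp(raw[mi])
    raw[grepl("N", raw, fixed = TRUE)] <- NA_character_
    out[ok] <- raw
  }
  out
}
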
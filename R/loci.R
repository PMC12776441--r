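# Fast enumeration of context-classified loci inside region sets.
#
# These enumerations back rate estimation (occurrence counts), damage
# simulation, zero-count reconstruction for distributional checks, and the
# context-preserving shuffle nulls.  Sequences are encoded as integer base
# codes once per chromosome; context indices are built by rolling base-4
# sums, so no per-locus string operations happen on hot paths.

#' Enumerate dipyrimidine loci with their sequence contexts
#'
#' Lists every locus whose central dipyrimidine (both bases) lies inside
#' the merged `regions`, on both strands.  The context is the
#' `2*k_flank+2`-mer read 5'->3' on the damaged strand; flanks may extend
#' past a region edge into the genome but not past a chromosome end.  Loci
#' whose context window contains N or crosses a chromosome boundary carry
#' `ctx = NA` and are excluded from rate estimation by callers.
#'
#' @param genome A `uvf_genome`.
#' @param regions Interval table.
#' @param k_flank Flank width (1 = NYYN, 2 = NNYYNN).
#' @return Tibble with columns `chrom`, `strand`, `pos5` (damaged-strand
#'   5'-base convention), `ctx` (integer k-mer index, see
#'   [kmer_to_index()]).
#' @export
enumerate_dipyrimidine_loci <- function(genome, regions, k_flank = 2L) {
  stopifnot(k_flank %in% c(1L, 2L))
  red <- reduce_intervals(regions)
  parts <- list()
  for (chr in intersect(names(genome), unique(red$chrom))) {
    rr <- red[red$chrom == chr, , drop = FALSE]
    code <- .encode_seq(unclass(genome)[[chr]])
    tr <- .kmer_tracks(code, k_flank)
    # candidate lower coordinates: both dinucleotide bases inside a region
    len <- rr$end - 1 - rr$start
    len[len < 0] <- 0
    if (all(len == 0)) next
    p <- sequence(len, from = rr$start + 1L)  # 1-based R index of lower coord
    pl <- tr$plus_ok[p]
    mi <- tr$minus_ok[p]
    parts[[chr]] <- tibble::tibble(
      chrom = chr,
      strand = c(rep("+", sum(pl)), rep("-", sum(mi))),
      pos5 = c(p[pl] - 1L, p[mi]),  # minus: 5' base is the higher coord
      ctx = as.integer(round(c(tr$plus[p][pl], tr$minus[p][mi]))))
  }
  if (length(parts) == 0L) {
    return(tibble::tibble(chrom = character(0), strand = character(0),
                          pos5 = integer(0), ctx = integer(0)))
  }
  dplyr::bind_rows(parts)
}

#' Enumerate cytosine loci with trinucleotide contexts
#'
#' Lists every cytosine on either strand inside the merged regions, with
#' the pyrimidine-strand trinucleotide context (NCN) as an integer index.
#' Minus-strand cytosines appear as reference G; their context is the
#' reverse complement of the reference trinucleotide.
#'
#' @inheritParams enumerate_dipyrimidine_loci
#' @return Tibble with `chrom`, `strand` (pyrimidine strand), `pos`
#'   (0-based reference coordinate of the C), `ctx` (trinucleotide index).
#' @export
enumerate_cytosine_loci <- function(genome, regions) {
  red <- reduce_intervals(regions)
  parts <- list()
  for (chr in intersect(names(genome), unique(red$chrom))) {
    rr <- red[red$chrom == chr, , drop = FALSE]
    code <- .encode_seq(unclass(genome)[[chr]])
    n <- length(code)
    coded <- as.numeric(code)
    comp <- 3 - coded
    shift_vec <- function(v, off) {
      if (off >= 0) c(v[(off + 1):n], rep(NA_real_, off))
      else c(rep(NA_real_, -off), v[1:(n + off)])
    }
    plus3 <- shift_vec(coded, -1L) * 16 + coded * 4 + shift_vec(coded, 1L)
    minus3 <- shift_vec(comp, 1L) * 16 + comp * 4 + shift_vec(comp, -1L)
    len <- rr$end - rr$start
    p <- sequence(len, from = rr$start + 1L)
    isC <- !is.na(code[p]) & code[p] == 1L
    isG <- !is.na(code[p]) & code[p] == 2L
    parts[[chr]] <- tibble::tibble(
      chrom = chr,
      strand = c(rep("+", sum(isC)), rep("-", sum(isG))),
      pos = c(p[isC] - 1L, p[isG] - 1L),
      ctx = as.integer(round(c(plus3[p][isC], minus3[p][isG]))))
  }
  if (length(parts) == 0L) {
    return(tibble::tibble(chrom = character(0), strand = character(0),
                          pos = integer(0), ctx = integer(0)))
  }
  dplyr::bind_rows(parts)
}

# central dinucleotide (string) of a context index
dinuc_from_ctx <- function(ctx, k_flank) {
  L <- 2L * k_flank + 2L
  hi <- (ctx %/% 4^(k_flank)) %% 16
  out <- rep(NA_character_, length(ctx))
  ok <- !is.na(ctx)
  bases <- c("A", "C", "G", "T")
  out[ok] <- paste0(bases[(hi[ok] %/% 4) + 1L], bases[(hi[ok] %% 4) + 1L])
  out
}
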
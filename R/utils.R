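# Internal utilities: seed substreams, k-mer encoding, logging.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible substream seed from a master seed
#'
#' All stochastic stages draw their seed from one master seed plus a stage
#' name, so stages are independently reproducible and re-running one stage
#' never perturbs another.
#'
#' @param master Integer master seed.
#' @param name Character stage name (e.g. `"damage"`, `"repair"`).
#' @return A single integer in `[0, 2^31)`.
#' @export
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(master) %% 2147483647 * 48271 + h) %% 2147483647)
}

# base codes: A=0, C=1, G=2, T=3; anything else NA
.code_lut <- local({
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("a")] <- 0L
  lut[utf8ToInt("C")] <- 1L; lut[utf8ToInt("c")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("g")] <- 2L
  lut[utf8ToInt("T")] <- 3L; lut[utf8ToInt("t")] <- 3L
  lut
})

.encode_seq <- function(s) .code_lut[utf8ToInt(s)]

.decode_codes <- function(codes) {
  out <- rep("N", length(codes))
  ok <- !is.na(codes)
  out[ok] <- c("A", "C", "G", "T")[codes[ok] + 1L]
  paste(out, collapse = "")
}

.is_pyr <- function(code) !is.na(code) & (code == 1L | code == 3L)
.is_pur <- function(code) !is.na(code) & (code == 0L | code == 2L)

#' Convert k-mer strings to integer indices and back
#'
#' Big-endian base-4 encoding over the alphabet A,C,G,T (A=0 ... T=3).
#' Strings containing other letters map to `NA`.
#'
#' @param kmer Character vector of equal-length k-mers.
#' @return Integer vector of indices in `[0, 4^L)`.
#' @export
kmer_to_index <- function(kmer) {
  if (length(kmer) == 0L) return(integer(0))
  L <- unique(nchar(kmer))
  stopifnot(length(L) == 1L)
  m <- matrix(.code_lut[utf8ToInt(paste(kmer, collapse = ""))],
              nrow = L)
  as.integer(colSums(m * 4^((L - 1):0)))
}

#' @rdname kmer_to_index
#' @param index Integer indices.
#' @param width K-mer length.
#' @export
index_to_kmer <- function(index, width) {
  bases <- c("A", "C", "G", "T")
  out <- rep(NA_character_, length(index))
  ok <- which(!is.na(index))
  if (length(ok)) {
    digs <- vapply((width - 1):0, function(p) (index[ok] %/% 4^p) %% 4,
                   numeric(length(ok)))
    digs <- matrix(digs, nrow = length(ok))
    out[ok] <- apply(digs, 1L, function(d) paste(bases[d + 1L], collapse = ""))
  }
  out
}

#' Enumerate all pyrimidine-centered k-mers
#'
#' Contexts have the form N..YY..N with the two central bases pyrimidines
#' (C or T): 64 tetranucleotides (`k_flank = 1`) or 1,024 hexanucleotides
#' (`k_flank = 2`).
#'
#' @param k_flank Number of flanking bases on each side (1 or 2).
#' @return Sorted character vector of k-mers.
#' @export
all_pyrimidine_kmers <- function(k_flank) {
  stopifnot(k_flank %in% c(1L, 2L))
  bases <- c("A", "C", "G", "T")
  pyr <- c("C", "T")
  flank <- do.call(paste0, rev(expand.grid(rep(list(bases), k_flank),
                                           stringsAsFactors = FALSE)))
  cen <- do.call(paste0, expand.grid(pyr, pyr, stringsAsFactors = FALSE))
  out <- as.vector(outer(flank, outer(cen, flank, paste0), paste0))
  sort(out)
}

# reverse-complement for character vectors (API path; hot paths use codes)
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# condition-classed messages so callers/tests can suppress or capture
uvf_inform <- function(msg, class = "uvf_log") {
  rlang::inform(msg, class = class)
}

# Rolling context-index tracks over one chromosome's code vector.
# plus[p]  : context index for a + strand lesion whose 5' base is 0-based p
#            (R index p+1); window [p-k, p+1+k].
# minus[q] : context index for a - strand lesion whose dinucleotide occupies
#            reference coordinates (q, q+1); read 5'->3' on the minus strand
#            this is the reverse complement of reference window [q-k, q+1+k].
# Neither track checks the dipyrimidine constraint; N or out-of-range -> NA.
.kmer_tracks <- function(code, k_flank) {
  n <- length(code)
  L <- 2L * k_flank + 2L
  shift_vec <- function(v, off) {
    # value at position i of result = v[i + off] (0-based offsets)
    if (off >= 0) c(v[(off + 1):n], rep(NA_real_, off))
    else c(rep(NA_real_, -off), v[1:(n + off)])
  }
  coded <- as.numeric(code)
  comp <- 3 - coded
  plus <- numeric(n); minus <- numeric(n)
  for (j in 0:(L - 1L)) {
    w <- 4^(L - 1L - j)
    plus <- plus + shift_vec(coded, j - k_flank) * w
    minus <- minus + shift_vec(comp, 1L + k_flank - j) * w
  }
  pyr <- coded == 1 | coded == 3
  pur <- coded == 0 | coded == 2
  nxt <- shift_vec
  plus_ok <- pyr & nxt(as.numeric(pyr), 1L) == 1
  minus_ok <- pur & nxt(as.numeric(pur), 1L) == 1
  list(plus = plus, minus = minus,
       plus_ok = !is.na(plus_ok) & plus_ok,
       minus_ok = !is.na(minus_ok) & minus_ok)
}
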
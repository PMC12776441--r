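#' Log-odds PWM scoring
#'
#' Scores sequences against a position probability matrix:
#' `score = sum_i log2(p_i(base_i) / bg(base_i))` in bits.  An N base
#' contributes 0.  Used to rank binding-site calls by motif quality.
#'
#' @param pwm 4 x L probability matrix with rownames A, C, G, T (columns
#'   sum to 1), or a consensus string.
#' @param sequence Character vector of sequences, each of length L.
#' @param background Named base composition (defaults to uniform).
#' @return Numeric vector of scores in bits.
#' @export
pwm_log_odds_score <- function(pwm, sequence,
                               background = c(A = 0.25, C = 0.25,
                                              G = 0.25, T = 0.25)) {
  pwm <- .as_pwm(pwm)
  L <- ncol(pwm)
  if (any(nchar(sequence) != L)) {
    stop("sequence length must equal PWM length (", L, ")", call. = FALSE)
  }
  background <- background / sum(background)
  lo <- log2(pwm / background[rownames(pwm)])
  n <- length(sequence)
  if (n == 0L) return(numeric(0))
  m <- matrix(.code_lut[utf8ToInt(paste(toupper(sequence), collapse = ""))],
              nrow = L)
  sc <- numeric(n)
  for (j in seq_len(L)) {
    b <- m[j, ]
    contrib <- ifelse(is.na(b), 0, lo[cbind(b + 1L, j)])
    sc <- sc + contrib
  }
  sc
}

#' Score existing binding sites against a PWM
#'
#' Reads each site's motif-strand sequence from the genome and scores it;
#' useful for (re-)ranking externally supplied site calls.
#'
#' @param sites A `uvf_sites` table.
#' @param genome A `uvf_genome`.
#' @inheritParams pwm_log_odds_score
#' @return The site table with its `score` column replaced.
#' @export
score_sites <- function(sites, genome, pwm,
                        background = c(A = 0.25, C = 0.25,
                                       G = 0.25, T = 0.25)) {
  seqs <- substring(unclass(genome)[sites$chrom], sites$start + 1,
                    sites$end)
  mi <- sites$strand == "-"
  seqs[mi] <- revcomp(seqs[mi])
  sites$score <- pwm_log_odds_score(pwm, seqs, background)
  sites
}
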
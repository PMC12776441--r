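#' Binding-site tables
#'
#' A binding-site set holds motif matches of one motif cluster: columns
#' `chrom`, `start`, `end` (0-based half-open motif interval), `strand`
#' (motif strand) and `score` (log-odds motif score).  All sites share the
#' cluster id and motif length, stored as attributes.  Motif-relative
#' coordinate 0 is the motif center, `floor(motif_length / 2)` bases from
#' the motif 5' end on the motif strand.
#'
#' @param sites Data frame with chrom, start, end, strand, score columns.
#' @param cluster_id Cluster label shared by all sites.
#' @return A tibble of class `uvf_sites`.
#' @export
binding_sites <- function(sites, cluster_id = "cluster") {
  cols <- c("chrom", "start", "end", "strand", "score")
  if (!"score" %in% names(sites)) sites$score <- NA_real_
  if (!all(cols %in% names(sites))) {
    stop("site table needs columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  s <- tibble::as_tibble(sites)[, cols]
  if (nrow(s)) {
    if (!all(s$strand %in% c("+", "-"))) {
      stop("site strand must be + or -", call. = FALSE)
    }
    L <- unique(s$end - s$start)
    if (length(L) != 1L) stop("all sites must share one motif length",
                              call. = FALSE)
  } else {
    L <- 0
  }
  structure(s, class = c("uvf_sites", class(tibble::tibble())),
            cluster_id = cluster_id, motif_length = as.integer(L))
}

#' @export
print.uvf_sites <- function(x, ...) {
  cat("<uvf_sites> cluster ", attr(x, "cluster_id"), ": ", nrow(x),
      " sites, motif length ", attr(x, "motif_length"), "\n", sep = "")
  NextMethod()
}

#' Motif length and cluster id accessors
#' @param sites A `uvf_sites` table.
#' @export
motif_length <- function(sites) attr(sites, "motif_length")

#' @rdname motif_length
#' @export
cluster_id <- function(sites) attr(sites, "cluster_id")

# 0-based reference coordinate of motif-relative position 0 for each site
site_center <- function(sites) {
  L <- motif_length(sites)
  ifelse(sites$strand == "+",
         sites$start + floor(L / 2),
         sites$end - 1 - floor(L / 2))
}

#' Read/write binding sites as BED6
#'
#' Columns: chrom, start, end, name (cluster id), score, strand.
#'
#' @param path File path.
#' @param cluster_id Cluster id; defaults to the first name field.
#' @return A `uvf_sites` table.
#' @export
read_sites_bed <- function(path, cluster_id = NULL) {
  df <- readr::read_tsv(path,
                        col_names = c("chrom", "start", "end", "name",
                                      "score", "strand"),
                        col_types = "cddcdc", progress = FALSE)
  binding_sites(tibble::tibble(chrom = df$chrom, start = df$start,
                               end = df$end, strand = df$strand,
                               score = df$score),
                cluster_id = cluster_id %||%
                  (if (nrow(df)) df$name[[1]] else "cluster"))
}

#' @rdname read_sites_bed
#' @param sites A `uvf_sites` table to write.
#' @export
write_sites_bed <- function(sites, path) {
  out <- tibble::tibble(chrom = sites$chrom, start = sites$start,
                        end = sites$end, name = cluster_id(sites),
                        score = sites$score, strand = sites$strand)
  out <- dplyr::arrange(out, .data$chrom, .data$start, .data$strand)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Map genomic dipyrimidine loci into motif coordinates
#'
#' Given lesion loci (damaged-strand 5'-base convention) and a site table,
#' returns one row per (locus, overlapping site) with the motif-relative
#' position and profile strand.  Positions follow the "i/i+1" convention:
#' the reported position of a dipyrimidine is the *lower* of its two motif
#' coordinates (its 5' base read along the motif strand); minus-strand
#' motif sites are flipped so that their profiles are directly comparable.
#' `profile_strand` is `"motif"` when the damaged strand equals the site's
#' motif strand and `"complement"` otherwise.
#'
#' @param sites A `uvf_sites` table.
#' @param chrom,strand,pos5 Lesion locus vectors (see [extract_context()]).
#' @param window Half-width of the motif-relative window to retain.
#' @return Tibble with columns `locus` (input row), `site` (site row),
#'   `position`, `profile_strand`.
#' @export
map_to_motif_coords <- function(sites, chrom, strand, pos5, window) {
  n <- length(pos5)
  if (n == 0L || nrow(sites) == 0L) {
    return(tibble::tibble(locus = integer(0), site = integer(0),
                          position = numeric(0),
                          profile_strand = character(0)))
  }
  lo <- ifelse(strand == "+", pos5, pos5 - 1)  # lower ref coord of dinuc
  centers <- site_center(sites)
  # window footprint in reference coordinates for each site
  win_lo <- centers - window
  win_hi <- centers + window
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(lo + 1, lo + 2))
  s <- GenomicRanges::GRanges(sites$chrom,
                              IRanges::IRanges(win_lo + 1, win_hi + 1))
  hits <- GenomicRanges::findOverlaps(q, s)
  li <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  plus_site <- sites$strand[si] == "+"
  position <- ifelse(plus_site,
                     lo[li] - centers[si],
                     centers[si] - (lo[li] + 1))
  profile_strand <- ifelse(strand[li] == sites$strand[si],
                           "motif", "complement")
  keep <- position >= -window & position <= window
  tibble::tibble(locus = li[keep], site = si[keep],
                 position = position[keep],
                 profile_strand = profile_strand[keep])
}
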
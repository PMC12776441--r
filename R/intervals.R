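#' Genomic interval tables
#'
#' Intervals are plain tibbles with columns `chrom`, `start`, `end` (0-based
#' half-open, BED-native) and optionally `strand` (`"+"`, `"-"`, `"."`).
#' Set algebra is delegated to GenomicRanges; every operation is
#' strand-blind unless noted, since accessible/genic/blacklist interval sets
#' are unstranded.
#'
#' @param chrom,start,end,strand Vectors (recycled) describing the
#'   intervals, or pass a data frame as the single argument to `chrom`.
#' @return A tibble with class `uvf_intervals` prepended.
#' @export
genomic_intervals <- function(chrom, start = NULL, end = NULL,
                              strand = ".") {
  if (is.data.frame(chrom)) {
    df <- chrom
    if (!all(c("chrom", "start", "end") %in% names(df))) {
      stop("interval table needs chrom, start, end columns", call. = FALSE)
    }
    if (!"strand" %in% names(df)) df$strand <- "."
    return(genomic_intervals(df$chrom, df$start, df$end, df$strand))
  }
  n <- max(length(chrom), length(start), length(end))
  out <- tibble::tibble(chrom = as.character(rep_len(chrom, n)),
                        start = as.numeric(rep_len(start, n)),
                        end = as.numeric(rep_len(end, n)),
                        strand = as.character(rep_len(strand, n)))
  if (any(out$start < 0) || any(out$start >= out$end)) {
    stop("intervals must satisfy 0 <= start < end", call. = FALSE)
  }
  if (!all(out$strand %in% c("+", "-", "."))) {
    stop("strand must be one of + - .", call. = FALSE)
  }
  class(out) <- c("uvf_intervals", class(tibble::tibble()))
  out
}

.empty_intervals <- function() {
  genomic_intervals(character(0), numeric(0), numeric(0), character(0))
}

.gr <- function(x) {
  s <- x$strand %||% rep(".", nrow(x))
  s[s == "."] <- "*"
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(x$start + 1, x$end),
                         strand = s)
}

.from_gr <- function(gr) {
  if (length(gr) == 0L) return(.empty_intervals())
  s <- as.character(GenomicRanges::strand(gr))
  s[s == "*"] <- "."
  out <- genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                           GenomicRanges::start(gr) - 1,
                           GenomicRanges::end(gr), s)
  dplyr::arrange(out, .data$chrom, .data$start, .data$strand)
}

#' Interval set algebra
#'
#' `intersect_intervals()` and `subtract_intervals()` operate on the union
#' of each input (overlaps within one set are merged first);
#' `reduce_intervals()` merges overlapping/adjacent intervals.  All ignore
#' strand.
#'
#' @param x,y Interval tables (see [genomic_intervals()]).
#' @return An interval table, sorted by (chrom, start).
#' @export
intersect_intervals <- function(x, y) {
  if (nrow(x) == 0L || nrow(y) == 0L) return(.empty_intervals())
  .from_gr(GenomicRanges::intersect(.gr(x), .gr(y), ignore.strand = TRUE))
}

#' @rdname intersect_intervals
#' @export
subtract_intervals <- function(x, y) {
  if (nrow(x) == 0L) return(.empty_intervals())
  if (nrow(y) == 0L) return(reduce_intervals(x))
  .from_gr(GenomicRanges::setdiff(.gr(x), .gr(y), ignore.strand = TRUE))
}

#' @rdname intersect_intervals
#' @export
reduce_intervals <- function(x) {
  if (nrow(x) == 0L) return(.empty_intervals())
  .from_gr(GenomicRanges::reduce(.gr(x), ignore.strand = TRUE))
}

#' Total bases covered by an interval table
#' @param x Interval table.
#' @return Numeric total width after merging overlaps.
#' @export
interval_width <- function(x) {
  r <- reduce_intervals(x)
  sum(r$end - r$start)
}

# which of the half-open footprints [start, end) overlap any interval in y
.overlaps_any <- function(chrom, start, end, y) {
  if (length(chrom) == 0L) return(logical(0))
  if (is.null(y) || nrow(y) == 0L) return(rep(FALSE, length(chrom)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  GenomicRanges::countOverlaps(q, .gr(y), ignore.strand = TRUE) > 0
}

#' Remove records overlapping a blacklist
#'
#' Drops every record whose genomic footprint overlaps (half-open) any
#' blacklist interval: the two dipyrimidine bases for damage records, the
#' motif interval for binding sites, the mutated base for mutations, and
#' overlapping portions for interval tables.  An empty blacklist is the
#' identity.
#'
#' @param x A damage map, binding-site set, mutation table or interval
#'   table.
#' @param blacklist Interval table of regions to exclude.
#' @return Object of the same type with offending records removed.
#' @export
filter_blacklist <- function(x, blacklist) {
  UseMethod("filter_blacklist")
}

#' @export
filter_blacklist.uvf_intervals <- function(x, blacklist) {
  subtract_intervals(x, blacklist)
}

#' @export
filter_blacklist.uvf_damage_map <- function(x, blacklist) {
  lo <- ifelse(x$strand == "+", x$pos5, x$pos5 - 1)
  keep <- !.overlaps_any(x$chrom, lo, lo + 2, blacklist)
  n_drop <- sum(!keep)
  if (n_drop > 0) uvf_inform(paste0("filter_blacklist: removed ", n_drop,
                                    " damage record(s)"))
  .keep_attrs(x[keep, , drop = FALSE], x)
}

#' @export
filter_blacklist.uvf_sites <- function(x, blacklist) {
  keep <- !.overlaps_any(x$chrom, x$start, x$end, blacklist)
  .keep_attrs(x[keep, , drop = FALSE], x)
}

#' @export
filter_blacklist.uvf_mutations <- function(x, blacklist) {
  keep <- !.overlaps_any(x$chrom, x$pos, x$pos + 1, blacklist)
  .keep_attrs(x[keep, , drop = FALSE], x)
}

# carry class + uvf_* attributes through a row subset
.keep_attrs <- function(new, old) {
  for (a in setdiff(names(attributes(old)),
                    c("names", "row.names", "class"))) {
    attr(new, a) <- attr(old, a)
  }
  class(new) <- class(old)
  new
}
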
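#' Damage map tables
#'
#' A damage map holds stranded per-locus lesion counts for one lesion type
#' and timepoint: columns `chrom`, `strand` (of the damaged, pyrimidine
#' strand), `pos5` (0-based reference coordinate of the 5'-most base of the
#' dipyrimidine *on the damaged strand*; for minus-strand lesions this is
#' the higher of the two reference coordinates), `dinuc` (TT/TC/CT/CC) and
#' `count`.  Duplicate loci are summed on construction.
#'
#' @param records Data frame with columns chrom, strand, pos5, count and
#'   optionally dinuc.
#' @param lesion_type `"CPD"` or `"64PP"`.
#' @param timepoint Label such as `"0h"`, `"6h"`.
#' @param genome Optional `uvf_genome` used to annotate/validate `dinuc`.
#' @param scale_factor Optional library-scale factor stored as metadata.
#' @return A tibble of class `uvf_damage_map`.
#' @export
damage_map <- function(records, lesion_type = c("CPD", "64PP"),
                       timepoint = "0h", genome = NULL,
                       scale_factor = 1) {
  lesion_type <- match.arg(lesion_type)
  cols <- c("chrom", "strand", "pos5", "count")
  if (!all(cols %in% names(records))) {
    stop("damage records need columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  rec <- tibble::as_tibble(records)[
    , intersect(c(cols, "dinuc"), names(records))]
  if (nrow(rec)) {
    if (any(rec$count < 1) || any(rec$count != round(rec$count))) {
      stop("counts must be integers >= 1", call. = FALSE)
    }
    if (!all(rec$strand %in% c("+", "-"))) {
      stop("damage strand must be + or -", call. = FALSE)
    }
    key <- paste(rec$chrom, rec$strand, rec$pos5)
    if (anyDuplicated(key)) {
      total <- rowsum(rec$count, key)
      first <- !duplicated(key)
      rec <- rec[first, , drop = FALSE]
      rec$count <- unname(total[paste(rec$chrom, rec$strand, rec$pos5),
                                1L])
    }
    if (!"dinuc" %in% names(rec)) rec$dinuc <- NA_character_
    if (!is.null(genome)) {
      ctx <- extract_context(genome, rec$chrom, rec$strand, rec$pos5,
                             k_flank = 1L)
      dn <- ifelse(is.na(ctx),
                   # fall back to the bare dinucleotide when a flank is
                   # unavailable near a chromosome end
                   .bare_dinuc(genome, rec$chrom, rec$strand, rec$pos5),
                   substr(ctx, 2, 3))
      bad <- !dn %in% c("TT", "TC", "CT", "CC")
      if (any(bad)) stop(sum(bad), " record(s) not at dipyrimidines",
                         call. = FALSE)
      rec$dinuc <- dn
    }
    rec <- rec[order(rec$chrom, rec$pos5, rec$strand), , drop = FALSE]
  } else {
    rec$dinuc <- character(0)
  }
  rec <- rec[, c("chrom", "strand", "pos5", "dinuc", "count")]
  structure(rec,
            class = c("uvf_damage_map", class(tibble::tibble())),
            lesion_type = lesion_type, timepoint = timepoint,
            scale_factor = scale_factor)
}

.bare_dinuc <- function(genome, chrom, strand, pos5) {
  lo <- ifelse(strand == "+", pos5, pos5 - 1)
  lens <- chrom_lengths(genome)
  out <- rep(NA_character_, length(chrom))
  ok <- lo >= 0 & lo + 1 < lens[chrom]
  if (any(ok)) {
    s <- substring(unclass(genome)[chrom[ok]], lo[ok] + 1, lo[ok] + 2)
    s[strand[ok] == "-"] <- revcomp(s[strand[ok] == "-"])
    out[ok] <- s
  }
  out
}

#' @export
print.uvf_damage_map <- function(x, ...) {
  cat("<uvf_damage_map> ", attr(x, "lesion_type"), " @ ",
      attr(x, "timepoint"), ": ", nrow(x), " loci, ",
      sum(x$count), " lesions\n", sep = "")
  NextMethod()
}

#' Read a stranded damage BED file
#'
#' BED6 dialect: `chrom start end name count strand`, where `start` is the
#' lower reference coordinate of the dinucleotide on either strand (so the
#' internal `pos5` of a minus-strand record is `start + 1`).  Rows whose
#' damaged-strand dinucleotide is not a dipyrimidine are dropped with a
#' logged count; duplicate loci are summed.
#'
#' @param path BED file path.
#' @param genome A `uvf_genome` for dinucleotide annotation.
#' @inheritParams damage_map
#' @return A `uvf_damage_map`.
#' @export
read_damage_bed <- function(path, genome, lesion_type = c("CPD", "64PP"),
                            timepoint = "0h") {
  lesion_type <- match.arg(lesion_type)
  df <- readr::read_tsv(path,
                        col_names = c("chrom", "start", "end", "name",
                                      "count", "strand"),
                        col_types = "cddccc", progress = FALSE)
  if (nrow(df) == 0L) {
    return(damage_map(tibble::tibble(chrom = character(0),
                                     strand = character(0),
                                     pos5 = numeric(0), count = numeric(0)),
                      lesion_type, timepoint))
  }
  cnt <- suppressWarnings(as.numeric(df$count))
  bad <- is.na(cnt) | cnt < 1 | cnt != round(cnt)
  if (any(bad)) {
    stop("non-integer or < 1 count on row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  unknown <- !df$chrom %in% names(genome)
  if (any(unknown)) {
    stop("unknown chromosome on row(s): ",
         paste(utils::head(which(unknown), 5), collapse = ", "),
         call. = FALSE)
  }
  pos5 <- ifelse(df$strand == "+", df$start, df$start + 1)
  dn <- .bare_dinuc(genome, df$chrom, df$strand, pos5)
  keep <- dn %in% c("TT", "TC", "CT", "CC")
  if (any(!keep)) {
    uvf_inform(paste0("read_damage_bed: dropped ", sum(!keep),
                      " non-dipyrimidine record(s)"))
  }
  damage_map(tibble::tibble(chrom = df$chrom[keep],
                            strand = df$strand[keep],
                            pos5 = pos5[keep], count = cnt[keep]),
             lesion_type, timepoint, genome = genome)
}

#' @rdname read_damage_bed
#' @param map A `uvf_damage_map` to write.
#' @export
write_damage_bed <- function(map, path) {
  lo <- ifelse(map$strand == "+", map$pos5, map$pos5 - 1)
  out <- tibble::tibble(chrom = map$chrom, start = lo, end = lo + 2,
                        name = map$dinuc %||% ".",
                        count = map$count, strand = map$strand)
  out <- dplyr::arrange(out, .data$chrom, .data$start, .data$strand)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Restrict a damage map to a region set
#'
#' Keeps records whose two dipyrimidine bases overlap the (merged) regions.
#'
#' @param map A `uvf_damage_map`.
#' @param regions Interval table.
#' @param full_containment If `TRUE` (default) both bases of the
#'   dinucleotide must lie inside one region, matching the occurrence
#'   enumeration used for rate tables.
#' @return Filtered `uvf_damage_map`.
#' @export
filter_to_regions <- function(map, regions, full_containment = TRUE) {
  if (nrow(map) == 0L) return(map)
  lo <- ifelse(map$strand == "+", map$pos5, map$pos5 - 1)
  if (full_containment) {
    red <- reduce_intervals(regions)
    q <- GenomicRanges::GRanges(map$chrom, IRanges::IRanges(lo + 1, lo + 2))
    hit <- GenomicRanges::findOverlaps(q, .gr(red), type = "within")
    keep <- seq_len(nrow(map)) %in% S4Vectors::queryHits(hit)
  } else {
    keep <- .overlaps_any(map$chrom, lo, lo + 2, regions)
  }
  .keep_attrs(map[keep, , drop = FALSE], map)
}
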
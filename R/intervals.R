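#' Genomic intervals as tibbles
#'
#' Throughout the package a set of genomic intervals is an ordinary tibble
#' with columns `chrom` (character, compared as exact strings), `start`
#' (0-based inclusive), `end` (0-based exclusive) and optionally `label`.
#' BED files use this convention natively; VCF positions are converted on
#' ingest so that a single coordinate convention holds everywhere.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive starts.
#' @param end Integer vector, 0-based exclusive ends.
#' @param label Optional character vector of interval labels.
#' @return A tibble with columns `chrom`, `start`, `end` and, when supplied,
#'   `label`.
#' @examples
#' intervals("chr1", 0, 100)
#' @export
intervals <- function(chrom, start, end, label = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 0)) abort("interval start must be >= 0")
  if (any(end <= start)) abort("interval end must be > start")
  out <- tibble(chrom = as.character(chrom), start = start, end = end)
  if (!is.null(label)) out$label <- as.character(label)
  out
}

check_intervals <- function(x, arg = "regions") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    abort(paste0("`", arg, "` must be a data frame with chrom/start/end columns"))
  }
  if (nrow(x) > 0) {
    if (any(x$start < 0)) abort(paste0("`", arg, "`: negative start coordinate"))
    if (any(x$end <= x$start)) abort(paste0("`", arg, "`: end <= start"))
  }
  invisible(x)
}

as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

granges_to_tbl <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Coalesce overlapping or touching intervals
#'
#' Overlapping (and book-ended) intervals on the same chromosome are merged
#' into maximal disjoint intervals, sorted by chromosome and start. Labels are
#' dropped since a merged interval may descend from several labelled ones.
#'
#' @param x Interval tibble (see [intervals()]).
#' @return A merged interval tibble; merging is idempotent.
#' @export
merge_intervals <- function(x) {
  check_intervals(x, "x")
  if (nrow(x) == 0) return(tibble(chrom = character(), start = integer(), end = integer()))
  gr <- GenomicRanges::reduce(as_granges(x))
  out <- granges_to_tbl(gr)
  arrange(out, .data$chrom, .data$start)
}

#' Total number of bases covered by an interval set
#'
#' @param x Interval tibble; merged first so overlaps are not double-counted.
#' @return Integer count of distinct covered bases.
#' @export
total_bases <- function(x) {
  m <- merge_intervals(x)
  sum(as.numeric(m$end - m$start))
}

#' Intersect two interval sets
#'
#' @param x,y Interval tibbles.
#' @return Merged tibble of bases present in both `x` and `y`.
#' @export
intersect_intervals <- function(x, y) {
  check_intervals(x, "x"); check_intervals(y, "y")
  if (nrow(x) == 0 || nrow(y) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  gr <- GenomicRanges::intersect(
    GenomicRanges::reduce(as_granges(x)),
    GenomicRanges::reduce(as_granges(y))
  )
  arrange(granges_to_tbl(gr), .data$chrom, .data$start)
}

#' Test containment of one interval set within another
#'
#' @param x Candidate subset.
#' @param within Interval tibble that should cover every base of `x`.
#' @return TRUE iff every base of `x` lies inside `within`.
#' @export
intervals_within <- function(x, within) {
  check_intervals(x, "x"); check_intervals(within, "within")
  if (nrow(x) == 0) return(TRUE)
  if (nrow(within) == 0) return(FALSE)
  left <- suppressWarnings(GenomicRanges::setdiff(
    GenomicRanges::reduce(as_granges(x)),
    GenomicRanges::reduce(as_granges(within))
  ))
  length(left) == 0
}

#' Read a BED file into an interval tibble
#'
#' Standard BED convention: 0-based, half-open, tab-separated; column 4, when
#' present, is kept as `label`. The result is merged (column 4 labels survive
#' only in the unmerged attribute-free return when `merge = FALSE`).
#' Plain and gzip-compressed files are accepted.
#'
#' @param path Path to a BED file.
#' @param merge Coalesce overlapping intervals (default TRUE). With labels
#'   present and `merge = TRUE`, labels are dropped by the merge.
#' @return Interval tibble.
#' @export
read_bed <- function(path, merge = TRUE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- stringr::str_split(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(paste0("malformed BED line ", which(nf < 3)[1], ": fewer than 3 columns"))
  }
  chrom <- purrr::map_chr(fields, 1)
  start <- suppressWarnings(as.integer(purrr::map_chr(fields, 2)))
  end <- suppressWarnings(as.integer(purrr::map_chr(fields, 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort(paste0("malformed BED line ", bad[1], ": non-integer coordinates"))
  }
  bad <- which(end <= start | start < 0)
  if (length(bad) > 0) {
    abort(paste0("malformed BED line ", bad[1], ": end <= start or negative start"))
  }
  out <- tibble(chrom = chrom, start = start, end = end)
  if (all(nf >= 4)) out$label <- purrr::map_chr(fields, 4)
  if (merge) merge_intervals(out) else out
}

#' Write an interval tibble as BED
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x, "x")
  cols <- c("chrom", "start", "end", if ("label" %in% names(x)) "label")
  readr::write_tsv(x[cols], path, col_names = FALSE)
  invisible(path)
}

#' Restrict variant calls to a region set
#'
#' A call is kept iff its 1-based VCF position, converted to the 0-based
#' half-open convention, falls inside some interval: a call at position p is
#' inside \code{[start, end)} iff start < p <= end (1-based), i.e. p - 1 lies
#' in the interval.
#'
#' @param calls Variant-call tibble (see [read_vcf_calls()]).
#' @param regions Interval tibble.
#' @return The subset of `calls` inside `regions`.
#' @export
restrict_to_regions <- function(calls, regions) {
  check_intervals(regions, "regions")
  if (nrow(calls) == 0 || nrow(regions) == 0) return(calls[0, ])
  q <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(calls$pos, calls$pos))
  # chromosomes present in only one of the two sets are a legitimate miss,
  # not a seqlevel problem
  hits <- suppressWarnings(GenomicRanges::countOverlaps(q, as_granges(regions)))
  calls[hits > 0, ]
}
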
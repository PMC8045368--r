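#' Breadth of coverage over a region set
#'
#' Fraction of region bases sequenced to at least `threshold` depth. Bases of
#' the (merged) regions with no depth entry count as depth 0. Regions must
#' lie inside the profile's declared regions, otherwise absent entries would
#' be ambiguous.
#'
#' @param profile A `depth_profile`.
#' @param regions Interval tibble, subset of the declared regions.
#' @param threshold Depth threshold; comparison is `>= threshold` by default.
#' @param strict_gt Use strictly-greater comparison (`> threshold`).
#' @return Fraction in \[0, 1\], or NA for an empty region set.
#' @export
breadth_of_coverage <- function(profile, regions, threshold = 10,
                                strict_gt = FALSE) {
  stopifnot(inherits(profile, "depth_profile"))
  check_intervals(regions, "regions")
  if (nrow(regions) == 0) return(NA_real_)
  if (!intervals_within(regions, profile$declared_regions)) {
    abort("regions extend outside the profile's declared regions")
  }
  m <- merge_intervals(regions)
  denom <- total_bases(m)
  e <- profile$entries
  pass <- if (strict_gt) e$depth > threshold else e$depth >= threshold
  if (threshold <= 0 && !strict_gt) return(1)  # absent bases count as depth 0
  e <- e[pass, ]
  if (nrow(e) == 0) return(0)
  q <- GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$pos, e$pos))
  inside <- suppressWarnings(GenomicRanges::countOverlaps(q, as_granges(m))) > 0
  sum(inside) / denom
}

#' Per-gene breadth of coverage over exonic regions
#'
#' For each gene the fraction of its (merged) exonic bases at or above the
#' depth threshold, a `fully_covered` flag (fraction exactly 1), and set-level
#' summaries: the fraction of genes fully covered and the overall base-level
#' fraction over the union of all gene regions.
#'
#' @param profile A `depth_profile`.
#' @param gene_regions Interval tibble with a `gene` column (or a `label`
#'   column, taken as the gene name), e.g. exon BED records.
#' @param threshold Depth threshold (>=).
#' @param strict_gt Use strictly-greater comparison.
#' @return A `coverage_report`: list with `per_gene` tibble (gene, n_bases,
#'   fraction, fully_covered) and `summary` tibble (n_genes,
#'   frac_genes_fully_covered, overall_base_fraction).
#' @export
gene_coverage <- function(profile, gene_regions, threshold = 10,
                          strict_gt = FALSE) {
  gene_regions <- as_tibble(gene_regions)
  if (!"gene" %in% names(gene_regions)) {
    if ("label" %in% names(gene_regions)) {
      gene_regions$gene <- gene_regions$label
    } else {
      abort("gene_regions needs a gene (or label) column")
    }
  }
  genes <- split(gene_regions, gene_regions$gene)
  per_gene <- purrr::imap(genes, function(g, nm) {
    m <- merge_intervals(g)
    tibble(
      gene = nm,
      n_bases = total_bases(m),
      fraction = breadth_of_coverage(profile, m, threshold, strict_gt)
    )
  }) %>%
    bind_rows() %>%
    mutate(fully_covered = .data$fraction == 1) %>%
    arrange(.data$gene)
  summary <- tibble(
    n_genes = nrow(per_gene),
    frac_genes_fully_covered = mean(per_gene$fully_covered),
    overall_base_fraction = breadth_of_coverage(
      profile, gene_regions, threshold, strict_gt
    )
  )
  structure(list(per_gene = per_gene, summary = summary, threshold = threshold),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("<coverage_report> threshold ", x$threshold, "X: ",
      sprintf("%.2f%%", 100 * x$summary$frac_genes_fully_covered),
      " of ", x$summary$n_genes, " genes fully covered\n", sep = "")
  invisible(x)
}

#' Breadth of coverage per labelled region
#'
#' One row per label (e.g. DECIPHER syndrome CNV regions) with its base
#' fraction at or above the threshold, sorted ascending so poorly covered
#' regions surface first.
#'
#' @param profile A `depth_profile`.
#' @param named_regions Interval tibble with a `label` column.
#' @param threshold Depth threshold (>=).
#' @param strict_gt Use strictly-greater comparison.
#' @return Tibble with `label`, `n_bases`, `fraction`.
#' @export
region_coverage_table <- function(profile, named_regions, threshold = 10,
                                  strict_gt = FALSE) {
  if (!"label" %in% names(named_regions)) abort("named_regions needs a label column")
  split(as_tibble(named_regions), named_regions$label) %>%
    purrr::imap(function(r, nm) {
      m <- merge_intervals(r)
      tibble(
        label = nm,
        n_bases = total_bases(m),
        fraction = breadth_of_coverage(profile, m, threshold, strict_gt)
      )
    }) %>%
    bind_rows() %>%
    arrange(.data$fraction, .data$label)
}

#' Distribution summary of a call-quality field
#'
#' Median, integer mode and full histogram of DP or GQ across calls,
#' optionally stratified by variant class. The median of an even-length
#' sample is the lower of the two middle values; ties in the mode resolve to
#' the smallest value. Histogram bin width is 1 (integer-binned values).
#'
#' @param calls Variant-call tibble.
#' @param field "DP" or "GQ".
#' @param stratify_by_vclass Produce one summary per variant class.
#' @return Tibble with `stratum`, `n`, `median`, `mode` and a `histogram`
#'   list-column of value/count tibbles.
#' @export
dp_gq_distribution <- function(calls, field = c("DP", "GQ"),
                               stratify_by_vclass = TRUE) {
  field <- match.arg(field)
  vals <- calls[[field]]
  if (all(is.na(vals))) abort(paste0("no defined ", field, " values"))
  strata <- if (stratify_by_vclass) calls$vclass else rep("all", nrow(calls))
  keep <- !is.na(vals)
  vals <- vals[keep]; strata <- strata[keep]
  summarise_one <- function(x) {
    x <- sort(x)
    n <- length(x)
    med <- x[floor((n + 1) / 2)]  # lower middle value for even n
    tab <- table(x)
    mode_val <- as.integer(names(tab)[which.max(tab)])  # which.max: first = smallest
    hist <- tibble(value = as.integer(names(tab)), count = as.integer(tab))
    tibble(n = n, median = med, mode = mode_val, histogram = list(hist))
  }
  split(vals, strata) %>%
    purrr::imap(function(x, nm) mutate(summarise_one(x), stratum = nm, .before = 1)) %>%
    bind_rows()
}
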
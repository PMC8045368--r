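#' Read variant calls from a VCF file
#'
#' Parses a VCF 4.x file (plain or gzipped) into a tidy tibble of normalized
#' calls, one row per alternate allele. Multiallelic records are split: for
#' each ALT allele the genotype is re-expressed relative to that allele, so a
#' `1/2` genotype with two ALTs yields two heterozygous rows. GQ and DP are
#' taken from FORMAT when present and recorded as `NA` otherwise.
#'
#' Genotype mapping (diploid): allele count 2 of the focal ALT is `hom_alt`,
#' count 1 is `het`, count 0 with an all-reference genotype is `hom_ref`.
#' Haploid genotypes map to `hemi` (focal allele present) or `hom_ref`.
#' A missing genotype (`./.`) yields `missing`. When the genotype carries only
#' other ALT alleles, no row is emitted for the focal allele.
#'
#' @param path VCF file path.
#' @param sample Sample name; defaults to the first sample column. An unknown
#'   name is an error.
#' @return Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `zygosity`, `vclass`, `GQ`, `DP`.
#' @export
read_vcf_calls <- function(path, sample = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2) abort("VCF has no sample genotype columns")
  samples <- colnames(gt)[-1]
  if (is.null(sample)) {
    sample <- samples[1]
  } else if (!sample %in% samples) {
    abort(paste0("sample not found in VCF: ", sample))
  }
  if (nrow(fix) == 0) {
    return(tibble(
      chrom = character(), pos = integer(), ref = character(), alt = character(),
      zygosity = character(), vclass = character(), GQ = integer(), DP = integer()
    ))
  }
  fmt_keys <- stringr::str_split(gt[, "FORMAT"], ":")
  sample_vals <- stringr::str_split(gt[, sample], ":")
  get_field <- function(i, key) {
    idx <- match(key, fmt_keys[[i]])
    if (is.na(idx) || idx > length(sample_vals[[i]])) return(NA_character_)
    sample_vals[[i]][idx]
  }
  n <- nrow(fix)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (!"GT" %in% fmt_keys[[i]]) abort(paste0("record ", i, ": GT field missing"))
    gt_str <- get_field(i, "GT")  # NA: genotype masked as missing (./.)
    gq <- suppressWarnings(as.integer(get_field(i, "GQ")))
    dp <- suppressWarnings(as.integer(get_field(i, "DP")))
    alts <- stringr::str_split_1(fix[i, "ALT"], ",")
    alleles <- if (is.na(gt_str)) "." else stringr::str_split_1(gt_str, "[/|]")
    missing_gt <- all(alleles %in% c(".", ""))
    ai <- suppressWarnings(as.integer(alleles))
    ploidy <- length(alleles)
    keep_alt <- logical(length(alts))
    zyg <- character(length(alts))
    for (k in seq_along(alts)) {
      if (missing_gt) {
        keep_alt[k] <- TRUE; zyg[k] <- "missing"
      } else {
        cnt <- sum(ai == k, na.rm = TRUE)
        if (cnt == ploidy) {
          keep_alt[k] <- TRUE; zyg[k] <- if (ploidy == 1) "hemi" else "hom_alt"
        } else if (cnt >= 1) {
          keep_alt[k] <- TRUE; zyg[k] <- "het"
        } else if (all(ai == 0, na.rm = TRUE) && !anyNA(ai)) {
          keep_alt[k] <- TRUE; zyg[k] <- "hom_ref"
        }
      }
    }
    if (!any(keep_alt)) next
    rows[[i]] <- tibble(
      chrom = unname(fix[i, "CHROM"]),
      pos = as.integer(unname(fix[i, "POS"])),
      ref = unname(fix[i, "REF"]),
      alt = unname(alts[keep_alt]),
      zygosity = zyg[keep_alt],
      GQ = gq, DP = dp
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(
      chrom = character(), pos = integer(), ref = character(), alt = character(),
      zygosity = character(), vclass = character(), GQ = integer(), DP = integer()
    ))
  }
  out$vclass <- classify_variant(out$ref, out$alt)
  out[, c("chrom", "pos", "ref", "alt", "zygosity", "vclass", "GQ", "DP")]
}

#' Write variant calls as a minimal VCF 4.2 file
#'
#' The inverse of [read_vcf_calls()] for synthetic data: one record per row
#' with a GT:GQ:DP FORMAT. Zygosity maps back to 0/0, 0/1, 1/1, 1 (hemi) or
#' ./. (missing).
#'
#' @param calls Variant-call tibble.
#' @param path Output path (`.gz` suffix writes gzip).
#' @param sample Sample column name.
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample = "SAMPLE", contigs = NULL) {
  gt_map <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
              hemi = "1", missing = "./.")
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs))
    },
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  calls <- arrange(calls, .data$chrom, .data$pos, .data$alt)
  fmt_num <- function(x) ifelse(is.na(x), ".", as.character(x))
  body <- if (nrow(calls) == 0) character() else {
    paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".", "PASS", ".",
          "GT:GQ:DP",
          paste(gt_map[calls$zygosity], fmt_num(calls$GQ), fmt_num(calls$DP),
                sep = ":"),
          sep = "\t")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a per-base depth table
#'
#' Expects whitespace- or tab-separated columns chrom, position (1-based),
#' depth — the `samtools depth` layout. Positions outside `declared_regions`
#' are dropped with an informative message; within the declared regions a
#' position with no row is interpreted downstream as depth 0.
#'
#' @param path Depth table path (plain or gzip).
#' @param declared_regions Interval tibble over which the profile is defined.
#' @return A `depth_profile` object (see [depth_profile()]).
#' @export
read_depth_table <- function(path, declared_regions) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tab <- readr::read_table(
    path,
    col_names = c("chrom", "pos", "depth"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      depth = readr::col_integer()
    ),
    progress = FALSE
  )
  if (nrow(tab) > 0 && any(tab$depth < 0)) abort("negative depth in depth table")
  depth_profile(tab, declared_regions, drop_outside = TRUE)
}

#' Construct a depth profile
#'
#' A depth profile couples per-base depth entries with the regions over which
#' the profile is declared: inside the declared regions an absent position
#' means depth 0, outside them depth is unknown.
#'
#' @param entries Tibble with columns `chrom`, `pos` (1-based), `depth`.
#' @param declared_regions Interval tibble.
#' @param drop_outside Drop (with a message) entries outside the declared
#'   regions instead of erroring.
#' @return An object of class `depth_profile`: a list with `entries` and
#'   `declared_regions`.
#' @export
depth_profile <- function(entries, declared_regions, drop_outside = FALSE) {
  check_intervals(declared_regions, "declared_regions")
  stopifnot(all(c("chrom", "pos", "depth") %in% names(entries)))
  if (nrow(entries) > 0 && any(entries$depth < 0)) abort("negative depth")
  declared <- merge_intervals(declared_regions)
  if (nrow(entries) > 0) {
    q <- GenomicRanges::GRanges(entries$chrom,
                                IRanges::IRanges(entries$pos, entries$pos))
    inside <- suppressWarnings(GenomicRanges::countOverlaps(q, as_granges(declared))) > 0
    if (!all(inside)) {
      if (!drop_outside) abort("depth entries outside declared regions")
      inform(paste0("dropped ", sum(!inside), " depth entries outside declared regions"))
      entries <- entries[inside, ]
    }
  }
  structure(
    list(entries = as_tibble(entries), declared_regions = declared),
    class = "depth_profile"
  )
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("<depth_profile> ", nrow(x$entries), " entries over ",
      total_bases(x$declared_regions), " declared bases\n", sep = "")
  invisible(x)
}

#' Write a depth profile's entries as a depth table
#'
#' @param profile A `depth_profile`.
#' @param path Output path (`.gz` writes gzip).
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(profile, path) {
  readr::write_tsv(profile$entries, path, col_names = FALSE)
  invisible(path)
}
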
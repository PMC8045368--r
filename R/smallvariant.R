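#' Classify alleles as SNP or indel
#'
#' A variant is a SNP iff both alleles are single bases; everything else,
#' including same-length multi-base substitutions (MNVs), is classed as indel.
#'
#' @param ref,alt Character vectors of reference and alternate alleles.
#' @return Character vector, "SNP" or "indel".
#' @export
classify_variant <- function(ref, alt) {
  if (any(ref == alt)) abort("ref and alt alleles must differ")
  ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP", "indel")
}

#' Gate variant calls on genotype quality and depth
#'
#' Keeps calls with `GQ >= min_gq` and `DP >= min_dp` (boundary inclusive,
#' the usual GQ >= 20 / DP >= 10 clinical gates by default). Calls with a
#' missing GQ or DP are dropped; their count is reported via a message and an
#' attribute `n_dropped_missing`.
#'
#' @param calls Variant-call tibble.
#' @param min_gq,min_dp Non-negative thresholds.
#' @param quiet Suppress the dropped-calls message.
#' @return Filtered tibble with attribute `n_dropped_missing`.
#' @export
filter_calls <- function(calls, min_gq = 20, min_dp = 10, quiet = TRUE) {
  if (min_gq < 0 || min_dp < 0) abort("thresholds must be >= 0")
  miss <- is.na(calls$GQ) | is.na(calls$DP)
  keep <- !miss & calls$GQ >= min_gq & calls$DP >= min_dp
  if (!quiet && any(miss)) {
    inform(paste0("dropped ", sum(miss), " calls with missing GQ/DP"))
  }
  out <- calls[keep, ]
  attr(out, "n_dropped_missing") <- sum(miss)
  out
}

call_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = "\r")
}

#' Match a query call set against a truth set
#'
#' Calls match on the exact key (chrom, pos, ref, alt). With
#' `genotype_aware = TRUE` (default) a key match whose zygosity differs
#' counts as both a false negative and a false positive, and is tallied in
#' `gt_mismatch` — so sensitivity and PPV are both penalised by genotype
#' errors, as in stratified hom/het reporting. With `genotype_aware = FALSE`
#' any key match is a true positive.
#'
#' Truth-side counts (tp, fn) are stratified by the truth call's class and
#' zygosity; fp by the query call's.
#'
#' @param truth,query Variant-call tibbles, already restricted to the same
#'   confident regions and filtered. Duplicate keys within either input are
#'   an error.
#' @param genotype_aware Logical.
#' @return A `match_result`: list with `per_stratum` (tibble of vclass,
#'   zygosity, tp, fn, fp, gt_mismatch), scalar totals `tp`, `fn`, `fp`,
#'   `gt_mismatch`, `n_truth`, `n_query`, and the flag `genotype_aware`.
#' @export
match_calls <- function(truth, query, genotype_aware = TRUE) {
  tk <- call_key(truth)
  qk <- call_key(query)
  if (anyDuplicated(tk)) abort("duplicate keys in truth set; deduplicate upstream")
  if (anyDuplicated(qk)) abort("duplicate keys in query set; deduplicate upstream")
  idx <- match(tk, qk)
  has_match <- !is.na(idx)
  zyg_equal <- has_match & truth$zygosity == query$zygosity[ifelse(is.na(idx), 1L, idx)]
  if (genotype_aware) {
    truth_tp <- has_match & zyg_equal
    gt_mis <- has_match & !zyg_equal
  } else {
    truth_tp <- has_match
    gt_mis <- rep(FALSE, length(tk))
  }
  # query-side: a query call is fp iff it is not the match of a tp truth call
  matched_query <- rep(FALSE, length(qk))
  if (any(truth_tp)) matched_query[idx[truth_tp]] <- TRUE

  strata <- tidyr::expand_grid(
    vclass = VCLASS_LEVELS,
    zygosity = c("hom_alt", "het", "hemi")
  )
  count_by <- function(tbl, keep) {
    tbl %>%
      filter(keep) %>%
      count(.data$vclass, .data$zygosity, name = "n")
  }
  tp_tab <- count_by(truth, truth_tp)
  fn_tab <- count_by(truth, !truth_tp)
  fp_tab <- count_by(query, !matched_query)
  gt_tab <- count_by(truth, gt_mis)
  per <- strata %>%
    left_join(rename(tp_tab, tp = "n"), by = c("vclass", "zygosity")) %>%
    left_join(rename(fn_tab, fn = "n"), by = c("vclass", "zygosity")) %>%
    left_join(rename(fp_tab, fp = "n"), by = c("vclass", "zygosity")) %>%
    left_join(rename(gt_tab, gt_mismatch = "n"), by = c("vclass", "zygosity")) %>%
    mutate(across(c("tp", "fn", "fp", "gt_mismatch"), ~ dplyr::coalesce(.x, 0L)))
  structure(
    list(
      per_stratum = per,
      tp = sum(truth_tp), fn = sum(!truth_tp),
      fp = sum(!matched_query), gt_mismatch = sum(gt_mis),
      n_truth = length(tk), n_query = length(qk),
      genotype_aware = genotype_aware
    ),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> tp=", x$tp, " fn=", x$fn, " fp=", x$fp,
      " gt_mismatch=", x$gt_mismatch,
      if (x$genotype_aware) " (genotype-aware)\n" else "\n", sep = "")
  invisible(x)
}

safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' Concordance metrics from a match result
#'
#' Computes, per stratum (variant class x zygosity) and overall:
#' sensitivity = tp / (tp + fn), PPV = tp / (tp + fp). When reference-site
#' counts are supplied, the overall row also carries
#' specificity = `query_ref_agree` / `truth_ref_sites` and
#' accuracy = (tp + `query_ref_agree`) / (truth variant sites +
#' `truth_ref_sites`). A zero denominator yields `NA`, never an error.
#'
#' @param match A `match_result` from [match_calls()].
#' @param truth_ref_sites Number of confident reference positions assessed
#'   (conventionally: confident-region bases minus truth variant sites), or
#'   NULL to omit specificity/accuracy.
#' @param query_ref_agree Number of those positions called reference by the
#'   query.
#' @return Tibble with columns `vclass`, `zygosity`, `tp`, `fn`, `fp`,
#'   `n_truth`, `n_query`, `sensitivity`, `ppv`, `specificity`, `accuracy`;
#'   one row per stratum plus an `overall` row (vclass = "all").
#' @export
concordance_metrics <- function(match, truth_ref_sites = NULL,
                                query_ref_agree = NULL) {
  stopifnot(inherits(match, "match_result"))
  if (!is.null(truth_ref_sites)) {
    if (truth_ref_sites < 0 || (query_ref_agree %||% 0) < 0) {
      abort("reference-site counts must be >= 0")
    }
  }
  per <- match$per_stratum %>%
    mutate(
      n_truth = .data$tp + .data$fn,
      n_query = .data$tp + .data$fp,
      sensitivity = safe_div(.data$tp, .data$n_truth),
      ppv = safe_div(.data$tp, .data$n_query),
      specificity = NA_real_,
      accuracy = NA_real_
    ) %>%
    filter(.data$n_truth > 0 | .data$n_query > 0)
  overall <- tibble(
    vclass = "all", zygosity = "all",
    tp = match$tp, fn = match$fn, fp = match$fp,
    n_truth = match$n_truth, n_query = match$n_query,
    sensitivity = safe_div(match$tp, match$n_truth),
    ppv = safe_div(match$tp, match$n_query),
    specificity = if (is.null(truth_ref_sites)) NA_real_ else
      safe_div(query_ref_agree, truth_ref_sites),
    accuracy = if (is.null(truth_ref_sites)) NA_real_ else
      safe_div(match$tp + query_ref_agree, match$n_truth + truth_ref_sites)
  )
  bind_rows(per, overall)
}

#' Run the full small-variant benchmark on one truth/query pair
#'
#' Convenience wrapper: restricts both call sets to the confident regions,
#' applies the GQ/DP gates to the query, matches, and computes metrics.
#' Truth sets are conventionally taken as given (no gating).
#'
#' @param truth,query Variant-call tibbles.
#' @param regions Confident-region interval tibble (NULL to skip restriction).
#' @param min_gq,min_dp Gates applied to the query calls.
#' @param genotype_aware Passed to [match_calls()].
#' @param ref_sites Optional list(truth_ref_sites=, query_ref_agree=).
#' @return Tibble as from [concordance_metrics()].
#' @export
bench_small_variants <- function(truth, query, regions = NULL,
                                 min_gq = 20, min_dp = 10,
                                 genotype_aware = TRUE, ref_sites = NULL) {
  if (!is.null(regions)) {
    truth <- restrict_to_regions(truth, regions)
    query <- restrict_to_regions(query, regions)
  }
  query <- filter_calls(query, min_gq, min_dp)
  m <- match_calls(truth, query, genotype_aware)
  concordance_metrics(m, ref_sites$truth_ref_sites, ref_sites$query_ref_agree)
}

#' Concordance across a depth titration series
#'
#' Runs [bench_small_variants()] once per labelled run (e.g. down-sampled
#' mean depths 10X..150X) and stacks the results into one tidy table sorted
#' by numeric depth.
#'
#' @param labeled_runs Named list; each element a list with components
#'   `truth`, `query`, and optionally `regions`, `min_gq`, `min_dp`,
#'   `genotype_aware`. Names are depth labels like "10X"; duplicates error.
#' @return Tidy tibble: one row per depth x stratum with all metric columns,
#'   plus `depth_label` and numeric `depth`.
#' @export
depth_titration <- function(labeled_runs) {
  if (length(labeled_runs) == 0) abort("need at least one run")
  labs <- names(labeled_runs)
  if (is.null(labs) || any(!nzchar(labs))) abort("runs must be named by depth label")
  if (anyDuplicated(labs)) abort("duplicate depth label")
  out <- purrr::imap(labeled_runs, function(run, lab) {
    res <- bench_small_variants(
      run$truth, run$query, run$regions,
      min_gq = run$min_gq %||% 20, min_dp = run$min_dp %||% 10,
      genotype_aware = run$genotype_aware %||% TRUE
    )
    mutate(res, depth_label = lab, .before = 1)
  })
  bind_rows(out) %>%
    mutate(depth = readr::parse_number(.data$depth_label)) %>%
    arrange(.data$depth, .data$vclass, .data$zygosity)
}
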
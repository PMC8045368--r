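#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a match result into per-stratum counts
#'
#' @param x A `match_result` from [match_calls()].
#' @param ... Ignored.
#' @return Tibble of per-stratum tp/fn/fp/gt_mismatch counts.
#' @export
tidy.match_result <- function(x, ...) x$per_stratum

#' One-row summary of a match result
#'
#' @param x A `match_result`.
#' @param ... Ignored.
#' @return One-row tibble with total counts and overall sensitivity/PPV.
#' @export
glance.match_result <- function(x, ...) {
  tibble(
    n_truth = x$n_truth, n_query = x$n_query,
    tp = x$tp, fn = x$fn, fp = x$fp, gt_mismatch = x$gt_mismatch,
    sensitivity = safe_div(x$tp, x$n_truth),
    ppv = safe_div(x$tp, x$n_query),
    genotype_aware = x$genotype_aware
  )
}

#' Tidy a coverage report into the per-gene table
#'
#' @param x A `coverage_report` from [gene_coverage()].
#' @param ... Ignored.
#' @return Per-gene tibble.
#' @export
tidy.coverage_report <- function(x, ...) x$per_gene

#' One-row summary of a coverage report
#'
#' @param x A `coverage_report`.
#' @param ... Ignored.
#' @return One-row tibble of set-level coverage.
#' @export
glance.coverage_report <- function(x, ...) x$summary

#' Tidy a trio evaluation into per-class rows
#'
#' @param x A `trio_eval` from [evaluate_offspring()].
#' @param ... Ignored.
#' @return Per-class tibble (excluding the "all" row).
#' @export
tidy.trio_eval <- function(x, ...) {
  filter(as_tibble(x), .data$vclass != "all")
}

#' One-row summary of a trio evaluation
#'
#' @param x A `trio_eval`.
#' @param ... Ignored.
#' @return The overall row as a one-row tibble.
#' @export
glance.trio_eval <- function(x, ...) {
  select(filter(as_tibble(x), .data$vclass == "all"), -"vclass")
}
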
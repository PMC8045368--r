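#' Reciprocal overlap of two genomic intervals
#'
#' For intervals a and b on the same chromosome, reciprocal overlap is
#' min(ovl / len(a), ovl / len(b)) where ovl is the length of their
#' intersection; intervals on different chromosomes have overlap 0. The
#' standard CNV-matching statistic (BEDTools `-f x -r`).
#'
#' Vectorized over its arguments.
#'
#' @param chrom_a,start_a,end_a First interval(s), 0-based half-open.
#' @param chrom_b,start_b,end_b Second interval(s).
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
reciprocal_overlap <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  ovl <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b))
  len_a <- end_a - start_a
  len_b <- end_b - start_b
  ifelse(chrom_a == chrom_b, pmin(ovl / len_a, ovl / len_b), 0)
}

#' CNV call tibbles
#'
#' A CNV call set is a tibble with columns `chrom`, `start` (0-based), `end`
#' (exclusive), `cnv_type` ("DEL" or "DUP") and `source` (tool or call-set
#' label); `size` = end - start is added if absent.
#'
#' @param x Data frame with at least chrom/start/end/cnv_type.
#' @param source Default source label when the column is absent.
#' @return Validated CNV tibble with a `size` column.
#' @export
as_cnv_calls <- function(x, source = "unknown") {
  check_intervals(x, "cnv calls")
  if (!"cnv_type" %in% names(x)) abort("cnv calls need a cnv_type column")
  if (!all(x$cnv_type %in% c("DEL", "DUP"))) abort("cnv_type must be DEL or DUP")
  x <- as_tibble(x)
  if (!"source" %in% names(x)) x$source <- source
  x$size <- x$end - x$start
  x
}

#' Read a BED-like CNV file
#'
#' Tab-separated columns: chrom, start (0-based), end, type (DEL/DUP) and
#' optionally source.
#'
#' @param path File path (plain or gzip).
#' @param source Source label used when the file has no 5th column.
#' @return CNV tibble (see [as_cnv_calls()]).
#' @export
read_cnv_calls <- function(path, source = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tab <- readr::read_tsv(
    path, col_names = FALSE, progress = FALSE,
    show_col_types = FALSE, comment = "#"
  )
  if (ncol(tab) < 4) abort("CNV file needs >= 4 columns (chrom start end type)")
  names(tab)[1:4] <- c("chrom", "start", "end", "cnv_type")
  if (ncol(tab) >= 5) names(tab)[5] <- "source"
  as_cnv_calls(tab[, seq_len(min(5, ncol(tab)))],
               source = source %||% basename(path))
}

#' Write a CNV tibble as BED-like TSV
#'
#' @param cnvs CNV tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnv_calls <- function(cnvs, path) {
  readr::write_tsv(cnvs[, c("chrom", "start", "end", "cnv_type", "source")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Match truth CNVs against a call set by reciprocal overlap
#'
#' A truth CNV is matched iff at least one call of compatible type has
#' reciprocal overlap >= `threshold` ("at least 50%" by default). Matching is
#' many-to-one: several truth CNVs may be recovered by the same call, since
#' benchmark sensitivity counts truth recovery, not a bijection.
#'
#' @param truth,calls CNV tibbles.
#' @param threshold Reciprocal-overlap threshold in (0, 1].
#' @param type_aware Require equal `cnv_type` (default TRUE).
#' @return List with tibbles `matched_truth`, `unmatched_truth`,
#'   `unmatched_calls`.
#' @export
match_cnvs <- function(truth, calls, threshold = 0.5, type_aware = TRUE) {
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  truth <- as_tibble(truth)
  calls <- as_tibble(calls)
  t_matched <- rep(FALSE, nrow(truth))
  c_matched <- rep(FALSE, nrow(calls))
  if (nrow(truth) > 0 && nrow(calls) > 0) {
    ti <- tibble(.t = seq_len(nrow(truth)), chrom = truth$chrom,
                 ts = truth$start, te = truth$end, tt = truth$cnv_type)
    ci <- tibble(.c = seq_len(nrow(calls)), chrom = calls$chrom,
                 cs = calls$start, ce = calls$end, ct = calls$cnv_type)
    pairs <- inner_join(ti, ci, by = "chrom", relationship = "many-to-many")
    if (type_aware) pairs <- filter(pairs, .data$tt == .data$ct)
    if (nrow(pairs) > 0) {
      ro <- reciprocal_overlap(pairs$chrom, pairs$ts, pairs$te,
                               pairs$chrom, pairs$cs, pairs$ce)
      hit <- pairs[ro >= threshold, ]
      t_matched[unique(hit$.t)] <- TRUE
      c_matched[unique(hit$.c)] <- TRUE
    }
  }
  list(
    matched_truth = truth[t_matched, ],
    unmatched_truth = truth[!t_matched, ],
    unmatched_calls = calls[!c_matched, ]
  )
}

#' Assign CNV sizes to bins
#'
#' Bin edges follow the \[lo, hi) convention; sizes at or above the last edge
#' fall into an open overflow bin.
#'
#' @param size Numeric vector of CNV sizes in bases.
#' @param bins Strictly increasing numeric vector of bin edges.
#' @return Character vector of bin labels like "[1e+03,5e+03)".
#' @export
size_bin_labels <- function(size, bins) {
  if (is.unsorted(bins, strictly = TRUE)) abort("bins must be strictly increasing")
  edges <- c(0, bins, Inf)
  labs <- paste0("[", format(edges[-length(edges)], trim = TRUE, scientific = FALSE),
                 ",", format(edges[-1], trim = TRUE, scientific = FALSE), ")")
  labs[findInterval(size, edges)]
}

#' Default CNV size-bin edges (bases)
#' @export
default_size_bins <- function() c(1e3, 5e3, 1e4, 5e4, 1e5, 5e5, 1e6)

#' Size-stratified CNV detection sensitivity
#'
#' Matches `truth` against `calls` (see [match_cnvs()]) and reports, per size
#' bin, the fraction of truth CNVs recovered. Each resulting row is one cell
#' of the depth x tool x call-set sensitivity grid.
#'
#' @param truth,calls CNV tibbles.
#' @param bins Strictly increasing size-bin edges (bases).
#' @param depth_label Mean-depth tag, e.g. 10 or "10X".
#' @param tool Caller label.
#' @param callset Truth-set label.
#' @param threshold,type_aware Passed to [match_cnvs()].
#' @return Tibble of cells: `depth_label`, `tool`, `callset`, `size_bin`,
#'   `n_truth`, `n_matched`, `sensitivity` (NA when the bin is empty).
#' @export
sensitivity_by_size <- function(truth, calls, bins = default_size_bins(),
                                depth_label, tool, callset,
                                threshold = 0.5, type_aware = TRUE) {
  truth <- as_cnv_calls(truth, source = callset)
  m <- match_cnvs(truth, calls, threshold, type_aware)
  tk <- paste(truth$chrom, truth$start, truth$end, truth$cnv_type)
  mk <- paste(m$matched_truth$chrom, m$matched_truth$start,
              m$matched_truth$end, m$matched_truth$cnv_type)
  matched <- tk %in% mk
  all_bins <- size_bin_labels(c(1, bins), bins)  # every label incl. overflow
  tibble(
    size_bin = factor(size_bin_labels(truth$size, bins), levels = unique(all_bins)),
    matched = matched
  ) %>%
    group_by(.data$size_bin, .drop = FALSE) %>%
    summarise(n_truth = n(), n_matched = sum(.data$matched), .groups = "drop") %>%
    mutate(
      depth_label = depth_label, tool = tool, callset = callset,
      size_bin = as.character(.data$size_bin),
      sensitivity = safe_div(.data$n_matched, .data$n_truth)
    ) %>%
    select("depth_label", "tool", "callset", "size_bin",
           "n_truth", "n_matched", "sensitivity")
}

#' Select qualified (tool, call set, size bin) groups for MDI
#'
#' A group of sensitivity cells qualifies iff every depth has at least
#' `min_truth` truth CNVs in the bin and, when `require_variation` is TRUE,
#' the sensitivities are not identical across depths (a flat profile carries
#' no information about which depth is worst).
#'
#' @param cells Sensitivity-cell tibble from [sensitivity_by_size()].
#' @param min_truth Minimum truth count per depth.
#' @param require_variation Disqualify flat sensitivity profiles.
#' @return The subset of `cells` belonging to qualified groups.
#' @export
qualified_size_bins <- function(cells, min_truth = 10, require_variation = TRUE) {
  cells %>%
    group_by(.data$tool, .data$callset, .data$size_bin) %>%
    filter(
      all(.data$n_truth >= min_truth),
      !require_variation || dplyr::n_distinct(.data$sensitivity) > 1
    ) %>%
    ungroup()
}

#' Miss detection index across sequencing depths
#'
#' For each qualified (tool, call set, size bin) group, every depth attaining
#' the group's minimum sensitivity scores one "lowest-sensitivity" event
#' (ties all count, so the event total N equals the number of attaining
#' depths summed over groups). MDI for depth i is M_i / N — the frequency
#' with which depth i is the worst — and sums to 1 over depths.
#'
#' @param cells Qualified sensitivity cells; every group must have a
#'   sensitivity at every depth.
#' @return An `mdi_table`: tibble with `depth_label`, `M`, `N`, `mdi`.
#' @export
compute_mdi <- function(cells) {
  if (nrow(cells) == 0) abort("no qualified groups")
  depths <- unique(cells$depth_label)
  grp <- cells %>% group_by(.data$tool, .data$callset, .data$size_bin)
  sizes <- grp %>% summarise(nd = n(), nna = sum(is.na(.data$sensitivity)),
                             .groups = "drop")
  if (any(sizes$nd != length(depths)) || any(sizes$nna > 0)) {
    abort("every qualified group needs a sensitivity at every depth")
  }
  minima <- grp %>%
    filter(.data$sensitivity == min(.data$sensitivity)) %>%
    ungroup() %>%
    count(.data$depth_label, name = "M")
  out <- tibble(depth_label = depths) %>%
    left_join(minima, by = "depth_label") %>%
    mutate(M = dplyr::coalesce(.data$M, 0L))
  out$N <- sum(out$M)
  if (out$N[1] == 0) abort("no qualified groups")
  out$mdi <- out$M / out$N
  out <- arrange(out, suppressWarnings(readr::parse_number(as.character(.data$depth_label))))
  class(out) <- c("mdi_table", class(out))
  out
}

#' Compile a consensus CNV call set from several benchmark sets
#'
#' Takes the union of the input call sets, deduplicated so that no two
#' retained CNVs of the same type have reciprocal overlap >= `threshold`
#' (first-come within chrom/start order wins). Each retained CNV is
#' annotated with the number of tools having at least one detection with
#' reciprocal overlap strictly greater than `threshold` (the consensus
#' support rule), and `needs_manual_review = TRUE` throughout: visual
#' confirmation of the copy-ratio signal is a manual step outside this
#' package.
#'
#' @param callsets List of >= 2 CNV tibbles (benchmark sets).
#' @param tool_detections Named list of CNV tibbles, one per tool.
#' @param threshold Reciprocal-overlap threshold in (0, 1].
#' @return Consensus CNV tibble with `n_supporting_tools` and
#'   `needs_manual_review` columns.
#' @export
compile_consensus_callset <- function(callsets, tool_detections = list(),
                                      threshold = 0.5) {
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  if (length(callsets) < 2) abort("need at least 2 call sets")
  all_cnvs <- bind_rows(purrr::imap(callsets, function(cs, i) {
    as_cnv_calls(cs, source = paste0("callset", i))
  })) %>% arrange(.data$chrom, .data$start, .data$end)
  keep <- logical(nrow(all_cnvs))
  for (i in seq_len(nrow(all_cnvs))) {
    prior <- which(keep & all_cnvs$cnv_type == all_cnvs$cnv_type[i] &
                     all_cnvs$chrom == all_cnvs$chrom[i])
    dup <- length(prior) > 0 && any(
      reciprocal_overlap(all_cnvs$chrom[prior], all_cnvs$start[prior],
                         all_cnvs$end[prior], all_cnvs$chrom[i],
                         all_cnvs$start[i], all_cnvs$end[i]) >= threshold
    )
    keep[i] <- !dup
  }
  consensus <- all_cnvs[keep, ]
  n_support <- integer(nrow(consensus))
  for (tool in names(tool_detections)) {
    det <- tool_detections[[tool]]
    if (nrow(det) == 0) next
    supported <- purrr::map_lgl(seq_len(nrow(consensus)), function(i) {
      same <- det$cnv_type == consensus$cnv_type[i] &
        det$chrom == consensus$chrom[i]
      any(reciprocal_overlap(det$chrom[same], det$start[same], det$end[same],
                             consensus$chrom[i], consensus$start[i],
                             consensus$end[i]) > threshold)
    })
    n_support <- n_support + supported
  }
  consensus$n_supporting_tools <- n_support
  consensus$needs_manual_review <- TRUE
  consensus
}
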
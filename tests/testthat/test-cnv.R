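cnv_tbl <- function(start, end, type = "DEL", chrom = "chr1", source = "x") {
  as_cnv_calls(tibble::tibble(chrom = chrom, start = start, end = end,
                              cnv_type = type, source = source))
}

test_that("reciprocal overlap matches hand arithmetic and the per-base oracle", {
  expect_equal(reciprocal_overlap("chr1", 100, 200, "chr1", 100, 200), 1)
  expect_equal(reciprocal_overlap("chr1", 100, 200, "chr1", 150, 250), 0.5)
  expect_equal(reciprocal_overlap("chr1", 0, 1000, "chr1", 400, 500), 0.1)
  expect_equal(reciprocal_overlap("chr1", 0, 100, "chr2", 0, 100), 0)
  set.seed(12)
  for (i in 1:200) {
    s1 <- sample.int(5000, 1); l1 <- sample.int(500, 1)
    s2 <- sample.int(5000, 1); l2 <- sample.int(500, 1)
    got <- reciprocal_overlap("chr1", s1, s1 + l1, "chr1", s2, s2 + l2)
    expect_equal(got, oracle_ro("chr1", s1, s1 + l1, "chr1", s2, s2 + l2))
    # symmetry
    expect_identical(got, reciprocal_overlap("chr1", s2, s2 + l2, "chr1", s1, s1 + l1))
  }
})

test_that("CNV matching respects the threshold boundary and type awareness", {
  truth <- cnv_tbl(100, 200)
  # RO exactly 0.5 matches ("at least")
  m <- match_cnvs(truth, cnv_tbl(150, 250), threshold = 0.5)
  expect_equal(nrow(m$matched_truth), 1)
  # same geometry, wrong type
  m2 <- match_cnvs(truth, cnv_tbl(150, 250, type = "DUP"), threshold = 0.5)
  expect_equal(nrow(m2$matched_truth), 0)
  expect_equal(nrow(m2$unmatched_calls), 1)
  # type-blind accepts it
  m3 <- match_cnvs(truth, cnv_tbl(150, 250, type = "DUP"), type_aware = FALSE)
  expect_equal(nrow(m3$matched_truth), 1)
  # empty calls leave all truth unmatched
  m4 <- match_cnvs(truth, truth[0, ])
  expect_equal(nrow(m4$unmatched_truth), 1)
  expect_error(match_cnvs(truth, truth, threshold = 0), "\\(0, 1\\]")
})

test_that("size-stratified sensitivity bins on [lo, hi) and handles empty bins", {
  bins <- c(1000, 5000)
  truth <- cnv_tbl(
    start = c(0, 10000, 20000, 30000),
    end = c(500, 11000, 21000, 36000)  # sizes 500, 1000, 1000, 6000
  )
  calls <- truth[c(1, 2), ]  # recover the first two exactly
  cells <- sensitivity_by_size(truth, calls, bins = bins,
                               depth_label = 10, tool = "t", callset = "c")
  expect_equal(nrow(cells), 3)  # two bounded bins + overflow
  small <- cells[cells$size_bin == "[0,1000)", ]
  expect_equal(small$n_truth, 1)
  expect_equal(small$sensitivity, 1)
  mid <- cells[cells$size_bin == "[1000,5000)", ]
  expect_equal(mid$n_truth, 2)  # size 1000 belongs to [1000,5000), not [0,1000)
  expect_equal(mid$sensitivity, 0.5)
  over <- cells[cells$size_bin == "[5000,Inf)", ]
  expect_equal(over$n_truth, 1)
  expect_equal(over$sensitivity, 0)
  # empty bin reports NA sensitivity
  cells2 <- sensitivity_by_size(truth[1, ], calls[1, ], bins = bins,
                                depth_label = 10, tool = "t", callset = "c")
  expect_true(is.na(cells2$sensitivity[cells2$size_bin == "[1000,5000)"]))
  expect_error(sensitivity_by_size(truth, calls, bins = c(5000, 1000),
                                   depth_label = 10, tool = "t", callset = "c"),
               "strictly increasing")
})

test_that("qualification requires truth counts at every depth and variation", {
  cells <- tidyr::expand_grid(
    tool = "t", callset = "c", size_bin = c("A", "B", "C"),
    depth_label = c(10, 20)
  )
  cells$n_truth <- ifelse(cells$size_bin == "A", 3L, 20L)
  cells$sensitivity <- dplyr::case_when(
    cells$size_bin == "B" ~ 0.5,                       # flat profile
    cells$depth_label == 10 ~ 0.4, TRUE ~ 0.9
  )
  q <- qualified_size_bins(cells, min_truth = 10, require_variation = TRUE)
  expect_setequal(unique(q$size_bin), "C")
  # identity settings admit everything
  q2 <- qualified_size_bins(cells, min_truth = 0, require_variation = FALSE)
  expect_equal(nrow(q2), nrow(cells))
})

test_that("MDI counts minima with ties and sums to one", {
  # 4 groups: depth 10 is the unique minimum in 3, depth 20 in 1
  grid <- tidyr::expand_grid(tool = "t", callset = "c",
                             size_bin = c("A", "B", "C", "D"),
                             depth_label = c(10, 20, 30))
  grid$n_truth <- 50L
  grid$sensitivity <- with(grid, dplyr::case_when(
    size_bin != "D" & depth_label == 10 ~ 0.2,
    size_bin == "D" & depth_label == 20 ~ 0.1,
    TRUE ~ 0.8 + depth_label / 1000  # break flatness, keep non-minimal
  ))
  m <- compute_mdi(qualified_size_bins(grid, min_truth = 10))
  expect_equal(m$mdi[m$depth_label == 10], 0.75)
  expect_equal(m$mdi[m$depth_label == 20], 0.25)
  expect_equal(m$mdi[m$depth_label == 30], 0)
  expect_equal(sum(m$mdi), 1)
  # ties: both depths attaining the minimum increment M and N
  tie <- grid[grid$size_bin == "A", ]
  tie$sensitivity <- c(0.2, 0.2, 0.9)
  mt <- compute_mdi(tie)
  expect_equal(mt$M, c(1, 1, 0))
  expect_equal(mt$N, rep(2, 3))
  expect_equal(sum(mt$mdi), 1)
  # single depth is degenerate: mdi = 1
  single <- grid[grid$size_bin == "A" & grid$depth_label == 10, ]
  ms <- compute_mdi(qualified_size_bins(single, require_variation = FALSE))
  expect_equal(ms$mdi, 1)
  expect_error(compute_mdi(grid[0, ]), "no qualified groups")
  # agreement with the plain-loop re-count
  bf <- brute_force_mdi(grid, depths = c(10, 20, 30), min_truth = 10)
  expect_equal(m$mdi, bf$mdi)
})

test_that("adding a group with its minimum at depth d weakly increases mdi_d", {
  base <- tidyr::expand_grid(tool = "t", callset = "c", size_bin = c("A", "B"),
                             depth_label = c(10, 20))
  base$n_truth <- 50L
  base$sensitivity <- c(0.2, 0.8, 0.3, 0.9)  # both minima at depth 10
  m0 <- compute_mdi(base)
  extra <- base[base$size_bin == "A", ]
  extra$size_bin <- "Z"
  extra$sensitivity <- c(0.9, 0.1)  # minimum at depth 20
  m1 <- compute_mdi(dplyr::bind_rows(base, extra))
  expect_gte(m1$mdi[m1$depth_label == 20], m0$mdi[m0$depth_label == 20])
})

test_that("consensus compilation deduplicates and counts strict tool support", {
  a <- cnv_tbl(100, 200)
  b <- cnv_tbl(100, 200)        # identical in second set: one consensus record
  other <- cnv_tbl(10000, 12000)
  cons <- compile_consensus_callset(
    list(dplyr::bind_rows(a, other), b),
    tool_detections = list(
      tool1 = cnv_tbl(100, 200), tool2 = cnv_tbl(105, 205), tool3 = cnv_tbl(5000, 6000)
    ),
    threshold = 0.5
  )
  expect_equal(nrow(cons), 2)
  rec <- cons[cons$start == 100, ]
  expect_equal(rec$n_supporting_tools, 2L)
  expect_true(all(cons$needs_manual_review))
  expect_equal(cons$n_supporting_tools[cons$start == 10000], 0L)
  # empty detections retain everything with zero support
  cons2 <- compile_consensus_callset(list(a, b), tool_detections = list())
  expect_equal(cons2$n_supporting_tools, 0L)
  # support threshold is strict: RO exactly 0.5 does not count
  cons3 <- compile_consensus_callset(
    list(a, b), tool_detections = list(t1 = cnv_tbl(150, 250)), threshold = 0.5
  )
  expect_equal(cons3$n_supporting_tools, 0L)
})
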
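test_that("read_bed parses, merges and validates", {
  p <- write_lines_tmp(c("chr1\t0\t100"), ".bed")
  b <- read_bed(p)
  expect_equal(nrow(b), 1)
  expect_equal(total_bases(b), 100)

  p2 <- write_lines_tmp(c("chr1\t0\t100", "chr1\t50\t150"), ".bed")
  b2 <- read_bed(p2)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$start, 0)
  expect_equal(b2$end, 150)
  expect_equal(total_bases(b2), 150)

  p3 <- write_lines_tmp(character(), ".bed")
  b3 <- read_bed(p3)
  expect_equal(nrow(b3), 0)
  expect_equal(total_bases(b3), 0)

  expect_error(read_bed(write_lines_tmp("chr1\tfoo\t100")), "line 1")
  expect_error(read_bed(write_lines_tmp(c("chr1\t0\t10", "chr1\t20\t5"))), "line 2")
  # labels survive an unmerged read
  p4 <- write_lines_tmp("chr1\t0\t10\tACMG59", ".bed")
  expect_equal(read_bed(p4, merge = FALSE)$label, "ACMG59")
})

test_that("merging is idempotent and order-invariant", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    s <- sample.int(500, n)
    x <- intervals(sample(c("chr1", "chr2"), n, replace = TRUE), s, s + sample.int(60, n))
    m1 <- merge_intervals(x)
    expect_identical(merge_intervals(m1), m1)
    m2 <- merge_intervals(x[sample.int(n), ])
    expect_identical(m2, m1)
    expect_equal(total_bases(x), total_bases(m1))
  }
})

test_that("interval overlap agrees with a per-base set-intersection oracle", {
  set.seed(42)
  for (i in 1:1000) {
    s1 <- sample.int(1000, 1); l1 <- sample.int(200, 1)
    s2 <- sample.int(1000, 1); l2 <- sample.int(200, 1)
    a <- intervals("chr1", s1, s1 + l1)
    b <- intervals("chr1", s2, s2 + l2)
    got <- total_bases(intersect_intervals(a, b))
    want <- length(intersect(seq.int(s1 + 1, s1 + l1), seq.int(s2 + 1, s2 + l2)))
    expect_identical(as.integer(got), as.integer(want))
  }
})

test_that("restrict_to_regions uses exact 1-based/0-based conversion", {
  call100 <- make_calls(100)
  # region [99,100) covers 1-based position 100
  expect_equal(nrow(restrict_to_regions(call100, intervals("chr1", 99, 100))), 1)
  # region [100,200) covers 1-based 101..200, so position 100 is excluded
  expect_equal(nrow(restrict_to_regions(call100, intervals("chr1", 100, 200))), 0)
  expect_equal(nrow(restrict_to_regions(make_calls(101), intervals("chr1", 100, 200))), 1)
  # empty regions, chrom mismatch, subset property
  empty <- intervals("chr1", 0, 1)[0, ]
  expect_equal(nrow(restrict_to_regions(call100, empty)), 0)
  expect_equal(nrow(restrict_to_regions(make_calls(100, chrom = "chr2"),
                                        intervals("chr1", 0, 1000))), 0)
  set.seed(5)
  calls <- make_calls(sample.int(1000, 50))
  kept <- restrict_to_regions(calls, intervals("chr1", 200, 400))
  expect_true(all(kept$pos %in% calls$pos))
  expect_true(all(kept$pos >= 201 & kept$pos <= 400))
})

test_that("VCF reading maps genotypes and splits multiallelics", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t10\t.\tA\tG\t.\tPASS\t.\tGT:GQ:DP\t0/1:50:30",
    "chr1\t20\t.\tA\tAT\t.\tPASS\t.\tGT:GQ:DP\t1/1:60:25",
    "chr1\t30\t.\tA\tG,T\t.\tPASS\t.\tGT:GQ:DP\t1/2:40:22",
    "chr1\t40\t.\tC\tT\t.\tPASS\t.\tGT\t./.",
    "chr1\t50\t.\tG\tA\t.\tPASS\t.\tGT:GQ:DP\t0/0:99:31"
  )
  p <- write_lines_tmp(vcf, ".vcf")
  calls <- read_vcf_calls(p)
  expect_equal(calls$zygosity[calls$pos == 10], "het")
  expect_equal(calls$vclass[calls$pos == 10], "SNP")
  expect_equal(calls$zygosity[calls$pos == 20], "hom_alt")
  expect_equal(calls$vclass[calls$pos == 20], "indel")
  multi <- calls[calls$pos == 30, ]
  expect_equal(nrow(multi), 2)
  expect_setequal(multi$alt, c("G", "T"))
  expect_equal(unique(multi$zygosity), "het")
  expect_equal(calls$zygosity[calls$pos == 40], "missing")
  expect_true(is.na(calls$GQ[calls$pos == 40]))
  expect_equal(calls$zygosity[calls$pos == 50], "hom_ref")
  expect_error(read_vcf_calls(p, sample = "NOPE"), "sample not found")
})

test_that("VCF writing round-trips through the reader", {
  set.seed(9)
  sim <- simulate_truth_and_calls(n_variants = 120, seed = 9)
  p <- tempfile(fileext = ".vcf")
  write_vcf(sim$truth, p)
  back <- read_vcf_calls(p)
  orig <- dplyr::arrange(sim$truth, chrom, pos, alt)
  expect_equal(as.data.frame(back), as.data.frame(orig))
  # gzip output is readable too
  pz <- tempfile(fileext = ".vcf.gz")
  write_vcf(sim$truth, pz)
  expect_equal(as.data.frame(read_vcf_calls(pz)), as.data.frame(orig))
})

test_that("depth tables keep declared positions and reject bad depths", {
  regions <- intervals("chr1", 0, 10)
  p <- write_lines_tmp(c("chr1 5 12", "chr1 50 3"), ".tsv")
  expect_message(prof <- read_depth_table(p, regions), "dropped 1")
  expect_equal(prof$entries$pos, 5)
  expect_equal(prof$entries$depth, 12)
  p2 <- write_lines_tmp("chr1 5 -2", ".tsv")
  expect_error(read_depth_table(p2, regions), "negative depth")
})
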
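parent_call <- function(pos, zygosity, DP = 30L, GQ = 60L, chrom = "chr1") {
  make_calls(pos, zygosity = zygosity, DP = DP, GQ = GQ, chrom = chrom)
}

test_that("informative loci require the hom_ref/hom_alt parental pattern with gates", {
  father <- parent_call(100, "hom_ref", DP = 20L, GQ = 50L)
  mother <- parent_call(100, "hom_alt", DP = 30L, GQ = 60L)
  loci <- select_informative_loci(father, mother)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$alt_parent, "mother")
  expect_equal(loci$expected_offspring, "het")

  # both hom_ref: not informative
  expect_equal(nrow(select_informative_loci(father, parent_call(100, "hom_ref"))), 0)
  # het parent: not informative
  expect_equal(nrow(select_informative_loci(parent_call(100, "het"), mother)), 0)
  # DP gate on the alt parent
  low_dp <- parent_call(100, "hom_alt", DP = 9L)
  expect_equal(nrow(select_informative_loci(father, low_dp)), 0)
  # GQ gate on the ref parent
  low_gq <- parent_call(100, "hom_ref", GQ = 19L)
  expect_equal(nrow(select_informative_loci(low_gq, mother)), 0)
  # absent hom_ref record is not informative by default, but can be opted in
  expect_equal(nrow(select_informative_loci(father[0, ], mother)), 0)
  expect_equal(nrow(select_informative_loci(father[0, ], mother,
                                            absent_as_hom_ref = TRUE)), 1)
  # conflicting duplicate records are dropped
  dup <- dplyr::bind_rows(father, parent_call(100, "hom_alt"))
  expect_message(out <- select_informative_loci(dup, mother), "conflicting")
  expect_equal(nrow(out), 0)
})

test_that("chrX loci are emitted only for a maternal alt allele, as hemizygous", {
  fa_x <- parent_call(500, "hom_alt", chrom = "chrX")
  mo_x <- parent_call(500, "hom_ref", chrom = "chrX")
  # father-alt X locus: excluded for a male offspring
  expect_equal(nrow(select_informative_loci(fa_x, mo_x)), 0)
  # mother-alt X locus: hemizygous expectation
  loci <- select_informative_loci(parent_call(500, "hom_ref", chrom = "chrX"),
                                  parent_call(500, "hom_alt", chrom = "chrX"))
  expect_equal(loci$expected_offspring, "hemi")
  expect_equal(nrow(select_informative_loci(
    parent_call(500, "hom_ref", chrom = "chrX"),
    parent_call(500, "hom_alt", chrom = "chrX"),
    autosomes_only = TRUE
  )), 0)
})

test_that("offspring evaluation uses the stated sensitivity and PPV denominators", {
  set.seed(61)
  n <- 100
  father <- parent_call(1:n, "hom_ref")
  mother <- parent_call(1:n, "hom_alt")
  loci <- select_informative_loci(father, mother)
  expect_equal(nrow(loci), n)
  # offspring: het at 97, hom_alt at 2, missing at 1
  offspring <- dplyr::bind_rows(
    parent_call(1:97, "het"),
    parent_call(98:99, "hom_alt")
  )
  ev <- evaluate_offspring(loci, offspring)
  all_row <- ev[ev$vclass == "all", ]
  expect_equal(all_row$sensitivity, 0.97)
  expect_equal(all_row$ppv, 97 / 99)
  # perfect offspring
  ev2 <- evaluate_offspring(loci, parent_call(1:n, "het"))
  expect_equal(ev2$sensitivity[ev2$vclass == "all"], 1)
  expect_equal(ev2$ppv[ev2$vclass == "all"], 1)
  expect_error(evaluate_offspring(loci[0, ], offspring), "no informative loci")
})

test_that("tightening the gates never increases the locus count", {
  sim <- simulate_trio(n_loci = 300, seed = 71)
  base <- nrow(select_informative_loci(sim$father, sim$mother, min_dp = 10, min_gq = 20))
  tighter_dp <- nrow(select_informative_loci(sim$father, sim$mother, min_dp = 40, min_gq = 20))
  tighter_gq <- nrow(select_informative_loci(sim$father, sim$mother, min_dp = 10, min_gq = 80))
  expect_lte(tighter_dp, base)
  expect_lte(tighter_gq, base)
})

test_that("every emitted locus re-verifies the parental pattern against inputs", {
  sim <- simulate_trio(n_loci = 400, n_decoys = 150, seed = 81)
  loci <- select_informative_loci(sim$father, sim$mother, sim$regions)
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt)
  fk <- key(sim$father); mk <- key(sim$mother)
  for (i in seq_len(nrow(loci))) {
    f <- sim$father[match(key(loci[i, ]), fk), ]
    m <- sim$mother[match(key(loci[i, ]), mk), ]
    expect_true(
      (f$zygosity == "hom_ref" && m$zygosity == "hom_alt") ||
        (f$zygosity == "hom_alt" && m$zygosity == "hom_ref")
    )
    expect_true(f$DP >= 10 && f$GQ >= 20 && m$DP >= 10 && m$GQ >= 20)
  }
  # decoy-only input yields no loci, and the evaluator then errors
  decoys_f <- sim$father[sim$father$zygosity == "het", ]
  decoys_m <- sim$mother[sim$mother$zygosity == "het", ]
  none <- select_informative_loci(decoys_f, decoys_m)
  expect_equal(nrow(none), 0)
  expect_error(evaluate_offspring(none, sim$offspring), "no informative loci")
})

test_that("trio recovery matches the generator's recorded expectations", {
  sim <- simulate_trio(n_loci = 2000, r = 0.97, e = 0.02, seed = 91)
  loci <- select_informative_loci(sim$father, sim$mother, sim$regions)
  ev <- evaluate_offspring(loci, sim$offspring)
  all_row <- ev[ev$vclass == "all", ]
  # exact agreement with realized bookkeeping
  expect_equal(all_row$n_correct, sim$expected$realized$n_correct)
  expect_equal(all_row$n_called, sim$expected$realized$n_called)
  expect_equal(all_row$sensitivity, sim$expected$realized$sensitivity)
  expect_equal(all_row$ppv, sim$expected$realized$ppv)
  # within 3 binomial SE of the analytic expectation
  p_sens <- sim$expected$analytic$sensitivity
  se_sens <- sqrt(p_sens * (1 - p_sens) / 2000)
  expect_lt(abs(all_row$sensitivity - p_sens), 3 * se_sens)
})
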
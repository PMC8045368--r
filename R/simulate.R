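#' Seeded synthetic truth/query variant call sets
#'
#' Generates a truth call set placed uniformly (without collision) on a
#' single synthetic contig, and a query call set derived from it with known
#' error structure: per-stratum Bernoulli misses (`p_fn`), Poisson false
#' positives at novel positions (`fp_rate` per truth variant), Bernoulli
#' zygosity flips (`gt_error`, het <-> hom_alt), and a configurable fraction
#' of query calls whose GQ/DP fall below the 20/10 gates. The generator
#' records its ground truth: analytic per-stratum expectations and the
#' realized counts after all coin flips, so benchmark output can be asserted
#' exactly.
#'
#' Strata are variant class (SNP/indel) x zygosity (hom_alt/het); counts per
#' stratum are allocated deterministically from the mixes.
#'
#' @param n_variants Total truth variants.
#' @param region_length Contig length in bases (must exceed the variants
#'   plus expected false positives).
#' @param class_mix Fraction of SNPs (vs indels).
#' @param zygosity_mix Fraction of het (vs hom_alt) calls.
#' @param p_fn Miss probability; scalar or named per stratum
#'   (names like "SNP.het").
#' @param fp_rate Expected false positives per truth variant.
#' @param gt_error Probability a detected variant gets the wrong zygosity.
#' @param gate_fail_frac Fraction of query calls drawn with GQ or DP below
#'   the default gates.
#' @param chrom Contig name.
#' @param seed Mandatory RNG seed.
#' @return List with `truth` and `query` call tibbles, `regions` (the
#'   confident region covering the contig), and `expected`: a list with
#'   `analytic` (tibble of per-stratum expected sensitivity/ppv) and
#'   `realized` (per-stratum and overall counts the benchmark must
#'   reproduce exactly under genotype-aware matching and default gates).
#' @export
simulate_truth_and_calls <- function(n_variants = 1000, region_length = 10 * n_variants,
                                     class_mix = 0.5, zygosity_mix = 0.5,
                                     p_fn = 0.05, fp_rate = 0.05, gt_error = 0,
                                     gate_fail_frac = 0, chrom = "chr1",
                                     seed) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(n_variants > 0, all(p_fn >= 0 & p_fn <= 1),
            gt_error >= 0, gt_error <= 1, fp_rate >= 0)
  n_fp_budget <- ceiling(n_variants * (fp_rate + 1) * 2)
  if (region_length < n_variants + n_fp_budget) {
    abort("region too small for the requested number of variants")
  }
  set.seed(seed)
  strata <- tidyr::expand_grid(vclass = c("SNP", "indel"),
                               zygosity = c("hom_alt", "het"))
  n_snp <- round(n_variants * class_mix)
  n_het_snp <- round(n_snp * zygosity_mix)
  n_het_ind <- round((n_variants - n_snp) * zygosity_mix)
  strata$n <- c(n_snp - n_het_snp, n_het_snp,
                (n_variants - n_snp) - n_het_ind, n_het_ind)
  strata <- strata[strata$n > 0, ]
  p_fn_of <- function(vclass, zygosity) {
    if (length(p_fn) == 1 && is.null(names(p_fn))) return(rep(p_fn, length(vclass)))
    unname(p_fn[paste(vclass, zygosity, sep = ".")])
  }

  pos_all <- sample.int(region_length, n_variants + n_fp_budget)
  pos_truth <- pos_all[seq_len(n_variants)]
  pos_novel <- pos_all[-seq_len(n_variants)]

  bases <- c("A", "C", "G", "T")
  make_alleles <- function(vclass, n) {
    ref <- sample(bases, n, replace = TRUE)
    if (n == 0) return(tibble(ref = character(), alt = character()))
    alt <- purrr::map_chr(ref, function(r) sample(setdiff(bases, r), 1))
    if (vclass == "indel") {
      ins <- runif(n) < 0.5
      alt <- ifelse(ins, paste0(ref, alt), ref)
      ref <- ifelse(ins, ref, paste0(ref, sample(bases, n, replace = TRUE)))
      # guard against rare ref == alt after construction
      fix <- ref == alt
      ref[fix] <- paste0(alt[fix], "A")
    }
    tibble(ref = ref, alt = alt)
  }
  draw_quals <- function(n, fail) {
    gq <- sample(30:99, n, replace = TRUE)
    dp <- sample(20:60, n, replace = TRUE)
    failing <- runif(n) < fail
    if (any(failing)) {
      side <- runif(sum(failing)) < 0.5
      gq[failing][side] <- sample(0:19, sum(side), replace = TRUE)
      dp[failing][!side] <- sample(0:9, sum(!side), replace = TRUE)
    }
    list(GQ = gq, DP = dp, failing = failing)
  }

  truth_rows <- purrr::pmap(strata, function(vclass, zygosity, n) {
    al <- make_alleles(vclass, n)
    tibble(vclass = vclass, zygosity = zygosity, ref = al$ref, alt = al$alt)
  })
  truth <- bind_rows(truth_rows)
  truth$chrom <- chrom
  truth$pos <- pos_truth
  truth$GQ <- 99L
  truth$DP <- 50L
  truth <- truth[, c("chrom", "pos", "ref", "alt", "zygosity", "vclass", "GQ", "DP")]

  p_miss <- p_fn_of(truth$vclass, truth$zygosity)
  detected <- runif(n_variants) >= p_miss
  flip <- detected & (runif(n_variants) < gt_error)
  q <- truth[detected, ]
  q_flip <- flip[detected]
  q$zygosity[q_flip] <- ifelse(q$zygosity[q_flip] == "het", "hom_alt", "het")
  quals <- draw_quals(nrow(q), gate_fail_frac)
  q$GQ <- quals$GQ; q$DP <- quals$DP
  q_pass <- !quals$failing

  n_fp <- min(rpois(1, fp_rate * n_variants), length(pos_novel))
  fp <- tibble(
    chrom = chrom,
    pos = pos_novel[seq_len(n_fp)],
    vclass = sample(c("SNP", "indel"), n_fp, replace = TRUE,
                    prob = c(class_mix, 1 - class_mix)),
    zygosity = sample(c("het", "hom_alt"), n_fp, replace = TRUE,
                      prob = c(zygosity_mix, 1 - zygosity_mix))
  )
  fp_alleles <- bind_rows(
    make_alleles("SNP", sum(fp$vclass == "SNP")),
    make_alleles("indel", sum(fp$vclass == "indel"))
  )
  fp <- bind_rows(fp[fp$vclass == "SNP", ], fp[fp$vclass == "indel", ])
  fp$ref <- fp_alleles$ref; fp$alt <- fp_alleles$alt
  fp_quals <- draw_quals(n_fp, gate_fail_frac)
  fp$GQ <- fp_quals$GQ; fp$DP <- fp_quals$DP
  fp <- fp[, names(truth)]
  query <- bind_rows(q, fp) %>% arrange(.data$pos)

  # ground truth after all coin flips, under default gates + genotype-aware match
  tp_vec <- detected & !flip
  tp_vec[detected] <- tp_vec[detected] & q_pass
  realized_per <- truth %>%
    mutate(tp = tp_vec) %>%
    group_by(.data$vclass, .data$zygosity) %>%
    summarise(n_truth = n(), tp = sum(.data$tp), .groups = "drop") %>%
    mutate(fn = .data$n_truth - .data$tp,
           sensitivity = .data$tp / .data$n_truth)
  n_query_pass <- sum(q_pass) + sum(!fp_quals$failing)
  realized_overall <- tibble(
    n_truth = n_variants,
    tp = sum(tp_vec),
    fn = n_variants - sum(tp_vec),
    n_query = n_query_pass,
    fp = n_query_pass - sum(tp_vec),
    sensitivity = sum(tp_vec) / n_variants,
    ppv = sum(tp_vec) / n_query_pass
  )
  analytic <- strata %>%
    mutate(
      p_fn = p_fn_of(.data$vclass, .data$zygosity),
      sensitivity = (1 - .data$p_fn) * (1 - gt_error) * (1 - gate_fail_frac)
    )
  list(
    truth = truth, query = query,
    regions = intervals(chrom, 0, region_length),
    expected = list(analytic = analytic, realized_per_stratum = realized_per,
                    realized_overall = realized_overall),
    params = list(n_variants = n_variants, p_fn = p_fn, fp_rate = fp_rate,
                  gt_error = gt_error, gate_fail_frac = gate_fail_frac,
                  seed = seed)
  )
}

#' Seeded synthetic per-base depth profile
#'
#' Per-base depths are drawn i.i.d. negative-binomial (mean `mean`,
#' dispersion `size = dispersion`), then a `dropout` fraction of bases is
#' forced to zero, mimicking uncovered blocks. The exact analytic breadth
#' expectation at each threshold is recorded:
#' breadth(t) = (1 - dropout) * P(NB >= t) for t >= 1, and 1 at t <= 0.
#'
#' @param region_length Number of bases on the synthetic contig.
#' @param mean,dispersion Negative-binomial mean and size.
#' @param dropout Fraction of bases forced to depth 0.
#' @param thresholds Depth thresholds at which to record expectations.
#' @param chrom Contig name.
#' @param seed Mandatory RNG seed.
#' @return List with `profile` (a [depth_profile()]; zero-depth bases are
#'   implicit) and `expected` (tibble of threshold, expected breadth).
#' @export
simulate_depth_profile <- function(region_length = 1e5, mean = 40,
                                   dispersion = 10, dropout = 0,
                                   thresholds = c(1, 10, 20),
                                   chrom = "chr1", seed) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(dropout >= 0, dropout <= 1, mean >= 0)
  set.seed(seed)
  depth <- if (mean == 0) integer(region_length) else
    rnbinom(region_length, size = dispersion, mu = mean)
  drop <- runif(region_length) < dropout
  depth[drop] <- 0L
  nz <- which(depth > 0)
  entries <- tibble(chrom = chrom, pos = nz, depth = as.integer(depth[nz]))
  regions <- intervals(chrom, 0, region_length)
  expected <- tibble(
    threshold = thresholds,
    expected_breadth = purrr::map_dbl(thresholds, function(t) {
      if (t <= 0) return(1)
      tail_p <- if (mean == 0) 0 else
        pnbinom(t - 1, size = dispersion, mu = mean, lower.tail = FALSE)
      (1 - dropout) * tail_p
    })
  )
  list(profile = depth_profile(entries, regions), expected = expected,
       params = list(mean = mean, dispersion = dispersion, dropout = dropout,
                     region_length = region_length, seed = seed))
}

#' Seeded synthetic CNV benchmark with size-dependent detection
#'
#' Generates truth CNV sets (per call-set label) with `n_per_bin` events per
#' size bin (sizes log-uniform within the bin, types mostly deletions),
#' placed with generous gaps so a call can only match its own truth event.
#' For every tool x depth, each truth CNV is detected independently with
#' probability `p_detect(bin_index, depth, tool)`; detected calls get
#' breakpoint jitter of at most `jitter` x size per side, which keeps
#' reciprocal overlap >= (1 - 2 jitter) / (1 + 2 jitter) — validated against
#' `ro_threshold` up front.
#'
#' The generator records the realized sensitivity grid and a brute-force
#' (plain-loop) miss-detection-index table computed from that grid, as the
#' independent oracle for [compute_mdi()].
#'
#' @param n_per_bin Truth CNVs per size bin and call set.
#' @param bins Size-bin edges in bases (as in [sensitivity_by_size()]); the
#'   generator fills the bounded bins only (no overflow events).
#' @param depths Numeric mean-depth labels.
#' @param tools Character tool labels.
#' @param callsets Character call-set labels.
#' @param p_detect `function(bin_index, depth, tool)` returning a detection
#'   probability; the default increases with depth.
#' @param jitter Max breakpoint jitter per side, as a fraction of size.
#' @param ro_threshold Reciprocal-overlap threshold the jitter must respect.
#' @param p_dup Fraction of duplications among truth CNVs.
#' @param min_truth,require_variation Qualification rule used for the
#'   recorded oracle MDI.
#' @param chrom Contig name.
#' @param seed Mandatory RNG seed.
#' @return List with `truth` (CNV tibble with `source` = call set), `calls`
#'   (detected CNV tibble with `tool`, `depth_label`), `cells` (realized
#'   sensitivity grid), `mdi_oracle` (brute-force MDI tibble or NULL when no
#'   group qualifies), `bins`, and `params`.
#' @export
simulate_cnv_benchmark <- function(n_per_bin = 50,
                                   bins = c(1e3, 5e3, 1e4, 5e4),
                                   depths = c(10, 20, 30, 40),
                                   tools = "cnvtoolA",
                                   callsets = "set1",
                                   p_detect = NULL,
                                   jitter = 0.1, ro_threshold = 0.5,
                                   p_dup = 0.1,
                                   min_truth = 10, require_variation = TRUE,
                                   chrom = "chr1", seed) {
  if (missing(seed)) abort("seed is mandatory")
  worst_ro <- (1 - 2 * jitter) / (1 + 2 * jitter)
  if (worst_ro < ro_threshold) {
    abort("jitter incompatible with reciprocal-overlap threshold")
  }
  if (is.null(p_detect)) {
    p_detect <- function(bin_index, depth, tool) {
      stats::plogis(-1.5 + 0.06 * depth + 0.1 * bin_index)
    }
  }
  set.seed(seed)
  edges <- c(50, bins)  # smallest simulated size: 50 bp
  n_bins <- length(bins)
  truth_list <- list()
  cursor <- 0
  for (cs in callsets) {
    sizes <- unlist(purrr::map(seq_len(n_bins), function(b) {
      lo <- edges[b]; hi <- edges[b + 1]
      round(exp(runif(n_per_bin, log(lo), log(hi - 1))))
    }))
    bin_idx <- rep(seq_len(n_bins), each = n_per_bin)
    starts <- numeric(length(sizes))
    for (i in seq_along(sizes)) {
      cursor <- cursor + 3 * sizes[i]
      starts[i] <- cursor
      cursor <- cursor + 3 * sizes[i]
    }
    truth_list[[cs]] <- tibble(
      chrom = chrom, start = as.integer(starts),
      end = as.integer(starts + sizes),
      cnv_type = ifelse(runif(length(sizes)) < p_dup, "DUP", "DEL"),
      source = cs, size = as.integer(sizes), bin_index = bin_idx
    )
  }
  if (cursor > .Machine$integer.max) {
    abort("simulated contig exceeds integer coordinates; reduce n_per_bin or bins")
  }
  truth <- bind_rows(truth_list)

  calls <- list()
  cells <- list()
  for (cs in callsets) {
    tr <- truth_list[[cs]]
    for (tool in tools) {
      for (d in depths) {
        p <- purrr::map_dbl(tr$bin_index, ~ p_detect(.x, d, tool))
        det <- runif(nrow(tr)) < p
        if (any(det)) {
          sz <- tr$size[det]
          ds <- round(runif(sum(det), -jitter, jitter) * sz)
          de <- round(runif(sum(det), -jitter, jitter) * sz)
          calls[[length(calls) + 1]] <- tibble(
            chrom = chrom,
            start = as.integer(tr$start[det] + ds),
            end = as.integer(tr$end[det] + de),
            cnv_type = tr$cnv_type[det],
            source = tool, tool = tool, depth_label = d, callset = cs
          )
        }
        cells[[length(cells) + 1]] <- tibble(
          bin_index = seq_len(n_bins),
          n_truth = as.integer(table(factor(tr$bin_index, seq_len(n_bins)))),
          n_matched = as.integer(tapply(det, factor(tr$bin_index, seq_len(n_bins)),
                                        sum, default = 0L)),
          depth_label = d, tool = tool, callset = cs
        )
      }
    }
  }
  calls <- bind_rows(calls)
  if (nrow(calls) > 0) calls$size <- calls$end - calls$start
  bin_labels <- size_bin_labels(edges[seq_len(n_bins)], bins)
  cells <- bind_rows(cells) %>%
    mutate(size_bin = bin_labels[.data$bin_index],
           sensitivity = .data$n_matched / .data$n_truth) %>%
    select("depth_label", "tool", "callset", "size_bin",
           "n_truth", "n_matched", "sensitivity")

  mdi_oracle <- brute_force_mdi(cells, depths, min_truth, require_variation)

  list(truth = truth[, c("chrom", "start", "end", "cnv_type", "source", "size")],
       calls = calls, cells = cells, mdi_oracle = mdi_oracle, bins = bins,
       params = list(n_per_bin = n_per_bin, depths = depths, tools = tools,
                     callsets = callsets, jitter = jitter,
                     ro_threshold = ro_threshold, seed = seed))
}

#' Brute-force miss-detection-index re-count
#'
#' Independent plain-loop implementation of the MDI statistic used as an
#' oracle for [compute_mdi()]: iterates over every (tool, call set, size bin)
#' group that passes the qualification rule, finds all depths attaining the
#' group's minimum sensitivity, and tallies minima events.
#'
#' @param cells Sensitivity-cell tibble.
#' @param depths Depth labels in reporting order.
#' @param min_truth,require_variation Qualification rule.
#' @return Tibble with `depth_label`, `M`, `N`, `mdi`, or NULL when no group
#'   qualifies.
#' @export
brute_force_mdi <- function(cells, depths = unique(cells$depth_label),
                            min_truth = 10, require_variation = TRUE) {
  M <- setNames(numeric(length(depths)), as.character(depths))
  N <- 0
  groups <- unique(cells[, c("tool", "callset", "size_bin")])
  for (g in seq_len(nrow(groups))) {
    sub <- cells[cells$tool == groups$tool[g] &
                   cells$callset == groups$callset[g] &
                   cells$size_bin == groups$size_bin[g], ]
    if (nrow(sub) != length(depths)) next
    if (any(sub$n_truth < min_truth)) next
    if (anyNA(sub$sensitivity)) next
    if (require_variation && length(unique(sub$sensitivity)) == 1) next
    lows <- sub$depth_label[sub$sensitivity == min(sub$sensitivity)]
    for (d in lows) {
      M[as.character(d)] <- M[as.character(d)] + 1
      N <- N + 1
    }
  }
  if (N == 0) return(NULL)
  tibble(depth_label = depths, M = unname(M), N = N, mdi = unname(M) / N)
}

#' Seeded synthetic trio with Mendelian informative loci
#'
#' Generates parental call sets containing `n_loci` informative loci (one
#' parent an explicit hom_ref record, the other hom_alt, both passing the
#' DP/GQ gates) plus `n_decoys` non-informative background loci (both
#' parents het). The offspring carries a gate-passing call at each
#' informative locus with probability `r`; a called genotype is the expected
#' het with probability 1 - `e` and a hom_alt miscall with probability `e`;
#' otherwise the locus is missing from the offspring. So the analytic
#' expectation is sensitivity = r (1 - e) and PPV = 1 - e.
#'
#' @param n_loci Number of informative loci.
#' @param r Offspring call rate at informative loci.
#' @param e Genotype-error rate among called loci.
#' @param n_decoys Non-informative background loci.
#' @param region_length Contig length.
#' @param class_mix Fraction of SNP loci.
#' @param chrom Contig name.
#' @param seed Mandatory RNG seed.
#' @return List with `father`, `mother`, `offspring` call tibbles, `loci`
#'   (the informative-locus truth), `regions`, and `expected` (analytic and
#'   realized sensitivity/PPV).
#' @export
simulate_trio <- function(n_loci = 1000, r = 0.97, e = 0.02, n_decoys = 200,
                          region_length = 20 * (n_loci + n_decoys),
                          class_mix = 0.5, chrom = "chr1", seed) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(r >= 0, r <= 1, e >= 0, e <= 1, n_loci > 0)
  set.seed(seed)
  n_all <- n_loci + n_decoys
  pos <- sample.int(region_length, n_all)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_all, replace = TRUE)
  alt <- purrr::map_chr(ref, function(x) sample(setdiff(bases, x), 1))
  is_snp <- runif(n_all) < class_mix
  alt <- ifelse(is_snp, alt, paste0(ref, alt))
  base <- tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    vclass = ifelse(is_snp, "SNP", "indel")
  )
  informative <- seq_len(n_loci)
  alt_parent <- sample(c("father", "mother"), n_loci, replace = TRUE)

  quals <- function(n) list(GQ = sample(30:99, n, replace = TRUE),
                            DP = sample(20:60, n, replace = TRUE))
  parent_calls <- function(which_parent) {
    zyg <- c(ifelse(alt_parent == which_parent, "hom_alt", "hom_ref"),
             rep("het", n_decoys))
    qq <- quals(n_all)
    mutate(base, zygosity = zyg, GQ = qq$GQ, DP = qq$DP)[
      , c("chrom", "pos", "ref", "alt", "zygosity", "vclass", "GQ", "DP")]
  }
  father <- parent_calls("father")
  mother <- parent_calls("mother")

  called <- runif(n_loci) < r
  err <- called & (runif(n_loci) < e)
  off_rows <- base[informative, ][called, ]
  off_rows$zygosity <- ifelse(err[called], "hom_alt", "het")
  # offspring also inherits one allele at decoy loci about half the time
  decoy_called <- runif(n_decoys) < 0.5
  off_decoy <- base[n_loci + which(decoy_called), ]
  if (nrow(off_decoy) > 0) off_decoy$zygosity <- "het"
  offspring <- bind_rows(off_rows, off_decoy)
  qq <- quals(nrow(offspring))
  offspring$GQ <- qq$GQ; offspring$DP <- qq$DP
  offspring <- arrange(
    offspring[, c("chrom", "pos", "ref", "alt", "zygosity", "vclass", "GQ", "DP")],
    .data$pos)

  loci <- base[informative, ] %>%
    mutate(alt_parent = alt_parent, expected_offspring = "het") %>%
    arrange(.data$pos)
  realized <- tibble(
    n_loci = n_loci,
    n_called = sum(called),
    n_correct = sum(called & !err),
    sensitivity = sum(called & !err) / n_loci,
    ppv = sum(called & !err) / sum(called)
  )
  list(
    father = father, mother = mother, offspring = offspring, loci = loci,
    regions = intervals(chrom, 0, region_length),
    expected = list(
      analytic = tibble(sensitivity = r * (1 - e), ppv = 1 - e),
      realized = realized
    ),
    params = list(n_loci = n_loci, r = r, e = e, n_decoys = n_decoys, seed = seed)
  )
}
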
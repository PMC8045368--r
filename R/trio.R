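#' Select trio-informative loci from parental calls
#'
#' An informative locus is a site where one parent is homozygous for the
#' reference allele and the other homozygous for the alternate allele, both
#' genotypes passing the DP/GQ gates: Mendelian inheritance then forces a
#' heterozygous offspring on the autosomes, giving a family-derived truth
#' set ("gold standard set") without external validation.
#'
#' The homozygous-reference parent must carry an explicit hom_ref call at the
#' key (e.g. a 0/0 record from joint calling); by default an absent record is
#' not interpreted as reference (set `absent_as_hom_ref = TRUE` for
#' single-sample VCFs that omit reference sites, at the cost of conflating
#' no-calls with reference calls). Keys with conflicting duplicate records in
#' either parent are dropped.
#'
#' On chrX (for a male offspring) loci are emitted only when the mother is
#' the alt-homozygous parent, and the expected offspring state is
#' hemizygous-alt; `autosomes_only = TRUE` drops chrX entirely.
#'
#' @param father,mother Variant-call tibbles (including hom_ref records).
#' @param regions Optional confident-region interval tibble.
#' @param min_dp,min_gq Gates applied to both parental genotypes.
#' @param chrx Chromosome X name(s) as they appear in the data
#'   (default c("X", "chrX")).
#' @param autosomes_only Drop chrX loci.
#' @param absent_as_hom_ref Treat a parent with no record at a key as hom_ref
#'   (passing gates vacuously). Default FALSE.
#' @return Tibble of informative loci: `chrom`, `pos`, `ref`, `alt`,
#'   `vclass`, `alt_parent` ("father"/"mother"), `expected_offspring`
#'   ("het" or "hemi").
#' @export
select_informative_loci <- function(father, mother, regions = NULL,
                                    min_dp = 10, min_gq = 20,
                                    chrx = c("X", "chrX"),
                                    autosomes_only = FALSE,
                                    absent_as_hom_ref = FALSE) {
  prep <- function(calls) {
    if (!is.null(regions)) calls <- restrict_to_regions(calls, regions)
    key <- call_key(calls)
    dup <- key %in% key[duplicated(key)]
    if (any(dup)) {
      inform(paste0("dropped ", length(unique(key[dup])),
                    " loci with conflicting duplicate records"))
      calls <- calls[!dup, ]
    }
    mutate(calls,
           pass = !is.na(.data$DP) & !is.na(.data$GQ) &
             .data$DP >= min_dp & .data$GQ >= min_gq)
  }
  fa <- prep(father)
  mo <- prep(mother)
  j <- dplyr::full_join(
    select(fa, "chrom", "pos", "ref", "alt", "vclass",
           f_zyg = "zygosity", f_pass = "pass"),
    select(mo, "chrom", "pos", "ref", "alt", "vclass",
           m_zyg = "zygosity", m_pass = "pass"),
    by = c("chrom", "pos", "ref", "alt", "vclass")
  )
  if (absent_as_hom_ref) {
    j <- mutate(j,
      f_zyg = dplyr::coalesce(.data$f_zyg, "hom_ref"),
      f_pass = dplyr::coalesce(.data$f_pass, TRUE),
      m_zyg = dplyr::coalesce(.data$m_zyg, "hom_ref"),
      m_pass = dplyr::coalesce(.data$m_pass, TRUE)
    )
  }
  loci <- j %>%
    filter(
      !is.na(.data$f_zyg), !is.na(.data$m_zyg),
      .data$f_pass, .data$m_pass,
      (.data$f_zyg == "hom_alt" & .data$m_zyg == "hom_ref") |
        (.data$f_zyg == "hom_ref" & .data$m_zyg == "hom_alt")
    ) %>%
    mutate(
      alt_parent = ifelse(.data$f_zyg == "hom_alt", "father", "mother"),
      on_x = .data$chrom %in% chrx
    )
  if (autosomes_only) {
    loci <- filter(loci, !.data$on_x)
  } else {
    # male offspring: X comes from the mother, so only mother-alt X loci are
    # informative, and the expected state is hemizygous alt
    loci <- filter(loci, !.data$on_x | .data$alt_parent == "mother")
  }
  loci %>%
    mutate(expected_offspring = ifelse(.data$on_x, "hemi", "het")) %>%
    select("chrom", "pos", "ref", "alt", "vclass",
           "alt_parent", "expected_offspring") %>%
    arrange(.data$chrom, .data$pos, .data$alt)
}

#' Evaluate offspring calls against trio-informative loci
#'
#' For each informative locus the offspring should carry the expected
#' genotype (het on autosomes). Sensitivity is the fraction of loci where a
#' gate-passing offspring call has the expected zygosity; PPV conditions on
#' loci where the offspring has any gate-passing non-reference call, so a
#' homozygous-alt miscall hurts both metrics.
#'
#' @param loci Informative-locus tibble from [select_informative_loci()].
#' @param offspring Variant-call tibble for the offspring.
#' @param min_dp,min_gq Gates applied to offspring calls.
#' @return A `trio_eval`: tibble with one row per variant class (plus "all"):
#'   `vclass`, `n_loci`, `n_correct`, `n_called`, `sensitivity`, `ppv`.
#' @export
evaluate_offspring <- function(loci, offspring, min_dp = 10, min_gq = 20) {
  if (nrow(loci) == 0) abort("no informative loci to evaluate")
  off <- filter_calls(offspring, min_gq = min_gq, min_dp = min_dp)
  off <- filter(off, .data$zygosity %in% c("het", "hom_alt", "hemi"))
  j <- left_join(
    loci,
    select(off, "chrom", "pos", "ref", "alt", off_zyg = "zygosity"),
    by = c("chrom", "pos", "ref", "alt")
  ) %>%
    mutate(
      called = !is.na(.data$off_zyg),
      correct = .data$called & .data$off_zyg == .data$expected_offspring
    )
  per <- j %>%
    group_by(vclass = .data$vclass) %>%
    summarise(n_loci = n(), n_correct = sum(.data$correct),
              n_called = sum(.data$called), .groups = "drop")
  all_row <- summarise(j, vclass = "all", n_loci = n(),
                       n_correct = sum(.data$correct),
                       n_called = sum(.data$called))
  out <- bind_rows(per, all_row) %>%
    mutate(sensitivity = safe_div(.data$n_correct, .data$n_loci),
           ppv = safe_div(.data$n_correct, .data$n_called))
  class(out) <- c("trio_eval", class(out))
  out
}
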
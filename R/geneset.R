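#' Orphanet association types accepted by the gene-list rules
#'
#' The seven gene–disease association types that, together with an
#' "assessed" status, retain a gene from Orphanet.
#'
#' @return Character vector of the seven association-type phrases.
#' @export
orphanet_association_types <- function() {
  c(
    "Disease-causing germline mutation(s) in",
    "Disease-causing germline mutation(s) (gain of function) in",
    "Disease-causing germline mutation(s) (loss of function) in",
    "Major susceptibility factor in",
    "Modifying germline mutation in",
    "Role in the phenotype of",
    "Candidate gene tested in"
  )
}

split_multi <- function(x) {
  purrr::map(x, function(s) {
    if (is.na(s) || !nzchar(s)) character() else stringr::str_split_1(s, "\\|")
  })
}

#' Evaluate the disease-gene inclusion criteria for evidence records
#'
#' Applies the six rules that compile a putative disease-associated gene
#' list from per-source annotation evidence. A gene is retained iff at least
#' one of criteria 1-5 fires and criterion 6 does not exclude it:
#' \enumerate{
#'   \item Orphanet status "assessed" with at least one of the seven
#'     association types in [orphanet_association_types()];
#'   \item recorded as a disease gene in Genetics Home Reference;
#'   \item recorded in OMIM with the molecular basis of the disease known,
#'     unless the inheritance is recorded as "SMu" (somatic mutation) only
#'     (the union of inheritance codes across the gene's phenotype rows);
#'   \item at least one HGMD variant recorded as probable/possible
#'     pathological;
#'   \item at least one ClinVar variant pathogenic or likely pathogenic;
#'   \item exclusion: the gene lacks a well-defined gene ID or genome
#'     coordinates in the reference annotation.
#' }
#'
#' @param records Tibble of gene evidence, one row per gene, with columns:
#'   `gene_id`, `gene_symbol`, `has_coordinates` (logical),
#'   `orphanet_status` (character or NA), `orphanet_association_types`
#'   (`|`-separated string), `ghr_disease_gene` (logical),
#'   `omim_molecular_basis_known` (logical or NA when not in OMIM),
#'   `omim_inheritances` (`|`-separated string),
#'   `hgmd_probable_possible` (logical), `clinvar_pathogenic_or_likely`
#'   (logical). Missing columns are treated as absent evidence.
#' @param association_types Accepted Orphanet association phrases
#'   (exact, case-sensitive match); unknown phrases in the data produce a
#'   warning, not an error.
#' @return The input tibble with logical columns `c1`..`c5`,
#'   `excluded_by_6`, a `fired_criteria` string (e.g. "1,5") and `retained`.
#' @export
evaluate_criteria <- function(records,
                              association_types = orphanet_association_types()) {
  records <- as_tibble(records)
  get_col <- function(nm, default) {
    if (nm %in% names(records)) records[[nm]] else rep(default, nrow(records))
  }
  assoc <- split_multi(get_col("orphanet_association_types", NA_character_))
  unknown <- setdiff(unique(unlist(assoc)), association_types)
  if (length(unknown) > 0) {
    warn(paste0("ignoring unknown Orphanet association type(s): ",
                paste(unknown, collapse = "; ")))
  }
  inh <- split_multi(get_col("omim_inheritances", NA_character_))
  status <- get_col("orphanet_status", NA_character_)
  mbk <- get_col("omim_molecular_basis_known", NA)

  c1 <- !is.na(status) & status == "assessed" &
    purrr::map_lgl(assoc, ~ any(.x %in% association_types))
  c2 <- dplyr::coalesce(get_col("ghr_disease_gene", FALSE), FALSE)
  smu_only <- purrr::map_lgl(inh, ~ length(.x) > 0 && all(.x == "SMu"))
  c3 <- !is.na(mbk) & mbk & !smu_only
  c4 <- dplyr::coalesce(get_col("hgmd_probable_possible", FALSE), FALSE)
  c5 <- dplyr::coalesce(get_col("clinvar_pathogenic_or_likely", FALSE), FALSE)
  excluded <- !dplyr::coalesce(get_col("has_coordinates", TRUE), FALSE)

  fired <- purrr::pmap_chr(list(c1, c2, c3, c4, c5), function(...) {
    paste(which(c(...)), collapse = ",")
  })
  records %>%
    mutate(
      c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5,
      excluded_by_6 = excluded,
      fired_criteria = fired,
      retained = (c1 | c2 | c3 | c4 | c5) & !excluded
    )
}

#' Compile the putative disease-associated gene list
#'
#' Evaluates the inclusion criteria and returns the retained genes sorted by
#' gene ID with their firing-criteria provenance.
#'
#' @param records Gene-evidence tibble (see [evaluate_criteria()]);
#'   duplicate `gene_id`s are an error.
#' @param association_types Passed to [evaluate_criteria()].
#' @return Tibble of retained genes: `gene_id`, `gene_symbol`,
#'   `fired_criteria`.
#' @export
compile_gene_list <- function(records,
                              association_types = orphanet_association_types()) {
  if (nrow(records) == 0) {
    return(tibble(gene_id = character(), gene_symbol = character(),
                  fired_criteria = character()))
  }
  if (anyDuplicated(records$gene_id)) abort("duplicate gene_id in records")
  evaluate_criteria(records, association_types) %>%
    filter(.data$retained) %>%
    arrange(.data$gene_id) %>%
    select("gene_id", "gene_symbol", "fired_criteria")
}

#' Read gene-evidence records from TSV
#'
#' One row per gene with the columns documented in [evaluate_criteria()];
#' logical columns accept TRUE/FALSE or 1/0.
#'
#' @param path TSV path.
#' @return Gene-evidence tibble.
#' @export
read_gene_records <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) %>%
    mutate(across(
      dplyr::any_of(c("has_coordinates", "ghr_disease_gene",
                      "omim_molecular_basis_known", "hgmd_probable_possible",
                      "clinvar_pathogenic_or_likely")),
      as.logical
    ))
}
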
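# Independent brute-force oracles the fast implementations are checked against.

# Per-base set-intersection reciprocal overlap: enumerate covered bases.
oracle_ro <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  if (chrom_a != chrom_b) return(0)
  a <- seq.int(start_a + 1, end_a)
  b <- seq.int(start_b + 1, end_b)
  ovl <- length(intersect(a, b))
  min(ovl / length(a), ovl / length(b))
}

# Exhaustive pairwise key matcher for small-variant concordance.
oracle_match <- function(truth, query, genotype_aware = TRUE) {
  tp <- 0L; fn <- 0L; gt_mismatch <- 0L
  matched_q <- rep(FALSE, nrow(query))
  for (i in seq_len(nrow(truth))) {
    hit <- which(
      query$chrom == truth$chrom[i] & query$pos == truth$pos[i] &
        query$ref == truth$ref[i] & query$alt == truth$alt[i]
    )
    if (length(hit) == 0) {
      fn <- fn + 1L
    } else if (!genotype_aware || query$zygosity[hit[1]] == truth$zygosity[i]) {
      tp <- tp + 1L
      matched_q[hit[1]] <- TRUE
    } else {
      fn <- fn + 1L
      gt_mismatch <- gt_mismatch + 1L
    }
  }
  list(tp = tp, fn = fn, fp = sum(!matched_q), gt_mismatch = gt_mismatch)
}

# Quick variant-call tibble constructor with passing quality values.
make_calls <- function(pos, zygosity = "het", ref = "A", alt = "G",
                       chrom = "chr1", GQ = 99L, DP = 50L) {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    zygosity = zygosity, vclass = classify_variant(ref, alt),
    GQ = as.integer(GQ), DP = as.integer(DP)
  )
}

# Random small truth/query fixture over few positions so keys collide often.
random_fixture <- function(n_truth, n_query, max_pos = 120) {
  draw <- function(n) {
    pos <- sample.int(max_pos, n)
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    make_calls(pos, zygosity = sample(c("het", "hom_alt"), n, replace = TRUE),
               ref = ref, alt = alt)
  }
  list(truth = draw(n_truth), query = draw(n_query))
}

# Builds one gene-evidence record wired to fire exactly the requested criteria.
record_firing <- function(id, fire = integer(), has_coordinates = TRUE,
                          smu_only = FALSE) {
  tibble::tibble(
    gene_id = id,
    gene_symbol = toupper(id),
    has_coordinates = has_coordinates,
    orphanet_status = if (1 %in% fire) "assessed" else NA_character_,
    orphanet_association_types =
      if (1 %in% fire) "Disease-causing germline mutation(s) in" else NA_character_,
    ghr_disease_gene = 2 %in% fire,
    omim_molecular_basis_known = if (3 %in% fire || smu_only) TRUE else NA,
    omim_inheritances = if (smu_only) "SMu" else if (3 %in% fire) "AD|AR" else NA_character_,
    hgmd_probable_possible = 4 %in% fire,
    clinvar_pathogenic_or_likely = 5 %in% fire
  )
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
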
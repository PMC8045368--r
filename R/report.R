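#' Run manifest for report envelopes
#'
#' Every JSON report carries a manifest: package version, subcommand,
#' resolved parameters, md5 digests of the input files, a timestamp and the
#' seed for stochastic runs. Identical parameters and inputs give an
#' identical manifest apart from the timestamp.
#'
#' @param subcommand Name of the operation being reported.
#' @param params Named list of resolved parameters.
#' @param inputs Character vector of input file paths (digested with md5).
#' @param seed Seed used, when the run is stochastic.
#' @return Named list suitable for JSON serialisation.
#' @export
run_manifest <- function(subcommand, params = list(), inputs = character(),
                         seed = NULL) {
  digests <- if (length(inputs) > 0) {
    as.list(setNames(unname(tools::md5sum(inputs)), basename(inputs)))
  } else {
    NULL
  }
  list(
    tool = "wgsbench",
    version = as.character(utils::packageVersion("wgsbench")),
    subcommand = subcommand,
    parameters = params,
    input_digests = digests,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' Write a JSON report with its manifest
#'
#' @param payload Named list or data frame (data frames become row-wise
#'   record arrays).
#' @param path Output path.
#' @param manifest Manifest from [run_manifest()].
#' @return `path`, invisibly.
#' @export
write_report_json <- function(payload, path, manifest) {
  jsonlite::write_json(
    list(manifest = manifest, results = payload),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE,
    na = "null"
  )
  invisible(path)
}

#' Simulate every stage and run the full benchmark suite
#'
#' End-to-end demonstration on synthetic data: generates a truth/query
#' variant pair, a depth profile, a CNV benchmark grid and a trio, writes
#' the standard input formats (VCF, BED, depth TSV, CNV TSV) plus a
#' gene-evidence fixture to `out_dir`, runs every benchmarking stage on the
#' written files, and writes one JSON report per stage. All randomness
#' derives from `seed`; re-running with the same seed reproduces every data
#' file byte-identically and every report payload up to the manifest
#' timestamp.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @param n_variants,n_loci,n_cnv_per_bin,depth_region_length Problem sizes.
#' @return Invisibly, a named list of the per-stage result objects.
#' @export
run_demo <- function(seed, out_dir, n_variants = 2000, n_loci = 500,
                     n_cnv_per_bin = 30, depth_region_length = 5e4) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)

  # --- small variants -------------------------------------------------------
  sv <- simulate_truth_and_calls(
    n_variants = n_variants, p_fn = 0.05, fp_rate = 0.05, gt_error = 0.01,
    seed = seed
  )
  write_vcf(sv$truth, p("truth.vcf"), sample = "TRUTH")
  write_vcf(sv$query, p("query.vcf"), sample = "QUERY")
  write_bed(sv$regions, p("confident.bed"))
  truth_in <- read_vcf_calls(p("truth.vcf"))
  query_in <- read_vcf_calls(p("query.vcf"))
  regions_in <- read_bed(p("confident.bed"))
  small <- bench_small_variants(truth_in, query_in, regions_in)
  write_report_json(
    small, p("bench_small.json"),
    run_manifest("bench-small",
                 params = list(min_gq = 20, min_dp = 10, genotype_aware = TRUE),
                 inputs = c(p("truth.vcf"), p("query.vcf"), p("confident.bed")),
                 seed = seed)
  )

  # --- depth / coverage -----------------------------------------------------
  dp <- simulate_depth_profile(region_length = depth_region_length,
                               mean = 40, dispersion = 10, dropout = 0.1,
                               seed = seed + 1)
  write_depth_table(dp$profile, p("depth.tsv"))
  write_bed(dp$profile$declared_regions, p("depth_regions.bed"))
  profile_in <- read_depth_table(p("depth.tsv"), read_bed(p("depth_regions.bed")))
  # carve a few labelled gene regions out of the contig
  genes <- intervals(
    rep("chr1", 6),
    seq(0, by = depth_region_length %/% 6, length.out = 6),
    seq(0, by = depth_region_length %/% 6, length.out = 6) + 2000,
    label = paste0("GENE", 1:6)
  )
  genes$gene <- genes$label
  cov <- gene_coverage(profile_in, genes, threshold = 10)
  write_report_json(
    list(per_gene = cov$per_gene, summary = cov$summary),
    p("coverage.json"),
    run_manifest("coverage", params = list(threshold = 10),
                 inputs = p("depth.tsv"), seed = seed + 1)
  )

  # --- CNV + MDI ------------------------------------------------------------
  cnv <- simulate_cnv_benchmark(n_per_bin = n_cnv_per_bin, seed = seed + 2)
  write_cnv_calls(cnv$truth, p("cnv_truth.tsv"))
  write_cnv_calls(cnv$calls, p("cnv_calls.tsv"))
  grid <- tidyr::expand_grid(tool = cnv$params$tools,
                             depth_label = cnv$params$depths,
                             callset = cnv$params$callsets)
  cells <- purrr::pmap(
    grid,
    function(tool, depth_label, callset) {
      sensitivity_by_size(
        truth = cnv$truth[cnv$truth$source == callset, ],
        calls = cnv$calls[cnv$calls$tool == tool &
                            cnv$calls$depth_label == depth_label &
                            cnv$calls$callset == callset, ],
        bins = cnv$bins, depth_label = depth_label, tool = tool,
        callset = callset
      )
    }
  ) %>% bind_rows()
  mdi <- compute_mdi(qualified_size_bins(cells, min_truth = 10))
  write_report_json(
    list(cells = cells, mdi = as_tibble(mdi)),
    p("cnv_mdi.json"),
    run_manifest("bench-cnv",
                 params = list(ro = 0.5, min_truth = 10),
                 inputs = c(p("cnv_truth.tsv"), p("cnv_calls.tsv")),
                 seed = seed + 2)
  )

  # --- trio -----------------------------------------------------------------
  trio <- simulate_trio(n_loci = n_loci, r = 0.97, e = 0.02, seed = seed + 3)
  write_vcf(trio$father, p("father.vcf"), sample = "FATHER")
  write_vcf(trio$mother, p("mother.vcf"), sample = "MOTHER")
  write_vcf(trio$offspring, p("offspring.vcf"), sample = "OFFSPRING")
  loci <- select_informative_loci(
    read_vcf_calls(p("father.vcf")), read_vcf_calls(p("mother.vcf")),
    regions = trio$regions
  )
  trio_eval <- evaluate_offspring(loci, read_vcf_calls(p("offspring.vcf")))
  write_report_json(
    as_tibble(trio_eval), p("trio.json"),
    run_manifest("trio", params = list(min_dp = 10, min_gq = 20),
                 inputs = c(p("father.vcf"), p("mother.vcf"), p("offspring.vcf")),
                 seed = seed + 3)
  )

  # --- gene list ------------------------------------------------------------
  records <- demo_gene_records()
  readr::write_tsv(records, p("gene_records.tsv"))
  gene_list <- compile_gene_list(read_gene_records(p("gene_records.tsv")))
  write_report_json(
    gene_list, p("gene_list.json"),
    run_manifest("compile-geneset", inputs = p("gene_records.tsv"))
  )

  invisible(list(
    small = small, coverage = cov, cells = cells, mdi = mdi,
    trio = trio_eval, gene_list = gene_list,
    simulated = list(small = sv, depth = dp, cnv = cnv, trio = trio)
  ))
}

# Small deterministic gene-evidence fixture exercising each rule once.
demo_gene_records <- function() {
  tibble(
    gene_id = paste0("G", 1:7),
    gene_symbol = paste0("GENE", 1:7),
    has_coordinates = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    orphanet_status = c("assessed", NA, NA, NA, NA, "assessed", "not assessed"),
    orphanet_association_types =
      c("Disease-causing germline mutation(s) in", NA, NA, NA, NA,
        "Role in the phenotype of", "Role in the phenotype of"),
    ghr_disease_gene = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    omim_molecular_basis_known = c(NA, NA, TRUE, NA, NA, NA, NA),
    omim_inheritances = c(NA, NA, "AR|AD", NA, NA, NA, NA),
    hgmd_probable_possible = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    clinvar_pathogenic_or_likely = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  )
}
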
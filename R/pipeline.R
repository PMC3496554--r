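#' Run the full genotyping pipeline on a read library
#'
#' Chains preprocessing (demultiplexing by unordered tag pairs, perfect
#' primer filtering, dereplication, copy and coverage filters, trimming to
#' the common region), MPAF-based allele validation and TMCA genotype
#' calling.
#'
#' @param reads Tibble `read_id`, `sequence`, or a `sim_reads` object.
#' @param tag_scheme Tag scheme (taken from a `sim_reads` object when
#'   omitted).
#' @param locus_configs Locus panel (likewise).
#' @param min_copies,min_reads,mpaf_threshold Stage thresholds.
#' @return An `mhc_pipeline` list: `variants`, `catalog`, `genotypes`,
#'   `summary` (per-stage filter table), `correlation` (MPAF vs carrier
#'   diagnostic), `demux`.
#' @export
genotype_pipeline <- function(reads, tag_scheme = NULL, locus_configs = NULL,
                              min_copies = 5L, min_reads = 18L,
                              mpaf_threshold = 0.05) {
  if (inherits(reads, "sim_reads")) {
    tag_scheme <- tag_scheme %||% reads$scheme
    locus_configs <- locus_configs %||% reads$configs
    reads <- reads$reads
  }
  if (is.null(tag_scheme)) abort("tag_scheme is required")
  locus_configs <- locus_configs %||% default_locus_configs()
  pp <- preprocess_reads(reads, tag_scheme, locus_configs,
                         min_copies = min_copies, min_reads = min_reads)
  catalog <- validate_alleles(pp$variants, mpaf_threshold = mpaf_threshold)
  genotypes <- call_genotypes(pp$variants, catalog,
                              mpaf_threshold = mpaf_threshold)
  structure(list(
    variants = pp$variants, catalog = catalog, genotypes = genotypes,
    summary = pp$summary, correlation = mpaf_carrier_correlation(catalog),
    demux = pp$demux
  ), class = "mhc_pipeline")
}

#' @export
print.mhc_pipeline <- function(x, ...) {
  cat("<mhc_pipeline>\n")
  print(x$summary)
  cat("\nValidated alleles per locus:\n")
  print(count(filter(x$catalog, .data$status == "validated"), .data$locus))
  cat("\nGenotypes called:", nrow(x$genotypes), "\n")
  invisible(x)
}
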
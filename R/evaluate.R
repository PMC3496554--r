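#' Evaluate pipeline output against simulation truth
#'
#' Compares called genotypes (as sequences, via the validated catalog) with
#' the simulated true genotypes (trimmed to the common region), and the
#' validated catalog with the true allele pool restricted to alleles
#' actually present in the simulated individuals.
#'
#' @param pipeline An `mhc_pipeline` object from [genotype_pipeline()].
#' @param truth The `sim_truth` the reads were simulated from.
#' @return List with `genotypes` (per individual and locus: called vs true,
#'   `correct`), `accuracy` (per locus: called, correct, accuracy, and the
#'   call rate over simulated individuals), and `catalog_check` (per locus:
#'   validated alleles, true among them, false positives, true alleles with
#'   at least two carriers that were missed).
#' @export
evaluate_against_truth <- function(pipeline, truth) {
  stopifnot(inherits(pipeline, "mhc_pipeline"), inherits(truth, "sim_truth"))
  pools <- truth$pools
  tg <- true_genotypes(truth) |>
    left_join(select(pools, "allele_id", true_seq1 = "core"),
              by = c(allele1 = "allele_id")) |>
    left_join(select(pools, "allele_id", true_seq2 = "core"),
              by = c(allele2 = "allele_id")) |>
    mutate(true_a = pmin(.data$true_seq1, .data$true_seq2),
           true_b = pmax(.data$true_seq1, .data$true_seq2)) |>
    select("individual_id", "locus", "true_a", "true_b")

  seq_of <- setNames(pipeline$catalog$sequence, pipeline$catalog$allele_id)
  called <- consensus_genotypes(pipeline$genotypes) |>
    mutate(seq1 = unname(seq_of[.data$allele1]),
           seq2 = unname(seq_of[.data$allele2]),
           called_a = pmin(.data$seq1, .data$seq2),
           called_b = pmax(.data$seq1, .data$seq2)) |>
    select("individual_id", "locus", "called_a", "called_b")

  cmp <- tg |>
    left_join(called, by = c("individual_id", "locus")) |>
    mutate(called = !is.na(.data$called_a),
           correct = .data$called & .data$called_a == .data$true_a &
             .data$called_b == .data$true_b)
  accuracy <- cmp |>
    group_by(.data$locus) |>
    summarise(n_simulated = n(), n_called = sum(.data$called),
              n_correct = sum(.data$correct),
              accuracy = sum(.data$correct) / sum(.data$called),
              call_rate = mean(.data$called), .groups = "drop")

  ## catalog check: which validated sequences are real pool alleles, and
  ## which true alleles carried by >= 2 individuals were recovered; carriers
  ## are counted among individuals whose amplicon survived preprocessing (an
  ## allele whose carriers were all discarded cannot be observed)
  surviving <- pipeline$variants |>
    distinct(.data$locus, .data$individual_id)
  carried <- true_genotypes(truth) |>
    inner_join(surviving, by = c("locus", "individual_id")) |>
    tidyr::pivot_longer(c("allele1", "allele2"), values_to = "allele_id") |>
    group_by(.data$locus, .data$allele_id) |>
    summarise(n_carriers = n_distinct(.data$individual_id), .groups = "drop") |>
    left_join(select(pools, "allele_id", "core"), by = "allele_id")
  catalog_check <- purrr::map(unique(pools$locus), function(loc) {
    val <- pipeline$catalog |>
      filter(.data$locus == loc, .data$status == "validated")
    car <- carried |> filter(.data$locus == loc)
    multi <- car |> filter(.data$n_carriers >= 2L)
    tibble(
      locus = loc,
      n_validated = nrow(val),
      n_true_validated = sum(val$sequence %in% car$core),
      n_false_validated = sum(!val$sequence %in% car$core),
      n_true_multi_carrier = nrow(multi),
      n_multi_carrier_missed = sum(!multi$core %in% val$sequence)
    )
  }) |> list_rbind()

  list(genotypes = cmp, accuracy = accuracy, catalog_check = catalog_check)
}

#' Inject genotyping errors into a genotype table
#'
#' With probability `rate` per genotype, one of the two alleles (chosen at
#' random) is replaced by a different allele drawn from the locus's observed
#' alleles; used to study how genotyping error propagates into pedigree
#' mismatch rates.
#'
#' @param genotypes Genotype tibble (`individual_id`, `locus`, `allele1`,
#'   `allele2`).
#' @param rate Per-genotype error probability.
#' @param seed Integer seed.
#' @return Genotype tibble with an added logical column `error_injected`.
#' @export
inject_genotype_errors <- function(genotypes, rate, seed = NULL) {
  with_seed_if(seed, {
    g <- genotypes
    g$error_injected <- runif(nrow(g)) < rate
    for (i in which(g$error_injected)) {
      pool <- unique(c(g$allele1[g$locus == g$locus[i]],
                       g$allele2[g$locus == g$locus[i]]))
      slot <- sample(c("allele1", "allele2"), 1)
      old <- g[[slot]][i]
      repl <- sample(setdiff(pool, old), 1)
      g[[slot]][i] <- repl
      a <- pmin(g$allele1[i], g$allele2[i])
      b <- pmax(g$allele1[i], g$allele2[i])
      g$allele1[i] <- a
      g$allele2[i] <- b
    }
    g
  })
}
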
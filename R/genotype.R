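#' Call genotypes as the two most common validated alleles (TMCA)
#'
#' Within each amplicon, validated alleles are ranked by copy count; the
#' genotype is the two most common.  A single validated allele gives a
#' homozygote, as does a second-ranked allele whose within-amplicon
#' frequency falls below the MPAF threshold (such a trace allele is more
#' plausibly a cross-amplicon contaminant than a real second allele).  More
#' than two validated alleles above the threshold raise the `excess_alleles`
#' flag while the call remains the TMCA.  Ties at rank 2 are broken
#' deterministically (higher within-amplicon frequency, then lexicographic
#' sequence) and flagged.
#'
#' @param variants Variant tibble from the preprocessing cascade.
#' @param catalog Catalog from [validate_alleles()].
#' @param mpaf_threshold Within-amplicon frequency below which a second
#'   allele is not believed; same default as validation.
#' @return Genotype tibble: `amplicon_id`, `sample_id`, `individual_id`,
#'   `locus`, `allele1`, `allele2` (allele ids, unordered so sorted),
#'   `count1`, `count2`, `freq1`, `freq2`, `homozygote`, `tie_broken`,
#'   `excess_alleles`.  Amplicons with zero validated alleles are logged in
#'   the `"log"` attribute.
#' @export
call_genotypes <- function(variants, catalog, mpaf_threshold = 0.05) {
  validated <- catalog |>
    filter(.data$status == "validated") |>
    select("locus", "sequence", "allele_id")
  vv <- variants |>
    inner_join(validated, by = c("locus", "sequence")) |>
    mutate(freq = .data$copy_count / .data$total_reads)
  no_call <- variants |>
    distinct(.data$amplicon_id, .data$sample_id, .data$individual_id,
             .data$locus) |>
    anti_join(distinct(vv, .data$amplicon_id), by = "amplicon_id")

  calls <- vv |>
    arrange(.data$amplicon_id, desc(.data$copy_count), .data$sequence) |>
    group_by(.data$amplicon_id, .data$sample_id, .data$individual_id,
             .data$locus) |>
    summarise(
      n_validated = n(),
      n_above = sum(.data$freq >= mpaf_threshold),
      a1 = .data$allele_id[1],
      a2 = if (n() >= 2L) .data$allele_id[2] else .data$allele_id[1],
      count1 = .data$copy_count[1],
      count2 = if (n() >= 2L) .data$copy_count[2] else .data$copy_count[1],
      freq1 = .data$freq[1],
      freq2 = if (n() >= 2L) .data$freq[2] else .data$freq[1],
      tie_broken = n() >= 3L && .data$copy_count[2] == .data$copy_count[3],
      .groups = "drop"
    ) |>
    mutate(
      homozygote = .data$n_validated == 1L | .data$freq2 < mpaf_threshold,
      a2 = ifelse(.data$homozygote, .data$a1, .data$a2),
      count2 = ifelse(.data$homozygote, .data$count1, .data$count2),
      freq2 = ifelse(.data$homozygote, .data$freq1, .data$freq2),
      excess_alleles = .data$n_above > 2L,
      allele1 = pmin(.data$a1, .data$a2),
      allele2 = pmax(.data$a1, .data$a2)
    ) |>
    select("amplicon_id", "sample_id", "individual_id", "locus",
           "allele1", "allele2", "count1", "count2", "freq1", "freq2",
           "homozygote", "tie_broken", "excess_alleles")
  attr(calls, "log") <- list(no_genotype = no_call)
  calls
}

#' Concordance of genotypes across replicate amplicons
#'
#' Individuals amplified more than once at a locus are checked for identical
#' calls.  The consensus rule assumes allelic dropout: a heterozygote call
#' overrides a homozygote call; two different heterozygote calls cannot be
#' reconciled and are left unresolved.
#'
#' @param genotypes Genotype tibble from [call_genotypes()].
#' @return List with `replicates` (per individual and locus: calls,
#'   concordance, consensus) and `summary` (per locus repeatability rate
#'   over replicated individuals).
#' @export
replicate_concordance <- function(genotypes) {
  reps <- genotypes |>
    group_by(.data$individual_id, .data$locus) |>
    filter(n() >= 2L) |>
    dplyr::group_modify(function(df, key) {
      gg <- distinct(df, .data$allele1, .data$allele2)
      het <- gg[gg$allele1 != gg$allele2, ]
      if (nrow(gg) == 1L) {
        cons <- c(gg$allele1, gg$allele2, TRUE)
      } else if (nrow(het) == 1L) {
        cons <- c(het$allele1, het$allele2, TRUE)
      } else {
        cons <- c(NA_character_, NA_character_, FALSE)
      }
      tibble(
        n_replicates = nrow(df),
        calls = paste(unique(paste(df$allele1, df$allele2, sep = "/")),
                      collapse = "; "),
        concordant = nrow(gg) == 1L,
        consensus1 = cons[1], consensus2 = cons[2],
        resolved = as.logical(cons[3])
      )
    }) |>
    ungroup()
  summary <- reps |>
    group_by(.data$locus) |>
    summarise(n_replicated = n(),
              n_concordant = sum(.data$concordant),
              repeatability = mean(.data$concordant),
              .groups = "drop")
  list(replicates = reps, summary = summary)
}

## One genotype row per individual x locus: consensus across replicates
## (heterozygote overrides homozygote), unresolved conflicts dropped.
consensus_genotypes <- function(genotypes) {
  singles <- genotypes |>
    group_by(.data$individual_id, .data$locus) |>
    filter(n() == 1L) |>
    ungroup() |>
    select("individual_id", "locus", "allele1", "allele2")
  multi <- genotypes |>
    group_by(.data$individual_id, .data$locus) |>
    filter(n() >= 2L) |>
    ungroup()
  if (nrow(multi) > 0L) {
    cons <- replicate_concordance(multi)$replicates |>
      filter(.data$resolved) |>
      select("individual_id", "locus",
             allele1 = "consensus1", allele2 = "consensus2")
    singles <- bind_rows(singles, cons)
  }
  singles
}

#' Mendelian consistency of genotypes against a pedigree
#'
#' A parent-offspring dyad is consistent when the two share at least one
#' allele; a triad is consistent when the offspring's two alleles can be
#' assigned one to each parent.  Dyads with a missing genotype are skipped
#' and counted as untested.  Mismatches co-occurring at both loci of one
#' offspring are tallied separately: they are the signature of a parentage
#' error rather than a genotyping error.
#'
#' @param genotypes Genotype tibble ([call_genotypes()] output or any tibble
#'   with `individual_id`, `locus`, `allele1`, `allele2`); replicates are
#'   resolved to a consensus first.
#' @param pedigree Tibble with `offspring_id`, `mother_id`, `father_id`
#'   (parents may be `NA`).
#' @return List with `dyads` (per offspring, parent role and locus:
#'   consistency), `triads`, `summary` (per locus: tested, mismatches,
#'   mismatch rate for dyads and triads) and `co_occurrence` (offspring
#'   mismatching at one locus vs both).
#' @export
pedigree_consistency <- function(genotypes, pedigree) {
  g <- consensus_genotypes(genotypes)
  lookup <- function(id, locus) {
    hit <- g[g$individual_id == id & g$locus == locus, ]
    if (nrow(hit) == 0L) NULL else c(hit$allele1[1], hit$allele2[1])
  }
  loci <- unique(g$locus)
  dyads <- list()
  triads <- list()
  for (i in seq_len(nrow(pedigree))) {
    off <- pedigree$offspring_id[i]
    for (locus in loci) {
      og <- lookup(off, locus)
      if (is.null(og)) next
      pg <- list(mother = NULL, father = NULL)
      for (role in c("mother", "father")) {
        pid <- pedigree[[paste0(role, "_id")]][i]
        if (is.na(pid)) next
        pgeno <- lookup(pid, locus)
        if (is.null(pgeno)) next
        pg[[role]] <- pgeno
        dyads[[length(dyads) + 1L]] <- tibble(
          offspring_id = off, parent_id = pid, role = role, locus = locus,
          consistent = any(og %in% pgeno)
        )
      }
      if (!is.null(pg$mother) && !is.null(pg$father)) {
        ok <- (og[1] %in% pg$mother && og[2] %in% pg$father) ||
          (og[2] %in% pg$mother && og[1] %in% pg$father)
        triads[[length(triads) + 1L]] <- tibble(
          offspring_id = off, locus = locus, consistent = ok
        )
      }
    }
  }
  dyads <- if (length(dyads)) list_rbind(dyads) else
    tibble(offspring_id = character(0), parent_id = character(0),
           role = character(0), locus = character(0), consistent = logical(0))
  triads <- if (length(triads)) list_rbind(triads) else
    tibble(offspring_id = character(0), locus = character(0),
           consistent = logical(0))
  summary <- dyads |>
    group_by(.data$locus) |>
    summarise(unit = "dyad", n_tested = n(),
              n_mismatch = sum(!.data$consistent),
              mismatch_rate = mean(!.data$consistent), .groups = "drop") |>
    bind_rows(
      triads |>
        group_by(.data$locus) |>
        summarise(unit = "triad", n_tested = n(),
                  n_mismatch = sum(!.data$consistent),
                  mismatch_rate = mean(!.data$consistent), .groups = "drop")
    )
  mm <- dyads |>
    group_by(.data$offspring_id) |>
    summarise(loci_mismatched = n_distinct(.data$locus[!.data$consistent]),
              .groups = "drop") |>
    filter(.data$loci_mismatched > 0L)
  co <- tibble(
    n_offspring_mismatched = nrow(mm),
    n_mismatched_both_loci = sum(mm$loci_mismatched >= 2L)
  )
  list(dyads = dyads, triads = triads, summary = summary, co_occurrence = co)
}

#' Report amplicons carrying more than two validated alleles
#'
#' For every amplicon flagged `excess_alleles`, lists the validated alleles
#' beyond the called TMCA pair together with their within-amplicon
#' frequencies, whether each extra allele is part of the called genotype of
#' another amplicon (the cross-amplicon contamination signature), and, when
#' a pedigree is supplied, whether it is shared with a genotyped relative.
#'
#' @param variants Variant tibble.
#' @param catalog Catalog from [validate_alleles()].
#' @param genotypes Genotype tibble from [call_genotypes()].
#' @param pedigree Optional pedigree tibble.
#' @param mpaf_threshold Frequency above which an extra allele counts.
#' @return Tibble: `amplicon_id`, `individual_id`, `locus`, `allele_id`,
#'   `freq`, `in_other_genotype`, `shared_with_relative`.
#' @export
multi_allele_report <- function(variants, catalog, genotypes, pedigree = NULL,
                                mpaf_threshold = 0.05) {
  validated <- catalog |>
    filter(.data$status == "validated") |>
    select("locus", "sequence", "allele_id")
  vv <- variants |>
    inner_join(validated, by = c("locus", "sequence")) |>
    mutate(freq = .data$copy_count / .data$total_reads)
  called <- genotypes |>
    select("amplicon_id", "allele1", "allele2")
  extra <- vv |>
    inner_join(called, by = "amplicon_id") |>
    filter(.data$allele_id != .data$allele1,
           .data$allele_id != .data$allele2,
           .data$freq >= mpaf_threshold) |>
    select("amplicon_id", "individual_id", "locus", "allele_id", "freq")
  if (nrow(extra) == 0L) {
    return(mutate(extra, in_other_genotype = logical(0),
                  shared_with_relative = logical(0)))
  }
  extra$in_other_genotype <- purrr::map2_lgl(
    extra$allele_id, extra$amplicon_id,
    function(a, amp) {
      any((genotypes$allele1 == a | genotypes$allele2 == a) &
            genotypes$amplicon_id != amp)
    })
  if (is.null(pedigree)) {
    extra$shared_with_relative <- NA
  } else {
    rel <- function(id) {
      rows <- pedigree$offspring_id == id
      kin <- c(pedigree$mother_id[rows], pedigree$father_id[rows],
               pedigree$offspring_id[pedigree$mother_id %in% id |
                                       pedigree$father_id %in% id])
      kin[!is.na(kin)]
    }
    extra$shared_with_relative <- purrr::pmap_lgl(
      list(extra$allele_id, extra$individual_id, extra$locus),
      function(a, id, locus) {
        kin <- rel(id)
        any(genotypes$individual_id %in% kin & genotypes$locus == locus &
              (genotypes$allele1 == a | genotypes$allele2 == a))
      })
  }
  extra
}
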
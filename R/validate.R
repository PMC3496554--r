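#' Mean per-amplicon frequency (MPAF) of each variant
#'
#' For every unique sequence at a locus, the within-amplicon frequency is its
#' copy count divided by the amplicon's surviving read total; MPAF is the
#' mean of these frequencies over the amplicons that carry the variant
#' (amplicons lacking it contribute nothing).  Artefacts arising from
#' sequencing or PCR errors recur at low within-amplicon frequency and so
#' display low MPAF, which makes this the pivotal sorting statistic.
#'
#' @param variants Variant tibble from the preprocessing cascade.
#' @return Catalog tibble: `locus`, `allele_id`, `sequence`, `mpaf`,
#'   `carrier_count`, ordered by locus and decreasing MPAF.
#' @export
compute_mpaf <- function(variants) {
  variants |>
    filter(.data$total_reads > 0L) |>
    mutate(freq = .data$copy_count / .data$total_reads) |>
    group_by(.data$locus, .data$sequence) |>
    summarise(mpaf = mean(.data$freq),
              carrier_count = n_distinct(.data$amplicon_id),
              .groups = "drop") |>
    arrange(.data$locus, desc(.data$mpaf), .data$sequence) |>
    group_by(.data$locus) |>
    mutate(allele_id = sprintf("%s_v%04d", .data$locus, row_number())) |>
    ungroup() |>
    select("locus", "allele_id", "sequence", "mpaf", "carrier_count")
}

#' Classify a variant against the more-common variants of its amplicon
#'
#' A variant is a `point_mutant` if it lies at edit distance 1 (one
#' substitution or one indel) from any parental sequence, and a `chimera` if
#' it equals `prefix(A) + suffix(B)` for some crossover position and ordered
#' pair of distinct parentals without itself being parental.  When both
#' explanations hold the single-event explanation wins (`point_mutant`).
#' With an empty parental set the variant is `unexplained`.
#'
#' @param sequence The variant sequence.
#' @param parents Character vector of parental sequences (the variants of
#'   strictly higher copy count in the same amplicon).
#' @return One of `"point_mutant"`, `"chimera"`, `"unexplained"`.
#' @export
classify_variant <- function(sequence, parents) {
  parents <- setdiff(unique(parents), sequence)
  if (length(parents) == 0L) return("unexplained")
  if (any(utils::adist(sequence, parents) == 1L)) return("point_mutant")
  if (length(parents) >= 2L) {
    for (a in parents) {
      for (b in setdiff(parents, a)) {
        if (sequence %in% crossover_products(a, b)) return("chimera")
      }
    }
  }
  "unexplained"
}

## Classify every variant of every amplicon against its more-common
## co-occurring variants. Returns per (amplicon, sequence) classification.
classify_amplicon_variants <- function(variants) {
  variants |>
    group_by(.data$amplicon_id) |>
    dplyr::group_modify(function(df, key) {
      df$artefact_class <- vapply(seq_len(nrow(df)), function(i) {
        classify_variant(df$sequence[i],
                         df$sequence[df$copy_count > df$copy_count[i]])
      }, character(1))
      df
    }) |>
    ungroup()
}

#' Validate alleles by MPAF threshold and artefact screening
#'
#' The stepwise sorting of true from artefactual alleles: variants with MPAF
#' below `mpaf_threshold` are eliminated outright (`low_mpaf`); each
#' remaining variant is screened within every amplicon that carries it
#' against the variants of strictly higher copy count there, and is
#' eliminated when it is explained as a chimera or point mutant in all of
#' its carrier amplicons.  Variants carried by a single amplicon survive
#' when they exceed the threshold and resist the artefact screen, but are
#' flagged `single_carrier`.
#'
#' @param variants Variant tibble from the preprocessing cascade.
#' @param mpaf_threshold Elimination threshold in (0, 1); default 0.05
#'   ("MPAF below 5 percent"); the boundary is strict, MPAF equal to the
#'   threshold is retained.
#' @param iterative If `TRUE`, MPAF is recomputed over surviving variants
#'   after each elimination round until stable (sensitivity analysis); the
#'   default single pass mirrors the published procedure.
#' @return Catalog tibble: `locus`, `allele_id`, `sequence`, `mpaf`,
#'   `carrier_count`, `status` (validated/eliminated), `artefact_class`
#'   (none/low_mpaf/point_mutant/chimera), `single_carrier`.
#' @export
validate_alleles <- function(variants, mpaf_threshold = 0.05,
                             iterative = FALSE) {
  if (mpaf_threshold <= 0 || mpaf_threshold >= 1) {
    abort("mpaf_threshold must lie in (0, 1)")
  }
  surviving <- variants
  repeat {
    catalog <- compute_mpaf(surviving)
    cls <- classify_amplicon_variants(surviving)
    explained <- cls |>
      group_by(.data$locus, .data$sequence) |>
      summarise(
        n_amp = n(),
        n_explained = sum(.data$artefact_class != "unexplained"),
        screen_class = if (any(.data$artefact_class == "point_mutant")) {
          "point_mutant"
        } else if (any(.data$artefact_class == "chimera")) "chimera" else
          "unexplained",
        .groups = "drop"
      )
    catalog <- catalog |>
      left_join(explained, by = c("locus", "sequence")) |>
      mutate(
        low = .data$mpaf < mpaf_threshold,
        artefactual = !.data$low & .data$n_explained == .data$n_amp &
          .data$screen_class != "unexplained",
        status = ifelse(.data$low | .data$artefactual, "eliminated", "validated"),
        artefact_class = dplyr::case_when(
          low ~ "low_mpaf",
          artefactual ~ screen_class,
          TRUE ~ "none"
        ),
        single_carrier = .data$status == "validated" & .data$carrier_count == 1L
      ) |>
      select("locus", "allele_id", "sequence", "mpaf", "carrier_count",
             "status", "artefact_class", "single_carrier")
    if (!iterative) break
    keep <- catalog |> filter(.data$status == "validated")
    nxt <- surviving |>
      inner_join(select(keep, "locus", "sequence"), by = c("locus", "sequence")) |>
      group_by(.data$amplicon_id) |>
      mutate(total_reads = sum(.data$copy_count)) |>
      ungroup()
    if (nrow(nxt) == nrow(surviving)) break
    surviving <- nxt
  }
  catalog |> arrange(.data$locus, .data$status, desc(.data$mpaf))
}

#' MPAF versus carrier-count correlation diagnostic
#'
#' A genotyping mistake that produces the same artefactual sequence rarely
#' recurs independently in many amplicons, so before sorting, MPAF and the
#' number of carrier amplicons are positively correlated (both low for
#' artefacts); an efficient sorting procedure removes that correlation among
#' the validated alleles.  Pearson's correlation with a two-sided p-value is
#' reported for the full catalog and for the validated subset.
#'
#' @param catalog Catalog tibble from [validate_alleles()] (or
#'   [compute_mpaf()], in which case only the `before` state is computed).
#' @return Tibble with one row per state (`before`, `after`): `n`, `r`,
#'   `p`, `note` (`"degenerate"` when either variable has zero variance).
#' @export
mpaf_carrier_correlation <- function(catalog) {
  one <- function(df, state) {
    if (nrow(df) < 3L || sd(df$mpaf) == 0 || sd(df$carrier_count) == 0) {
      return(tibble(state = state, n = nrow(df), r = NA_real_, p = NA_real_,
                    note = "degenerate"))
    }
    ct <- cor.test(df$mpaf, df$carrier_count, method = "pearson")
    tibble(state = state, n = nrow(df), r = unname(ct$estimate),
           p = ct$p.value, note = NA_character_)
  }
  out <- one(catalog, "before")
  if ("status" %in% names(catalog)) {
    out <- bind_rows(out, one(filter(catalog, .data$status == "validated"),
                              "after"))
  }
  out
}
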
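#' Demultiplex tagged amplicon reads and trim tags and primers
#'
#' Implements the strict extraction step of the pipeline: a read is kept only
#' if, in one of its two orientations, both 10-bp tags are fully present and
#' both template-specific primers match with zero mismatches.  The locus is
#' assigned by the primer pair; reads whose forward and reverse primers
#' belong to different loci are rejected as cross-locus chimeras; reads whose
#' unordered tag pair is not in the scheme are rejected, not errored.
#' Reverse-orientation reads are reverse-complemented before assignment, so
#' demultiplexing is orientation-invariant.
#'
#' @param reads Tibble with `read_id`, `sequence` (e.g. from [read_fasta()]
#'   or [simulate_reads()]).
#' @param tag_scheme Tibble from [make_tag_scheme()] (columns `sample_id`,
#'   `individual_id`, `tag_fwd`, `tag_rev`).
#' @param locus_configs Tibble from [default_locus_configs()].
#' @return A `demux` list: `assigned` (tibble `read_id`, `amplicon_id`,
#'   `sample_id`, `individual_id`, `locus`, `sequence` = trimmed template)
#'   and `rejected` (tibble `read_id`, `reason` in
#'   primer_mismatch/cross_locus_chimera/unknown_tag_pair).
#' @export
demultiplex_reads <- function(reads, tag_scheme, locus_configs = default_locus_configs()) {
  if (!all(c("read_id", "sequence") %in% names(reads))) {
    abort("reads must have columns read_id and sequence")
  }
  if (anyDuplicated(tag_pair_key(tag_scheme$tag_fwd, tag_scheme$tag_rev))) {
    abort("duplicate unordered tag pair assigned to two samples")
  }
  K <- nchar(tag_scheme$tag_fwd[1])
  n <- nrow(reads)
  loci <- locus_configs$locus
  pf <- setNames(locus_configs$primer_fwd, loci)
  pr_rc <- setNames(revcomp(locus_configs$primer_rev), loci)

  parse_strand <- function(s) {
    L <- nchar(s)
    lf <- rep(NA_character_, length(s))
    lr <- rep(NA_character_, length(s))
    for (loc in loci) {
      hit_f <- substr(s, K + 1L, K + nchar(pf[[loc]])) == pf[[loc]]
      lf[hit_f] <- loc
      nr <- nchar(pr_rc[[loc]])
      hit_r <- substring(s, L - K - nr + 1L, L - K) == pr_rc[[loc]]
      lr[hit_r] <- loc
    }
    tag_f <- substr(s, 1L, K)
    tag_r <- revcomp(substring(s, L - K + 1L, L))
    nf <- ifelse(is.na(lf), 0L, nchar(pf[lf]))
    nr <- ifelse(is.na(lr), 0L, nchar(pr_rc[lr]))
    template <- substring(s, K + nf + 1L, L - K - nr)
    list(lf = lf, lr = lr, tag_f = tag_f, tag_r = tag_r, template = template)
  }

  fwd <- parse_strand(reads$sequence)
  rev <- parse_strand(revcomp(reads$sequence))
  use_rev <- is.na(fwd$lf) & !is.na(rev$lf)
  pick <- function(a, b) ifelse(use_rev, b, a)
  lf <- pick(fwd$lf, rev$lf)
  lr <- pick(fwd$lr, rev$lr)
  tag_f <- pick(fwd$tag_f, rev$tag_f)
  tag_r <- pick(fwd$tag_r, rev$tag_r)
  template <- pick(fwd$template, rev$template)

  key <- tag_pair_key(tag_f, tag_r)
  scheme_key <- setNames(tag_scheme$sample_id,
                         tag_pair_key(tag_scheme$tag_fwd, tag_scheme$tag_rev))
  sample_id <- unname(scheme_key[key])

  reason <- rep(NA_character_, n)
  reason[is.na(lf) | is.na(lr)] <- "primer_mismatch"
  cross <- !is.na(lf) & !is.na(lr) & lf != lr
  reason[cross] <- "cross_locus_chimera"
  no_tag <- is.na(reason) & is.na(sample_id)
  reason[no_tag] <- "unknown_tag_pair"

  keep <- is.na(reason)
  ind <- setNames(tag_scheme$individual_id, tag_scheme$sample_id)
  assigned <- tibble(
    read_id = reads$read_id[keep],
    amplicon_id = paste(sample_id[keep], lf[keep], sep = ":"),
    sample_id = sample_id[keep],
    individual_id = unname(ind[sample_id[keep]]),
    locus = lf[keep],
    sequence = template[keep]
  )
  structure(list(
    assigned = assigned,
    rejected = tibble(read_id = reads$read_id[!keep], reason = reason[!keep])
  ), class = "demux")
}

#' @export
print.demux <- function(x, ...) {
  cat("<demux> ", nrow(x$assigned), " reads assigned to ",
      n_distinct(x$assigned$amplicon_id), " amplicons; ",
      nrow(x$rejected), " rejected\n", sep = "")
  if (nrow(x$rejected) > 0) print(count(x$rejected, .data$reason))
  invisible(x)
}

#' Dereplicate reads within amplicons
#'
#' Merges perfectly identical reads (no mismatches tolerated) within each
#' amplicon into variant records with copy counts.
#'
#' @param x A `demux` object or a tibble of assigned reads.
#' @return Variant tibble: `amplicon_id`, `sample_id`, `individual_id`,
#'   `locus`, `sequence`, `copy_count`, `total_reads` (reads in the amplicon
#'   at dereplication time).
#' @export
dereplicate_reads <- function(x) {
  assigned <- if (inherits(x, "demux")) x$assigned else x
  assigned |>
    count(.data$amplicon_id, .data$sample_id, .data$individual_id,
          .data$locus, .data$sequence, name = "copy_count") |>
    group_by(.data$amplicon_id) |>
    mutate(total_reads = sum(.data$copy_count)) |>
    ungroup() |>
    arrange(.data$amplicon_id, desc(.data$copy_count), .data$sequence)
}

#' Per-amplicon variant filters
#'
#' `filter_min_copies()` removes variants seen fewer than `min_copies` times
#' within an amplicon ("less than" is strict: a variant at exactly
#' `min_copies` is kept) and recomputes `total_reads` as the surviving copy
#' sum, which is the denominator used for all downstream per-amplicon
#' frequencies.  `filter_min_reads()` then discards whole amplicons whose
#' surviving total is below `min_reads`.  Both are idempotent; discarded
#' records are attached as the `"log"` attribute (see [filter_log()]).
#'
#' @param variants Variant tibble from [dereplicate_reads()].
#' @param min_copies,min_reads Strict lower thresholds (defaults 5 and 18).
#' @return Filtered variant tibble with a `"log"` attribute.
#' @export
filter_min_copies <- function(variants, min_copies = 5L) {
  dropped <- variants |> filter(.data$copy_count < min_copies)
  kept <- variants |>
    filter(.data$copy_count >= min_copies) |>
    group_by(.data$amplicon_id) |>
    mutate(total_reads = sum(.data$copy_count)) |>
    ungroup()
  emptied <- setdiff(unique(variants$amplicon_id), unique(kept$amplicon_id))
  attr(kept, "log") <- list(dropped_variants = dropped,
                            emptied_amplicons = emptied)
  kept
}

#' @rdname filter_min_copies
#' @export
filter_min_reads <- function(variants, min_reads = 18L) {
  discarded <- variants |> filter(.data$total_reads < min_reads)
  kept <- variants |> filter(.data$total_reads >= min_reads)
  attr(kept, "log") <- list(
    discarded_amplicons = distinct(discarded, .data$amplicon_id,
                                   .data$individual_id, .data$locus,
                                   .data$total_reads)
  )
  kept
}

#' @rdname filter_min_copies
#' @export
filter_log <- function(variants) attr(variants, "log")

#' Trim variants to the common alignable region
#'
#' Applies each locus's trim rule (leading/trailing bases removed) so that
#' both loci cover the same region, then re-merges variants that became
#' identical after trimming, summing their copy counts.  Variants shorter
#' than the trim amounts are dropped and logged.
#'
#' @param variants Variant tibble.
#' @param locus_configs Tibble from [default_locus_configs()].
#' @return Trimmed variant tibble with a `"log"` attribute listing dropped
#'   variants.
#' @export
trim_common_region <- function(variants, locus_configs = default_locus_configs()) {
  cfg <- locus_configs |> select("locus", "trim_lead", "trim_trail")
  x <- variants |>
    left_join(cfg, by = "locus") |>
    mutate(too_short = nchar(.data$sequence) <= .data$trim_lead + .data$trim_trail)
  dropped <- x |> filter(.data$too_short)
  out <- x |>
    filter(!.data$too_short) |>
    mutate(sequence = substr(.data$sequence, .data$trim_lead + 1L,
                             nchar(.data$sequence) - .data$trim_trail)) |>
    group_by(.data$amplicon_id, .data$sample_id, .data$individual_id,
             .data$locus, .data$sequence) |>
    summarise(copy_count = sum(.data$copy_count), .groups = "drop") |>
    group_by(.data$amplicon_id) |>
    mutate(total_reads = sum(.data$copy_count)) |>
    ungroup() |>
    arrange(.data$amplicon_id, desc(.data$copy_count), .data$sequence)
  attr(out, "log") <- list(dropped_variants = select(dropped, -"too_short",
                                                     -"trim_lead", -"trim_trail"))
  out
}

#' Minimum-coverage confidence model
#'
#' `coverage_confidence()` gives the exact probability, under independent
#' sampling of reads from `m` variants (equally likely by default, or with
#' probabilities `probs`), that every variant appears at least `r` times
#' among `n` reads, computed by multinomial inclusion-exclusion.
#' `min_reads_required()` returns the smallest `n` for which that
#' probability reaches the confidence level `f`.
#'
#' @param n Total number of reads.
#' @param m Maximal number of variants at the locus.
#' @param r Minimum copy number required of each true variant.
#' @param f Confidence level in (0, 1).
#' @param probs Optional per-variant sampling probabilities (length `m`,
#'   summing to 1); `NULL` means equal probabilities `1/m`.
#' @return `coverage_confidence()`: a probability; `min_reads_required()`:
#'   an integer `n`.
#' @export
coverage_confidence <- function(n, m, r, probs = NULL) {
  stopifnot(m >= 1L, r >= 1L, n >= 0L)
  if (is.null(probs)) probs <- rep(1 / m, m)
  if (length(probs) != m || abs(sum(probs) - 1) > 1e-9) {
    abort("probs must have length m and sum to 1")
  }
  if (n < m * r) return(0)

  ## P(every variant in subset S has count <= r-1):
  ## DP over members of S accumulating g(t) = sum over count vectors with
  ## total t of prod p_i^{c_i} / c_i!, then multiply by n!/(n-t)! (1-pS)^{n-t}.
  p_subset_low <- function(p_s) {
    j <- length(p_s)
    tmax <- j * (r - 1L)
    g <- c(1, rep(0, tmax))
    for (p in p_s) {
      gn <- rep(0, tmax + 1L)
      for (c_i in 0:(r - 1L)) {
        w <- p^c_i / factorial(c_i)
        src <- seq_len(tmax + 1L - c_i)
        gn[src + c_i] <- gn[src + c_i] + g[src] * w
      }
      g <- gn
    }
    rest <- 1 - sum(p_s)
    t <- 0:tmax
    valid <- t <= n
    coef <- exp(lfactorial(n) - lfactorial(n - t[valid]))
    sum(g[valid] * coef * rest^(n - t[valid]))
  }

  equal <- length(unique(round(probs, 12))) == 1L
  total <- 0
  if (equal) {
    for (j in 0:m) {
      pj <- if (j == 0L) 1 else p_subset_low(rep(probs[1], j))
      total <- total + (-1)^j * choose(m, j) * pj
    }
  } else {
    if (m > 12L) abort("unequal-probability model supports m <= 12")
    for (j in 0:m) {
      subs <- if (j == 0L) list(integer(0)) else
        asplit(utils::combn(m, j), 2)
      for (s in subs) {
        pj <- if (j == 0L) 1 else p_subset_low(probs[s])
        total <- total + (-1)^j * pj
      }
    }
  }
  min(max(total, 0), 1)
}

#' @rdname coverage_confidence
#' @export
min_reads_required <- function(m, r, f = 0.95, probs = NULL) {
  stopifnot(m >= 1L, r >= 1L)
  if (f >= 1 || f <= 0) abort("confidence level f must lie in (0, 1)")
  n <- as.integer(m * r)
  while (coverage_confidence(n, m, r, probs) < f) n <- n + 1L
  n
}

#' Preprocess a read library through the standard filter cascade
#'
#' Convenience wrapper chaining [demultiplex_reads()], [dereplicate_reads()],
#' [filter_min_copies()], [filter_min_reads()] and [trim_common_region()],
#' collecting a per-stage summary (reads, amplicons, individuals, variants)
#' in the style of a stepwise filtering table.
#'
#' @inheritParams demultiplex_reads
#' @param min_copies,min_reads Filter thresholds.
#' @return List with `variants` (final variant tibble), `demux` (the demux
#'   object) and `summary` (per-stage tibble).
#' @export
preprocess_reads <- function(reads, tag_scheme,
                             locus_configs = default_locus_configs(),
                             min_copies = 5L, min_reads = 18L) {
  dm <- demultiplex_reads(reads, tag_scheme, locus_configs)
  v1 <- dereplicate_reads(dm)
  v2 <- filter_min_copies(v1, min_copies)
  v3 <- filter_min_reads(v2, min_reads)
  v4 <- trim_common_region(v3, locus_configs)
  stage <- function(step, v) {
    tibble(step = step,
           reads = sum(v$copy_count),
           amplicons = n_distinct(v$amplicon_id),
           individuals = n_distinct(v$individual_id),
           variants = n_distinct(v$sequence))
  }
  summary <- bind_rows(
    tibble(step = "input", reads = nrow(reads), amplicons = NA_integer_,
           individuals = NA_integer_, variants = NA_integer_),
    tibble(step = "demultiplexed", reads = nrow(dm$assigned),
           amplicons = n_distinct(dm$assigned$amplicon_id),
           individuals = n_distinct(dm$assigned$individual_id),
           variants = NA_integer_),
    stage("dereplicated", v1),
    stage(paste0("copy_filter_", min_copies), v2),
    stage(paste0("amplicon_filter_", min_reads), v3),
    stage("common_region", v4)
  )
  list(variants = v4, demux = dm, summary = summary)
}
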
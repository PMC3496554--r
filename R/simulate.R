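#' Locus configurations for a two-locus amplicon panel
#'
#' Each locus is described by its template-specific primers, the length of the
#' analysable core region and a trim rule bringing both loci back to the same
#' region after primer removal (leading bases trimmed from one locus, trailing
#' bases from the other, as is done when two co-amplified fragments overlap a
#' common alignable region).
#'
#' @param locus Locus name.
#' @param primer_fwd,primer_rev Template-specific primer sequences (the
#'   reverse primer is given in its own reading direction and appears
#'   reverse-complemented on the forward strand of a read).
#' @param core_length Length in bp of the post-trim core region; a multiple
#'   of 3 so validated alleles stay in frame for codon analyses.
#' @param trim_lead,trim_trail Number of leading/trailing bases removed from
#'   the primer-trimmed template to reach the core region.
#' @return A one-row tibble (a locus configuration); `default_locus_configs()`
#'   returns the two-locus DRB/DQB panel used throughout.
#' @export
locus_config <- function(locus, primer_fwd, primer_rev, core_length = 162L,
                         trim_lead = 0L, trim_trail = 0L) {
  stopifnot(nchar(primer_fwd) > 0L, nchar(primer_rev) > 0L,
            trim_lead >= 0L, trim_trail >= 0L,
            trim_lead + trim_trail < trim_lead + trim_trail + core_length)
  tibble(
    locus = locus, primer_fwd = primer_fwd, primer_rev = primer_rev,
    core_length = as.integer(core_length),
    trim_lead = as.integer(trim_lead), trim_trail = as.integer(trim_trail),
    template_length = as.integer(core_length + trim_lead + trim_trail)
  )
}

#' @rdname locus_config
#' @export
default_locus_configs <- function() {
  bind_rows(
    locus_config("DRB", "GAGTGTCATTTCTACAACGG", "CTGGCTGTTCCAGTACTCGG",
                 core_length = 162L, trim_lead = 0L, trim_trail = 8L),
    locus_config("DQB", "CTCTGCTACTTCACTAACGG", "TTGTGTCTGCACACCGTGT",
                 core_length = 162L, trim_lead = 4L, trim_trail = 0L)
  )
}

#' Allele frequency spectra
#'
#' `allele_spectrum()` builds a sorted frequency vector summing to 1.  The
#' `"wide"` shape emulates the wide spectrum seen in large wild-population
#' MHC surveys (maximum around 0.21, median around 0.02, minimum around
#' 0.001): two power-law arcs hinged at the median, with the exponent solved
#' so the spectrum is exactly normalised.
#'
#' @param n_alleles Number of alleles.
#' @param shape `"uniform"`, `"geometric"` or `"wide"`.
#' @param decay Ratio of successive frequencies for the geometric shape.
#' @param fmax,fmed,fmin Anchor frequencies for the wide shape.
#' @return Numeric vector of length `n_alleles`, decreasing, summing to 1.
#' @export
allele_spectrum <- function(n_alleles, shape = c("uniform", "geometric", "wide"),
                            decay = 0.9, fmax = 0.21, fmed = 0.02, fmin = 0.001) {
  shape <- match.arg(shape)
  n <- as.integer(n_alleles)
  if (n < 1L) abort("n_alleles must be >= 1")
  if (n == 1L) return(1)
  f <- switch(shape,
    uniform = rep(1 / n, n),
    geometric = {
      f <- decay^(0:(n - 1))
      f / sum(f)
    },
    wide = spectrum_wide(n, fmax, fmed, fmin)
  )
  if (abs(sum(f) - 1) > 1e-9) abort("frequency spectrum not normalisable")
  f
}

spectrum_wide <- function(n, fmax, fmed, fmin) {
  if (!(fmax > fmed && fmed > fmin && fmin > 0)) {
    abort("need fmax > fmed > fmin > 0")
  }
  m <- ceiling(n / 2)
  if (m < 2L || n - m < 1L) { # too few alleles for the two-arc form
    f <- exp(seq(log(fmax), log(fmin), length.out = n))
    return(f / sum(f))
  }
  arc <- function(a) {
    i_up <- seq_len(m)
    up <- fmed + (fmax - fmed) * ((m - i_up) / (m - 1))^a
    i_lo <- seq(m + 1L, n)
    lo <- fmin + (fmed - fmin) * ((n - i_lo) / (n - m))^a
    c(up, lo)
  }
  tot <- function(a) sum(arc(a)) - 1
  if (tot(50) > 0 || tot(1e-3) < 0) { # anchors infeasible at this n: rescale
    f <- exp(seq(log(fmax), log(fmin), length.out = n))
    return(f / sum(f))
  }
  a <- stats::uniroot(tot, c(1e-3, 50), tol = 1e-12)$root
  arc(a)
}

## Random stop-free in-frame core sequence.
random_core <- function(core_length) {
  stopifnot(core_length %% 3L == 0L)
  sense <- setdiff(
    apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA")
  )
  paste(sample(sense, core_length / 3L, replace = TRUE), collapse = "")
}

## Mutate `core` at `k` random positions, avoiding stop codons.
mutate_core <- function(core, k) {
  x <- strsplit(core, "")[[1]]
  pos <- sample(length(x), k)
  for (p in pos) {
    repeat {
      b <- sample(setdiff(DNA_BASES, x[p]), 1)
      old <- x[p]
      x[p] <- b
      cod <- ((p - 1L) %/% 3L) * 3L + 1L
      if (!is_stop_codon(paste(x[cod:(cod + 2L)], collapse = ""))) break
      x[p] <- old
    }
  }
  paste(x, collapse = "")
}

## Generate a pool of divergent allele cores: pairwise Hamming distance at
## least `min_dist` and recombination-distinct (no allele equals a
## single-crossover product of two others), so true alleles can never be
## mistaken for each other's point mutants or chimeras downstream.
generate_allele_cores <- function(n_alleles, core_length, min_dist = 3L,
                                  max_tries = 5000L) {
  pool <- character(0)
  products <- new.env(hash = TRUE, parent = emptyenv())
  tries <- 0L
  while (length(pool) < n_alleles) {
    tries <- tries + 1L
    if (tries > max_tries) abort("failed to generate a divergent allele pool")
    cand <- if (length(pool) == 0L) {
      random_core(core_length)
    } else {
      mutate_core(pool[1], sample(8:24, 1))
    }
    if (length(pool) > 0L) {
      d <- vapply(pool, function(p) {
        sum(strsplit(p, "")[[1]] != strsplit(cand, "")[[1]])
      }, numeric(1))
      if (min(d) < min_dist) next
    }
    if (!is.null(products[[cand]])) next # equals a crossover of two alleles
    new_prod <- unlist(lapply(pool, function(p) {
      ## products equal to a parent are harmless: the chimera screen only
      ## considers recombinants distinct from both parentals
      setdiff(c(crossover_products(cand, p), crossover_products(p, cand)),
              c(cand, p))
    }))
    if (any(pool %in% new_prod)) next
    pool <- c(pool, cand)
    for (s in unique(new_prod)) products[[s]] <- TRUE
  }
  pool
}

#' Simulate a two-locus population with known truth
#'
#' Generates divergent allele pools for each locus, two-locus haplotype
#' frequencies under a chosen level of linkage disequilibrium, and diploid
#' genotypes drawn by random union of haplotypes.  Allele pools are built so
#' that no allele is within `min_allele_distance` substitutions of another or
#' equal to a single-crossover recombinant of two others, emulating the deep
#' divergence of MHC allelic lineages and keeping true alleles identifiable.
#'
#' @param n_individuals Number of diploid individuals (> 0).
#' @param n_alleles Integer vector of length 2: pool sizes for the two loci.
#' @param spectrum Frequency-spectrum shape per [allele_spectrum()], or a
#'   list of two explicit frequency vectors.
#' @param ld `"independent"` (haplotype frequencies are products of allele
#'   frequencies), `"complete"` (allele i at locus 1 is deterministically
#'   bound to allele i at locus 2), or `"intermediate"` (mixture controlled
#'   by `theta`).
#' @param theta Mixing weight in \[0, 1\] for `ld = "intermediate"`
#'   (0 = independent, 1 = complete).
#' @param locus_configs Panel from [default_locus_configs()].
#' @param min_allele_distance Minimum pairwise substitution distance between
#'   allele cores.
#' @param seed Integer seed; the returned truth is reproducible given it.
#' @return A `sim_truth` object: list with `pools` (locus, allele_id,
#'   frequency, core and full template sequence), `haplotypes` (allele pair
#'   and frequency), `haplotype_draws` (two haplotype rows per individual),
#'   `pedigree` (empty until [simulate_pedigree()]), and `loci`.
#' @export
simulate_population <- function(n_individuals, n_alleles = c(10L, 10L),
                                spectrum = "uniform",
                                ld = c("independent", "complete", "intermediate"),
                                theta = 0.5,
                                locus_configs = default_locus_configs(),
                                min_allele_distance = 3L, seed = NULL) {
  ld <- match.arg(ld)
  if (n_individuals < 1L) abort("need at least one individual")
  if (nrow(locus_configs) != 2L) abort("exactly two loci are supported")
  if (any(n_alleles < 1L)) abort("each locus needs at least one allele")
  if (theta < 0 || theta > 1) abort("theta must lie in [0, 1]")
  with_seed_if(seed, {
    loci <- locus_configs$locus
    freqs <- lapply(seq_len(2L), function(i) {
      if (is.list(spectrum)) {
        f <- spectrum[[i]]
        if (any(f < 0) || abs(sum(f) - 1) > 1e-9) {
          abort("frequency spectrum not normalisable")
        }
        f
      } else {
        allele_spectrum(n_alleles[i], spectrum)
      }
    })
    pools <- purrr::map(seq_len(2L), function(i) {
      cfg <- locus_configs[i, ]
      cores <- generate_allele_cores(length(freqs[[i]]), cfg$core_length,
                                     min_dist = min_allele_distance)
      lead <- if (cfg$trim_lead > 0) random_dna(1, cfg$trim_lead) else ""
      trail <- if (cfg$trim_trail > 0) random_dna(1, cfg$trim_trail) else ""
      tibble(
        locus = cfg$locus,
        allele_id = sprintf("%s*%02d", cfg$locus, seq_along(cores)),
        frequency = freqs[[i]],
        core = cores,
        sequence = paste0(lead, cores, trail)
      )
    }) |> list_rbind()

    k1 <- sum(pools$locus == loci[1])
    k2 <- sum(pools$locus == loci[2])
    h_ind <- outer(freqs[[1]], freqs[[2]])
    h_comp <- matrix(0, k1, k2)
    for (i in seq_len(k1)) {
      h_comp[i, ((i - 1L) %% k2) + 1L] <- freqs[[1]][i]
    }
    h <- switch(ld,
      independent = h_ind,
      complete = h_comp,
      intermediate = (1 - theta) * h_ind + theta * h_comp
    )
    hap_tbl <- tibble(
      allele_1 = rep(pools$allele_id[pools$locus == loci[1]], times = k2),
      allele_2 = rep(pools$allele_id[pools$locus == loci[2]], each = k1),
      frequency = as.vector(h)
    ) |> filter(.data$frequency > 0)

    draw <- sample.int(nrow(hap_tbl), 2L * n_individuals, replace = TRUE,
                       prob = hap_tbl$frequency)
    ids <- sprintf("IND%04d", seq_len(n_individuals))
    haplotype_draws <- tibble(
      individual_id = rep(ids, each = 2L),
      hap = rep(1:2, n_individuals),
      allele_1 = hap_tbl$allele_1[draw],
      allele_2 = hap_tbl$allele_2[draw]
    )
    structure(
      list(
        loci = locus_configs, pools = pools, haplotypes = hap_tbl,
        haplotype_draws = haplotype_draws,
        pedigree = tibble(offspring_id = character(0),
                          mother_id = character(0), father_id = character(0)),
        ld = ld, theta = if (ld == "intermediate") theta else NULL,
        seed = seed
      ),
      class = "sim_truth"
    )
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> ", n_distinct(x$haplotype_draws$individual_id),
      " individuals (", nrow(x$pedigree), " offspring), loci: ",
      paste(x$loci$locus, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' True genotypes of a simulated population
#'
#' @param truth A `sim_truth` object.
#' @return Tibble with one row per individual and locus: `individual_id`,
#'   `locus`, `allele1`, `allele2` (unordered, sorted; homozygotes repeat the
#'   allele).
#' @export
true_genotypes <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  loci <- truth$loci$locus
  purrr::map(1:2, function(i) {
    col <- paste0("allele_", i)
    truth$haplotype_draws |>
      group_by(.data$individual_id) |>
      summarise(locus = loci[i],
                allele1 = min(.data[[col]]),
                allele2 = max(.data[[col]]),
                .groups = "drop")
  }) |> list_rbind() |>
    arrange(.data$individual_id, .data$locus)
}

#' Add parent-offspring triads to a simulated population
#'
#' Pairs up founder individuals as parents and creates offspring receiving
#' one whole two-locus haplotype from each parent (Mendelian,
#' recombination-free).
#'
#' @param truth A `sim_truth` object.
#' @param n_triads Number of mother-father-offspring triads.
#' @param seed Integer seed.
#' @return The updated `sim_truth` with offspring appended and the pedigree
#'   table filled.
#' @export
simulate_pedigree <- function(truth, n_triads, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  founders <- setdiff(unique(truth$haplotype_draws$individual_id),
                      truth$pedigree$offspring_id)
  if (2L * n_triads > length(founders)) {
    abort("not enough founder individuals to serve as parents")
  }
  with_seed_if(seed, {
    parents <- sample(founders, 2L * n_triads)
    mothers <- parents[seq_len(n_triads)]
    fathers <- parents[n_triads + seq_len(n_triads)]
    off_ids <- sprintf("OFF%04d", nrow(truth$pedigree) + seq_len(n_triads))
    draws <- truth$haplotype_draws
    off_draws <- purrr::map(seq_len(n_triads), function(i) {
      mh <- draws[draws$individual_id == mothers[i], ][sample(2L, 1L), ]
      fh <- draws[draws$individual_id == fathers[i], ][sample(2L, 1L), ]
      tibble(individual_id = off_ids[i], hap = 1:2,
             allele_1 = c(mh$allele_1, fh$allele_1),
             allele_2 = c(mh$allele_2, fh$allele_2))
    }) |> list_rbind()
    truth$haplotype_draws <- bind_rows(draws, off_draws)
    truth$pedigree <- bind_rows(
      truth$pedigree,
      tibble(offspring_id = off_ids, mother_id = mothers, father_id = fathers)
    )
    truth
  })
}

#' Error model for simulated 454-style reads
#'
#' @param substitution_rate Per-base substitution probability.
#' @param indel_rate Per-base indel probability, multiplied at each site by
#'   the length of the homopolymer run containing it (454 chemistry's
#'   dominant error mode).
#' @param chimera_within Probability that a read is a within-locus PCR
#'   chimera of the individual's two alleles (uniform crossover).
#' @param chimera_between Probability that a read is a between-locus chimera
#'   carrying the first locus's forward primer and the second locus's reverse
#'   primer (the recombinant structure seen when two similar loci are
#'   co-amplified).
#' @param contamination_rate Probability that a read is copied from another
#'   amplicon of the same locus (cross-amplicon contamination).
#' @param coverage_mean Mean reads per amplicon (> 0).
#' @param coverage_size Negative-binomial size parameter; smaller values give
#'   more overdispersed per-amplicon coverage (`Inf` = Poisson).  The default
#'   0.85 reproduces the heavy per-amplicon coverage dispersion observed in
#'   pooled amplicon runs (SD slightly above the mean, i.e. a coefficient of
#'   variation around 1.1).
#' @return An `error_model` list.
#' @export
error_model <- function(substitution_rate = 1e-3, indel_rate = 1e-3,
                        chimera_within = 0.05, chimera_between = 0,
                        contamination_rate = 0.005,
                        coverage_mean = 100, coverage_size = 0.85) {
  rates <- c(substitution_rate, indel_rate, chimera_within, chimera_between,
             contamination_rate)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  if (chimera_within + chimera_between + contamination_rate > 1) {
    abort("chimera and contamination rates must sum to at most 1")
  }
  if (coverage_mean <= 0) abort("coverage_mean must be > 0")
  structure(list(
    substitution_rate = substitution_rate, indel_rate = indel_rate,
    chimera_within = chimera_within, chimera_between = chimera_between,
    contamination_rate = contamination_rate,
    coverage_mean = coverage_mean, coverage_size = coverage_size
  ), class = "error_model")
}

#' Build an unordered tag-pair scheme
#'
#' Assigns each sample a pair of 10-bp tags such that the unordered pair
#' (forward/reverse interchangeable) identifies the sample uniquely; tag
#' pairs are drawn from a minimal grid of distinct tags, mirroring the
#' cost-saving tagging design of pooled amplicon runs.
#'
#' @param individual_ids Character vector of individuals to tag.
#' @param replicates Individuals that get a second, independently tagged
#'   amplicon (for repeatability checks).
#' @param tag_length Tag length in bp.
#' @param seed Integer seed.
#' @return Tibble with `sample_id`, `individual_id`, `replicate`, `tag_fwd`,
#'   `tag_rev`.
#' @export
make_tag_scheme <- function(individual_ids, replicates = character(0),
                            tag_length = 10L, seed = NULL) {
  stopifnot(!anyDuplicated(individual_ids))
  if (!all(replicates %in% individual_ids)) {
    abort("replicates must name existing individuals")
  }
  n_samples <- length(individual_ids) + length(replicates)
  with_seed_if(seed, {
    n_tags <- ceiling((1 + sqrt(1 + 8 * n_samples)) / 2) + 1
    repeat {
      tags <- unique(random_dna(n_tags, tag_length))
      if (length(tags) >= n_tags) break
    }
    pairs <- utils::combn(seq_len(length(tags)), 2L)
    rep_ids <- if (length(replicates)) paste0(replicates, "_rep2") else character(0)
    scheme <- tibble(
      sample_id = c(individual_ids, rep_ids),
      individual_id = c(individual_ids, replicates),
      replicate = c(rep(1L, length(individual_ids)),
                    rep(2L, length(replicates))),
      tag_fwd = tags[pairs[1, seq_len(n_samples)]],
      tag_rev = tags[pairs[2, seq_len(n_samples)]]
    )
    key <- tag_pair_key(scheme$tag_fwd, scheme$tag_rev)
    if (anyDuplicated(key)) abort("duplicate unordered tag pair in scheme")
    scheme
  })
}

## Homopolymer-weighted per-site indel probabilities for one template.
indel_site_probs <- function(template, indel_rate) {
  x <- strsplit(template, "")[[1]]
  r <- rle(x)
  pmin(1, indel_rate * rep(r$lengths, r$lengths))
}

## Apply substitution + homopolymer indel errors to a vector of template
## strings sharing the same sequence. Returns list(seqs, n_events).
apply_point_errors <- function(templates, substitution_rate, indel_rate) {
  n <- length(templates)
  if (n == 0L) return(list(seqs = templates, n_events = integer(0)))
  L <- nchar(templates[1])
  n_sub <- rbinom(n, L, substitution_rate)
  p_ind <- indel_site_probs(templates[1], indel_rate)
  ind_hits <- matrix(runif(n * L) < rep(p_ind, each = n), nrow = n)
  n_ind <- rowSums(ind_hits)
  n_events <- n_sub + n_ind
  touched <- which(n_events > 0L)
  out <- templates
  for (i in touched) {
    x <- strsplit(templates[i], "")[[1]]
    if (n_sub[i] > 0L) {
      pos <- sample(L, n_sub[i])
      for (p in pos) x[p] <- sample(setdiff(DNA_BASES, x[p]), 1)
    }
    ipos <- which(ind_hits[i, ])
    if (length(ipos) > 0L) {
      for (p in sort(ipos, decreasing = TRUE)) {
        if (runif(1) < 0.5) {
          x <- append(x, x[p], after = p) # homopolymer extension
        } else {
          x <- x[-p]
        }
      }
    }
    out[i] <- paste(x, collapse = "")
  }
  list(seqs = out, n_events = as.integer(n_events))
}

#' Simulate a tagged amplicon read library with truth labels
#'
#' Emits one amplicon per sample and locus: reads are laid out as
#' `forward tag + forward primer + template + revcomp(reverse primer) +
#' revcomp(reverse tag)` and emitted in either orientation with equal
#' probability.  Per-amplicon depth is negative-binomial; each read is,
#' exclusively, a cross-amplicon contaminant, a between-locus chimera, a
#' within-locus chimera, or a faithful copy of one of the individual's two
#' alleles; point substitutions and homopolymer-biased indels are then
#' applied to the template of every read.
#'
#' @param truth A `sim_truth` object.
#' @param model An [error_model()].
#' @param tag_scheme Scheme from [make_tag_scheme()]; by default one amplicon
#'   per individual with no replicates.
#' @param seed Integer seed; the same seed reproduces the library exactly.
#' @return A `sim_reads` list: `reads` (tibble `read_id`, `sequence`),
#'   `truth` (per-read labels: `read_id`, `sample_id`, `individual_id`,
#'   `locus`, `provenance` in true_allele/point_error/chimera/contaminant,
#'   `n_errors`), `scheme`, `configs`, `model`.
#' @export
simulate_reads <- function(truth, model = error_model(), tag_scheme = NULL,
                           seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"), inherits(model, "error_model"))
  ids <- unique(truth$haplotype_draws$individual_id)
  cfg <- truth$loci
  loci <- cfg$locus
  geno <- true_genotypes(truth)
  pool_seq <- setNames(truth$pools$sequence, truth$pools$allele_id)

  with_seed_if(seed, {
    if (is.null(tag_scheme)) tag_scheme <- make_tag_scheme(ids)
    if (anyDuplicated(tag_pair_key(tag_scheme$tag_fwd, tag_scheme$tag_rev))) {
      abort("duplicate unordered tag pair in scheme")
    }
    amps <- tidyr::expand_grid(tag_scheme, locus = loci)
    n_amp <- nrow(amps)
    depth <- if (is.finite(model$coverage_size)) {
      rnbinom(n_amp, mu = model$coverage_mean, size = model$coverage_size)
    } else {
      rpois(n_amp, model$coverage_mean)
    }

    per_amp <- purrr::map(seq_len(n_amp), function(a) {
      nr <- depth[a]
      if (nr == 0L) return(NULL)
      ind <- amps$individual_id[a]
      loc <- amps$locus[a]
      g <- geno[geno$individual_id == ind & geno$locus == loc, ]
      alleles <- c(g$allele1, g$allele2)
      g1 <- geno[geno$individual_id == ind & geno$locus == loci[1], ]
      g2 <- geno[geno$individual_id == ind & geno$locus == loci[2], ]
      u <- runif(nr)
      p1 <- model$contamination_rate
      p2 <- p1 + model$chimera_between
      p3 <- p2 + model$chimera_within
      prov <- ifelse(u < p1, "contaminant",
               ifelse(u < p2, "chimera_between",
                ifelse(u < p3, "chimera_within", "true_allele")))
      tibble(sample_id = amps$sample_id[a], individual_id = ind, locus = loc,
             provenance = prov,
             allele = sample(alleles, nr, replace = TRUE))
    }) |> list_rbind()

    n_reads <- nrow(per_amp)
    per_amp$template <- unname(pool_seq[per_amp$allele])
    per_amp$locus_fwd <- per_amp$locus
    per_amp$locus_rev <- per_amp$locus

    ## within-locus chimeras: uniform crossover between the two alleles
    iw <- which(per_amp$provenance == "chimera_within")
    if (length(iw) > 0L) {
      for (i in iw) {
        g <- geno[geno$individual_id == per_amp$individual_id[i] &
                    geno$locus == per_amp$locus[i], ]
        pa <- pool_seq[[g$allele1]]
        pb <- pool_seq[[g$allele2]]
        if (runif(1) < 0.5) { tmp <- pa; pa <- pb; pb <- tmp }
        k <- sample(nchar(pa) - 1L, 1L)
        per_amp$template[i] <- paste0(substr(pa, 1L, k),
                                      substr(pb, k + 1L, nchar(pb)))
      }
    }
    ## between-locus chimeras: locus-1 prefix + locus-2 suffix, carrying the
    ## locus-1 forward and locus-2 reverse primers
    ib <- which(per_amp$provenance == "chimera_between")
    if (length(ib) > 0L) {
      for (i in ib) {
        ind <- per_amp$individual_id[i]
        a1 <- geno[geno$individual_id == ind & geno$locus == loci[1], ]
        a2 <- geno[geno$individual_id == ind & geno$locus == loci[2], ]
        pa <- pool_seq[[sample(c(a1$allele1, a1$allele2), 1L)]]
        pb <- pool_seq[[sample(c(a2$allele1, a2$allele2), 1L)]]
        k <- sample(min(nchar(pa), nchar(pb)) - 1L, 1L)
        per_amp$template[i] <- paste0(substr(pa, 1L, k),
                                      substr(pb, k + 1L, nchar(pb)))
        per_amp$locus_fwd[i] <- loci[1]
        per_amp$locus_rev[i] <- loci[2]
      }
    }
    ## contaminants: template copied from a random other individual, same locus
    ic <- which(per_amp$provenance == "contaminant")
    if (length(ic) > 0L) {
      for (i in ic) {
        others <- setdiff(ids, per_amp$individual_id[i])
        src <- sample(others, 1L)
        g <- geno[geno$individual_id == src & geno$locus == per_amp$locus[i], ]
        per_amp$template[i] <- pool_seq[[sample(c(g$allele1, g$allele2), 1L)]]
      }
    }

    ## point errors, applied per class of identical templates
    per_amp$n_errors <- 0L
    grp <- split(seq_len(n_reads), per_amp$template)
    for (idx in grp) {
      res <- apply_point_errors(per_amp$template[idx],
                                model$substitution_rate, model$indel_rate)
      per_amp$template[idx] <- res$seqs
      per_amp$n_errors[idx] <- res$n_events
    }
    per_amp$provenance <- ifelse(
      per_amp$provenance == "true_allele" & per_amp$n_errors > 0L,
      "point_error", per_amp$provenance)
    per_amp$provenance <- sub("chimera_(within|between)", "chimera",
                              per_amp$provenance)

    ## assemble reads
    fwd_primer <- setNames(cfg$primer_fwd, cfg$locus)
    rev_primer <- setNames(cfg$primer_rev, cfg$locus)
    sch_f <- setNames(tag_scheme$tag_fwd, tag_scheme$sample_id)
    sch_r <- setNames(tag_scheme$tag_rev, tag_scheme$sample_id)
    seqs <- paste0(
      sch_f[per_amp$sample_id],
      fwd_primer[per_amp$locus_fwd],
      per_amp$template,
      revcomp(rev_primer[per_amp$locus_rev]),
      revcomp(sch_r[per_amp$sample_id])
    )
    flip <- runif(n_reads) < 0.5
    seqs[flip] <- revcomp(seqs[flip])
    read_id <- sprintf("read%07d", seq_len(n_reads))

    structure(list(
      reads = tibble(read_id = read_id, sequence = seqs),
      truth = tibble(read_id = read_id,
                     sample_id = per_amp$sample_id,
                     individual_id = per_amp$individual_id,
                     locus = per_amp$locus,
                     provenance = per_amp$provenance,
                     n_errors = per_amp$n_errors),
      scheme = tag_scheme, configs = cfg, model = model, seed = seed
    ), class = "sim_reads")
  })
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("<sim_reads> ", nrow(x$reads), " reads, ",
      n_distinct(x$truth$sample_id), " samples x ",
      n_distinct(x$truth$locus), " loci\n", sep = "")
  print(count(x$truth, .data$provenance))
  invisible(x)
}
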
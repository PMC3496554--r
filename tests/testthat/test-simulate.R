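test_that("allele spectra are normalised, decreasing, and shaped as requested", {
  for (shape in c("uniform", "geometric", "wide")) {
    f <- allele_spectrum(60, shape)
    expect_equal(sum(f), 1, tolerance = 1e-9)
    expect_true(all(diff(f) <= 1e-12))
  }
  f <- allele_spectrum(60, "wide")
  expect_equal(max(f), 0.21, tolerance = 1e-6)
  expect_equal(min(f), 0.001, tolerance = 1e-6)
  expect_error(allele_spectrum(0), "n_alleles")
})

test_that("simulated populations conserve allele draws and honour LD modes", {
  truth <- simulate_population(100, n_alleles = c(10, 10), seed = 5)
  tg <- true_genotypes(truth)
  expect_equal(nrow(tg), 200) # one row per individual x locus
  counts <- table(c(tg$allele1[tg$locus == "DRB"], tg$allele2[tg$locus == "DRB"]))
  expect_equal(sum(counts), 200) # 2 draws per individual at the locus
  expect_equal(sum(truth$pools$frequency[truth$pools$locus == "DRB"]), 1,
               tolerance = 1e-9)

  comp <- simulate_population(80, n_alleles = c(6, 6), ld = "complete", seed = 6)
  draws <- comp$haplotype_draws
  idx <- function(x) as.integer(sub(".*\\*", "", x))
  expect_true(all(idx(draws$allele_1) == idx(draws$allele_2)))

  expect_error(simulate_population(0, seed = 1), "individual")
  expect_error(simulate_population(5, spectrum = list(c(0.5, 0.4), c(1)),
                                   n_alleles = c(2, 1), seed = 1),
               "normalisable")
})

test_that("allele pools are divergent and recombination-distinct", {
  truth <- simulate_population(10, n_alleles = c(12, 12), seed = 9)
  for (loc in c("DRB", "DQB")) {
    cores <- truth$pools$core[truth$pools$locus == loc]
    d <- utils::adist(cores)
    expect_true(all(d[upper.tri(d)] >= 3))
    for (i in seq_along(cores)) {
      for (j in seq_along(cores)) {
        if (i == j) next
        prods <- setdiff(mhctyper:::crossover_products(cores[i], cores[j]),
                         cores[c(i, j)])
        expect_false(any(cores %in% prods))
      }
    }
  }
})

test_that("pedigree simulation transmits one haplotype per parent", {
  truth <- simulate_population(40, n_alleles = c(8, 8), seed = 21)
  truth <- simulate_pedigree(truth, 10, seed = 22)
  tg <- true_genotypes(truth)
  ped <- truth$pedigree
  expect_equal(nrow(ped), 10)
  for (i in seq_len(nrow(ped))) {
    for (loc in c("DRB", "DQB")) {
      off <- tg[tg$individual_id == ped$offspring_id[i] & tg$locus == loc, ]
      mo <- tg[tg$individual_id == ped$mother_id[i] & tg$locus == loc, ]
      fa <- tg[tg$individual_id == ped$father_id[i] & tg$locus == loc, ]
      o <- c(off$allele1, off$allele2)
      expect_true((o[1] %in% c(mo$allele1, mo$allele2) &&
                     o[2] %in% c(fa$allele1, fa$allele2)) ||
                    (o[2] %in% c(mo$allele1, mo$allele2) &&
                       o[1] %in% c(fa$allele1, fa$allele2)))
    }
  }
  expect_error(simulate_pedigree(truth, 1000, seed = 1), "founder")
})

test_that("read provenance labels partition the library", {
  truth <- simulate_population(20, n_alleles = c(6, 6), seed = 31)
  sr <- simulate_reads(truth, error_model(), seed = 32)
  expect_equal(nrow(sr$reads), nrow(sr$truth))
  expect_true(all(sr$truth$provenance %in%
                    c("true_allele", "point_error", "chimera", "contaminant")))
})

test_that("no-noise reads reproduce the true alleles exactly", {
  truth <- simulate_population(15, n_alleles = c(5, 5), seed = 41)
  clean <- error_model(substitution_rate = 0, indel_rate = 0,
                       chimera_within = 0, chimera_between = 0,
                       contamination_rate = 0, coverage_mean = 40,
                       coverage_size = Inf)
  sr <- simulate_reads(truth, clean, seed = 42)
  expect_true(all(sr$truth$provenance == "true_allele"))
  derep <- dereplicate_reads(demultiplex_reads(sr$reads, sr$scheme, sr$configs))
  per_amp <- dplyr::count(derep, amplicon_id)
  expect_true(all(per_amp$n <= 2))
  pool_templates <- truth$pools$sequence
  expect_true(all(derep$sequence %in% pool_templates))
})

test_that("between-locus chimera rate and coverage overdispersion are realised", {
  truth <- simulate_population(60, n_alleles = c(8, 8), seed = 51)
  em <- error_model(substitution_rate = 0, indel_rate = 0, chimera_within = 0,
                    chimera_between = 0.22, contamination_rate = 0,
                    coverage_mean = 100, coverage_size = 0.85)
  sr <- simulate_reads(truth, em, seed = 52)
  frac <- mean(sr$truth$provenance == "chimera")
  se <- sqrt(0.22 * 0.78 / nrow(sr$truth))
  expect_lt(abs(frac - 0.22), 4 * se)
  depth <- dplyr::count(sr$truth, sample_id, locus)
  expect_gt(var(depth$n), 5 * mean(depth$n)) # variance far above Poisson
  # chimeric reads carry the locus-1 forward and locus-2 reverse primer
  dm <- demultiplex_reads(sr$reads, sr$scheme, sr$configs)
  chim_ids <- sr$truth$read_id[sr$truth$provenance == "chimera"]
  expect_true(all(chim_ids %in% dm$rejected$read_id))
  expect_true(all(dm$rejected$reason[dm$rejected$read_id %in% chim_ids] ==
                    "cross_locus_chimera"))
})

test_that("identical seeds give byte-identical read libraries", {
  truth <- simulate_population(10, n_alleles = c(4, 4), seed = 61)
  s1 <- simulate_reads(truth, error_model(), seed = 62)
  s2 <- simulate_reads(truth, error_model(), seed = 62)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  write_fasta(s1$reads, f1)
  write_fasta(s2$reads, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
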
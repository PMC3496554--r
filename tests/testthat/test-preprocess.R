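make_demo_library <- function(n = 12, seed = 71) {
  truth <- simulate_population(n, n_alleles = c(4, 4), seed = seed)
  sr <- simulate_reads(truth, error_model(coverage_mean = 40,
                                          coverage_size = Inf),
                       seed = seed + 1)
  list(truth = truth, sr = sr)
}

test_that("demultiplexing is orientation-invariant and conserves reads", {
  lib <- make_demo_library()
  sr <- lib$sr
  dm <- demultiplex_reads(sr$reads, sr$scheme, sr$configs)
  expect_equal(nrow(dm$assigned) + nrow(dm$rejected), nrow(sr$reads))

  flipped <- sr$reads
  flipped$sequence <- revcomp(flipped$sequence)
  dm2 <- demultiplex_reads(flipped, sr$scheme, sr$configs)
  a1 <- dplyr::arrange(dm$assigned, read_id)
  a2 <- dplyr::arrange(dm2$assigned, read_id)
  expect_identical(a1, a2)

  # assignment agrees with the simulator's truth labels
  joined <- dplyr::inner_join(dm$assigned, sr$truth, by = "read_id")
  expect_true(all(joined$sample_id.x == joined$sample_id.y))
  expect_true(all(joined$locus.x == joined$locus.y))
})

test_that("single primer mismatches and foreign tag pairs are rejected, not fatal", {
  lib <- make_demo_library(seed = 73)
  sr <- lib$sr
  r <- sr$reads[1:3, ]
  in_truth <- sr$truth[match(r$read_id, sr$truth$read_id), ]
  cfg <- sr$configs
  tagless <- paste0(
    sr$scheme$tag_fwd[match(in_truth$sample_id, sr$scheme$sample_id)],
    toupper(cfg$primer_fwd[match(in_truth$locus, cfg$locus)]),
    strrep("A", 150),
    revcomp(cfg$primer_rev[match(in_truth$locus, cfg$locus)]),
    revcomp(sr$scheme$tag_rev[match(in_truth$sample_id, sr$scheme$sample_id)])
  )
  ok <- tibble::tibble(read_id = paste0("ok", 1:3), sequence = tagless)
  broken <- ok
  substr(broken$sequence, 12, 12) <- "N" # primer mismatch
  dm_ok <- demultiplex_reads(ok, sr$scheme, cfg)
  dm_bad <- demultiplex_reads(broken, sr$scheme, cfg)
  expect_equal(nrow(dm_ok$assigned), 3)
  expect_equal(nrow(dm_bad$assigned), 0)
  expect_true(all(dm_bad$rejected$reason == "primer_mismatch"))

  # unknown unordered tag pair: swap in a tag absent from the scheme
  foreign <- ok
  substr(foreign$sequence, 1, 10) <- strrep("T", 10)
  dm_f <- demultiplex_reads(foreign, sr$scheme, cfg)
  expect_true(all(dm_f$rejected$reason == "unknown_tag_pair"))

  # reads pairing the locus-1 forward primer with the locus-2 reverse primer
  cross <- ok
  cross$sequence <- paste0(
    sr$scheme$tag_fwd[match(in_truth$sample_id, sr$scheme$sample_id)],
    cfg$primer_fwd[1],
    strrep("A", 150),
    revcomp(cfg$primer_rev[2]),
    revcomp(sr$scheme$tag_rev[match(in_truth$sample_id, sr$scheme$sample_id)])
  )
  dm_x <- demultiplex_reads(cross, sr$scheme, cfg)
  expect_true(all(dm_x$rejected$reason == "cross_locus_chimera"))
})

test_that("dereplication merges only perfectly identical reads", {
  reads <- tibble::tibble(
    read_id = paste0("r", 1:4),
    amplicon_id = "A:DRB", sample_id = "A", individual_id = "A",
    locus = "DRB", sequence = c("ACGT", "ACGT", "ACGT", "ACGA")
  )
  v <- dereplicate_reads(reads)
  expect_equal(nrow(v), 2)
  expect_equal(v$copy_count[v$sequence == "ACGT"], 3)
  expect_equal(v$copy_count[v$sequence == "ACGA"], 1)
  expect_true(all(v$total_reads == 4))
  empty <- dereplicate_reads(reads[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("copy and amplicon filters use strict 'less than' thresholds and are idempotent", {
  v <- make_variants(list(
    amp1 = c(AAAA = 10, CCCC = 5, GGGG = 4),
    amp2 = c(AAAA = 3, TTTT = 2),
    amp3 = c(AAAA = 30, CCCC = 12)
  ))
  f1 <- filter_min_copies(v, 5)
  expect_setequal(f1$sequence[f1$amplicon_id == "amp1:DRB"], c("AAAA", "CCCC"))
  expect_equal(unique(f1$total_reads[f1$amplicon_id == "amp1:DRB"]), 15)
  expect_false("amp2:DRB" %in% f1$amplicon_id)
  expect_equal(filter_log(f1)$emptied_amplicons, "amp2:DRB")
  strip <- function(x) { attr(x, "log") <- NULL; x }
  expect_identical(strip(filter_min_copies(f1, 5)), strip(f1))

  f2 <- filter_min_reads(f1, 18)
  expect_false("amp1:DRB" %in% f2$amplicon_id) # 15 < 18 discarded
  expect_true("amp3:DRB" %in% f2$amplicon_id)
  expect_identical(strip(filter_min_reads(f2, 18)), strip(f2))

  boundary <- make_variants(list(a = c(AAAA = 17), b = c(CCCC = 18)))
  fb <- filter_min_reads(filter_min_copies(boundary, 5), 18)
  expect_setequal(fb$sequence, "CCCC")
})

test_that("trimming to the common region merges variants that become identical", {
  cfg <- dplyr::bind_rows(
    locus_config("DRB", "AAAA", "TTTT", core_length = 6, trim_trail = 2),
    locus_config("DQB", "CCCC", "GGGG", core_length = 6, trim_lead = 2)
  )
  v <- dplyr::bind_rows(
    make_variants(list(a = c(ACGTACGG = 6, ACGTACTT = 7)), "DRB"),
    make_variants(list(b = c(GGACGTAC = 9)), "DQB")
  )
  tr <- trim_common_region(v, cfg)
  # DRB: both variants end up ACGTAC after removing 2 trailing bases -> merged
  drb <- tr[tr$locus == "DRB", ]
  expect_equal(nrow(drb), 1)
  expect_equal(drb$sequence, "ACGTAC")
  expect_equal(drb$copy_count, 13)
  dqb <- tr[tr$locus == "DQB", ]
  expect_equal(dqb$sequence, "ACGTAC")

  # zero trim is the identity
  cfg0 <- dplyr::bind_rows(
    locus_config("DRB", "AAAA", "TTTT", core_length = 8),
    locus_config("DQB", "CCCC", "GGGG", core_length = 8)
  )
  tr0 <- trim_common_region(v, cfg0)
  expect_setequal(tr0$sequence, c("ACGTACGG", "ACGTACTT", "GGACGTAC"))
})

test_that("minimum-coverage model matches closed forms and is monotone", {
  expect_equal(min_reads_required(1, 3, 0.95), 3)
  expect_equal(min_reads_required(2, 1, 0.95), 6) # 1 - 2*(1/2)^n >= 0.95
  expect_equal(min_reads_required(2, 3, 0.95), 12) # 1 - 2*P(Bin(n,1/2) <= 2)
  # closed-form check of the m = 2 case
  for (n in 6:14) {
    expect_equal(coverage_confidence(n, 2, 3),
                 1 - 2 * pbinom(2, n, 0.5), tolerance = 1e-12)
  }
  grid <- expand.grid(m = 1:3, r = 1:3, f = c(0.9, 0.95))
  vals <- mapply(min_reads_required, grid$m, grid$r, grid$f)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_gte(min_reads_required(g$m + 1, g$r, g$f), vals[i])
    expect_gte(min_reads_required(g$m, g$r + 1, g$f), vals[i])
    expect_gte(min_reads_required(g$m, g$r, g$f + 0.04), vals[i])
  }
  # unequal amplification probabilities need more reads
  expect_gte(min_reads_required(2, 3, 0.95, probs = c(0.8, 0.2)),
             min_reads_required(2, 3, 0.95))
  expect_error(min_reads_required(2, 3, 1), "confidence")
})
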
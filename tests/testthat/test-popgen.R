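test_that("allele frequencies, heterozygosity and Fis match hand calculations", {
  g <- tibble::tibble(individual_id = sprintf("I%02d", 1:10), locus = "L",
                      allele1 = "A", allele2 = "B")
  af <- allele_frequencies(g)
  expect_equal(sort(af$frequencies$frequency), c(0.5, 0.5))
  expect_equal(af$stats$ho, 1)
  he <- (20 / 19) * 0.5
  expect_equal(af$stats$he, he)
  expect_equal(af$stats$fis_naive, 1 - 1 / he)

  mono <- tibble::tibble(individual_id = c("a", "b"), locus = "L",
                         allele1 = "A", allele2 = "A")
  s <- allele_frequencies(mono)$stats
  expect_equal(s$he, 0)
  expect_true(is.na(s$fis_naive))
  expect_error(allele_frequencies(g, "missing_locus"), "no genotypes")
})

test_that("Fis is near zero across random-mating simulations", {
  set.seed(202)
  fis <- replicate(300, {
    g <- make_genotypes(80, 6)
    allele_frequencies(g)$stats$fis_wc
  })
  expect_lt(abs(mean(fis)), 0.02)
})

test_that("null-allele estimator follows the homozygote-excess closed form", {
  # Ho = He: estimate 0
  g <- make_genotypes(200, 8)
  af <- allele_frequencies(g)$stats
  nf <- null_allele_frequency(g)
  expect_equal(nf$null_freq, max(0, (af$he - af$ho) / (1 + af$he)))
  # all homozygotes at a locus with He = 0.5-ish
  g0 <- tibble::tibble(individual_id = sprintf("I%02d", 1:40), locus = "L",
                       allele1 = rep(c("A", "B"), 20),
                       allele2 = rep(c("A", "B"), 20))
  af0 <- allele_frequencies(g0)$stats
  expect_equal(null_allele_frequency(g0)$null_freq,
               (af0$he - 0) / (1 + af0$he))
})

test_that("null allele segregating at 0.10 is recovered by the estimator", {
  set.seed(77)
  ests <- replicate(60, {
    k <- 8
    al <- c(sprintf("A%02d", 1:k), "null")
    freqs <- c(rep(0.9 / k, k), 0.1)
    n <- 400
    a <- matrix(sample(al, 2 * n, replace = TRUE, prob = freqs), n, 2)
    # a null allele is invisible: null homozygotes drop out, null carriers
    # appear homozygous for their visible allele
    vis <- t(apply(a, 1, function(x) {
      if (all(x == "null")) c(NA, NA)
      else if (any(x == "null")) rep(x[x != "null"], 2)
      else x
    }))
    keep <- !is.na(vis[, 1])
    g <- tibble::tibble(individual_id = sprintf("I%04d", which(keep)),
                        locus = "L",
                        allele1 = pmin(vis[keep, 1], vis[keep, 2]),
                        allele2 = pmax(vis[keep, 1], vis[keep, 2]))
    null_allele_frequency(g)$null_freq
  })
  expect_lt(abs(mean(ests) - 0.10), 0.03)
})

test_that("heterozygote-excess U test is exact for two alleles and catches excess", {
  # exact Hardy-Weinberg proportions: p in the non-significant middle
  g <- tibble::tibble(
    individual_id = sprintf("I%03d", 1:40), locus = "L",
    allele1 = c(rep("A", 10), rep("A", 20), rep("B", 10)),
    allele2 = c(rep("A", 10), rep("B", 20), rep("B", 10))
  )
  ht <- hwe_excess_test(g, "L")
  expect_equal(ht$method, "exact_enumeration")
  expect_gt(ht$p, 0.2)
  expect_lt(ht$p, 0.9)

  # all heterozygotes with two equifrequent alleles: strong excess
  g2 <- tibble::tibble(individual_id = sprintf("I%03d", 1:50), locus = "L",
                       allele1 = "A", allele2 = "B")
  ht2 <- hwe_excess_test(g2, "L")
  expect_lt(ht2$p, 0.001)

  mono <- tibble::tibble(individual_id = c("x", "y"), locus = "L",
                         allele1 = "A", allele2 = "A")
  expect_equal(hwe_excess_test(mono, "L")$method, "not_applicable")

  # Monte Carlo p agrees with the conditional enumeration (Levene) oracle
  # on a biallelic configuration too large for the internal exact branch
  gl <- dplyr::bind_rows(g, dplyr::mutate(g, individual_id = paste0(individual_id, "b")))
  mc <- hwe_excess_test(gl, "L", n_resamples = 9999, seed = 3)
  n <- 80; nA <- 80; nB <- 80 # doubled 10 AA / 20 AB / 10 BB
  h_vals <- seq(nA %% 2, min(nA, nB), by = 2)
  logp <- lfactorial(n) - lfactorial((nA - h_vals) / 2) - lfactorial(h_vals) -
    lfactorial((nB - h_vals) / 2) + h_vals * log(2) -
    (lfactorial(2 * n) - lfactorial(nA) - lfactorial(nB))
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  p_oracle <- sum(pr[h_vals >= 40])
  expect_lt(abs(mc$p - p_oracle), 3 * sqrt(p_oracle * (1 - p_oracle) / 9999) + 1e-4)
})

test_that("EM haplotype estimation honours symmetry, marginals and likelihood ascent", {
  # both loci monomorphic: a single haplotype at frequency 1
  g <- dplyr::bind_rows(
    tibble::tibble(individual_id = c("a", "b"), locus = "L1",
                   allele1 = "A", allele2 = "A"),
    tibble::tibble(individual_id = c("a", "b"), locus = "L2",
                   allele1 = "X", allele2 = "X")
  )
  fit <- em_haplotypes(g, c("L1", "L2"))
  expect_equal(fit$haplotypes$frequency, 1)

  # a single double heterozygote: all four haplotypes at 0.25 by symmetry
  g2 <- dplyr::bind_rows(
    tibble::tibble(individual_id = "a", locus = "L1", allele1 = "A",
                   allele2 = "B"),
    tibble::tibble(individual_id = "a", locus = "L2", allele1 = "X",
                   allele2 = "Y")
  )
  fit2 <- em_haplotypes(g2, c("L1", "L2"))
  expect_equal(fit2$haplotypes$frequency, rep(0.25, 4))

  set.seed(9)
  g3 <- dplyr::bind_rows(make_genotypes(120, 4, "L1"),
                         make_genotypes(120, 4, "L2"))
  fit3 <- em_haplotypes(g3, c("L1", "L2"), trace = TRUE)
  expect_true(all(diff(fit3$loglik_trace) >= -1e-8))
  expect_gte(fit3$loglik, fit3$loglik_equilibrium)
  # haplotype marginals reconcile with single-locus frequencies
  marg <- tidy(fit3) |>
    dplyr::group_by(allele_1) |>
    dplyr::summarise(f = sum(frequency))
  af <- allele_frequencies(g3, "L1")$frequencies
  expect_equal(marg$f[match(af$allele_id, marg$allele_1)], af$frequency,
               tolerance = 1e-6)
  expect_equal(sum(tidy(fit3)$frequency), 1, tolerance = 1e-9)
})

test_that("LD permutation test has valid p-values and detects complete linkage", {
  set.seed(31)
  g <- dplyr::bind_rows(make_genotypes(60, 3, "L1"), make_genotypes(60, 3, "L2"))
  lt <- ld_test(g, c("L1", "L2"), n_permutations = 99, seed = 4)
  expect_gte(lt$lr, 0)
  expect_gt(lt$p, 0)
  expect_lte(lt$p, 1)

  # complete linkage: allele i at L1 always rides with allele i at L2
  n <- 100
  h <- sample(5, 2 * n, replace = TRUE)
  mk <- function(loc) {
    a <- matrix(sprintf("%s.A%02d", loc, h), n, 2)
    tibble::tibble(individual_id = sprintf("I%04d", 1:n), locus = loc,
                   allele1 = pmin(a[, 1], a[, 2]),
                   allele2 = pmax(a[, 1], a[, 2]))
  }
  gc <- dplyr::bind_rows(mk("L1"), mk("L2"))
  ltc <- ld_test(gc, c("L1", "L2"), n_permutations = 199, seed = 5)
  expect_equal(ltc$p, 1 / 200)
  expect_error(ld_test(gc, c("L1", "L2"), n_permutations = 0), "permutations")
})

test_that("rarefaction reaches the census count with zero SD and is monotone", {
  set.seed(41)
  g <- make_genotypes(90, 25, freqs = allele_spectrum(25, "geometric"))
  rc <- rarefaction_curve(g, "L1", step = 15, reps = 40, seed = 6)
  full <- rc[rc$sample_size == 90, ]
  observed <- dplyr::n_distinct(c(g$allele1, g$allele2))
  expect_equal(full$mean_alleles, observed)
  expect_equal(full$sd_alleles, 0)
  expect_true(all(diff(rc$mean_alleles) >= 0))
  expect_error(rarefaction_curve(g, "L1", step = 0), "step")
  expect_error(rarefaction_curve(g, "L1", max_n = 500), "max_n")
  p <- autoplot(rc)
  expect_s3_class(p, "ggplot")
})

test_that("stochastic popgen procedures are reproducible given a seed", {
  g <- dplyr::bind_rows(make_genotypes(50, 4, "L1"), make_genotypes(50, 4, "L2"))
  expect_identical(hwe_excess_test(g, "L1", 299, seed = 8),
                   hwe_excess_test(g, "L1", 299, seed = 8))
  expect_identical(glance(ld_test(g, c("L1", "L2"), 49, seed = 9)),
                   glance(ld_test(g, c("L1", "L2"), 49, seed = 9)))
  expect_identical(rarefaction_curve(g, "L1", step = 10, reps = 20, seed = 10),
                   rarefaction_curve(g, "L1", step = 10, reps = 20, seed = 10))
})
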
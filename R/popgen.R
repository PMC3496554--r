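## Extract one consensus genotype row per individual at one locus, as a
## two-column character matrix of alleles.
locus_matrix <- function(genotypes, locus) {
  g <- consensus_genotypes(genotypes)
  g <- g[g$locus == locus, ]
  if (nrow(g) == 0L) abort(paste0("no genotypes at locus ", locus))
  cbind(g$allele1, g$allele2)
}

#' Allele frequencies and heterozygosity at a locus
#'
#' Frequencies are taken from allele counts (two per individual).  Observed
#' heterozygosity Ho is the fraction of heterozygous individuals; expected
#' heterozygosity He is the unbiased small-sample estimator
#' `2n/(2n-1) * (1 - sum p^2)`.  Fis is reported both in the naive form
#' `1 - Ho/He` and as the Weir & Cockerham (1984) single-population
#' estimator.
#'
#' @param genotypes Genotype tibble (replicates are resolved to consensus).
#' @param locus Locus name; default all loci present.
#' @return List with `frequencies` (tibble `locus`, `allele_id`, `count`,
#'   `frequency`) and `stats` (tibble `locus`, `n`, `k`, `ho`, `he`,
#'   `fis_naive`, `fis_wc`; Fis is `NA` at a monomorphic locus).
#' @export
allele_frequencies <- function(genotypes, locus = NULL) {
  loci <- locus %||% unique(genotypes$locus)
  freqs <- list()
  stats <- list()
  for (loc in loci) {
    gm <- locus_matrix(genotypes, loc)
    n <- nrow(gm)
    alleles <- c(gm[, 1], gm[, 2])
    cnt <- sort(table(alleles), decreasing = TRUE)
    p <- as.numeric(cnt) / (2 * n)
    freqs[[loc]] <- tibble(locus = loc, allele_id = names(cnt),
                           count = as.integer(cnt), frequency = p)
    ho <- mean(gm[, 1] != gm[, 2])
    he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
    if (length(cnt) < 2L) {
      stats[[loc]] <- tibble(locus = loc, n = n, k = length(cnt),
                             ho = ho, he = 0, fis_naive = NA_real_,
                             fis_wc = NA_real_)
      next
    }
    ## Weir & Cockerham (1984) f for a single population: per-allele
    ## components b (between-individual) and c (within-individual).
    h_a <- vapply(names(cnt), function(a) {
      mean((gm[, 1] == a) != (gm[, 2] == a))
    }, numeric(1))
    pa <- as.numeric(cnt) / (2 * n)
    b <- (n / (n - 1)) * (pa * (1 - pa) - (2 * n - 1) / (4 * n) * h_a)
    cc <- h_a / 2
    fis_wc <- 1 - sum(cc) / sum(b + cc)
    stats[[loc]] <- tibble(locus = loc, n = n, k = length(cnt), ho = ho,
                           he = he, fis_naive = 1 - ho / he, fis_wc = fis_wc)
  }
  list(frequencies = list_rbind(freqs), stats = list_rbind(stats))
}

#' Null-allele frequency estimate from homozygote excess
#'
#' Brookfield (1996) equation 1: `(He - Ho) / (1 + He)`, floored at zero.
#' A null allele that systematically fails to amplify inflates apparent
#' homozygosity, so an excess of homozygotes over the Hardy-Weinberg
#' expectation estimates its frequency.
#'
#' @inheritParams allele_frequencies
#' @return Tibble `locus`, `null_freq` (`NA` at a monomorphic locus).
#' @export
null_allele_frequency <- function(genotypes, locus = NULL) {
  af <- allele_frequencies(genotypes, locus)
  af$stats |>
    mutate(null_freq = ifelse(.data$k < 2L, NA_real_,
                              pmax(0, (.data$he - .data$ho) / (1 + .data$he)))) |>
    select("locus", "null_freq")
}

## Heterozygote-excess U score (score statistic of the inbreeding model at
## f = 0, sign chosen so large values mean heterozygote excess); weights
## depend only on the allele counts, which resampling holds fixed.
u_score <- function(a1, a2, weight_by_allele) {
  het <- a1 != a2
  sum(het) - sum(weight_by_allele[a1[!het]])
}

#' Exact U-score test for heterozygote excess
#'
#' Tests Hardy-Weinberg equilibrium against the one-sided alternative of
#' heterozygote excess using the U score of Rousset & Raymond (1995).  The
#' null distribution conditions on the observed allele counts: for a
#' biallelic locus with up to 50 individuals it is enumerated exactly over
#' heterozygote counts (Levene's distribution); otherwise it is sampled by
#' Monte Carlo permutation of the 2n allele copies, with the p-value
#' computed as `(b + 1) / (m + 1)`.
#'
#' @inheritParams allele_frequencies
#' @param locus Locus name.
#' @param n_resamples Monte Carlo resamples.
#' @param seed Integer seed for the Monte Carlo null.
#' @return An `hwe_test` object: `U`, `p`, `method`, `n`, `k`,
#'   `n_resamples`.  A monomorphic locus gives `U = NA` with
#'   `method = "not_applicable"`.
#' @export
hwe_excess_test <- function(genotypes, locus, n_resamples = 999L, seed = NULL) {
  gm <- locus_matrix(genotypes, locus)
  n <- nrow(gm)
  alleles <- sort(unique(c(gm[, 1], gm[, 2])))
  k <- length(alleles)
  out <- structure(list(locus = locus, n = n, k = k, U = NA_real_,
                        p = NA_real_, method = "not_applicable",
                        n_resamples = 0L),
                   class = "hwe_test")
  if (k < 2L) return(out)
  a1 <- match(gm[, 1], alleles)
  a2 <- match(gm[, 2], alleles)
  cnt <- tabulate(c(a1, a2), k)
  p_a <- cnt / (2 * n)
  w <- (1 - p_a) / p_a
  u_obs <- u_score(a1, a2, w)
  out$U <- u_obs

  if (k == 2L && n <= 50L) {
    ## exact: conditional distribution of the heterozygote count h given
    ## allele counts (nA, nB); U is increasing in h
    nA <- cnt[1]; nB <- cnt[2]
    h_vals <- seq(nA %% 2L, min(nA, nB), by = 2L)
    logp <- lfactorial(n) - lfactorial((nA - h_vals) / 2) -
      lfactorial(h_vals) - lfactorial((nB - h_vals) / 2) +
      h_vals * log(2) - (lfactorial(2 * n) - lfactorial(nA) - lfactorial(nB))
    pr <- exp(logp - max(logp))
    pr <- pr / sum(pr)
    h_obs <- sum(a1 != a2)
    out$p <- sum(pr[h_vals >= h_obs])
    out$method <- "exact_enumeration"
    return(out)
  }
  pool <- c(a1, a2)
  b <- 0L
  with_seed_if(seed, {
    for (i in seq_len(n_resamples)) {
      perm <- sample(pool)
      x1 <- perm[seq_len(n)]
      x2 <- perm[n + seq_len(n)]
      if (u_score(x1, x2, w) >= u_obs) b <- b + 1L
    }
  })
  out$p <- (b + 1) / (n_resamples + 1)
  out$method <- "monte_carlo"
  out$n_resamples <- as.integer(n_resamples)
  out
}

#' @export
print.hwe_test <- function(x, ...) {
  cat("Heterozygote-excess U test (", x$locus, "): U = ",
      format(x$U, digits = 4), ", p = ", format(x$p, digits = 4),
      " [", x$method, "]\n", sep = "")
  invisible(x)
}

## ---- EM machinery for two-locus haplotype frequencies -------------------

## Encode two-locus genotypes: integer matrix with columns a1 <= a2 (locus 1
## allele indices) and b1 <= b2 (locus 2), plus class weights.
encode_two_locus <- function(genotypes, loci) {
  g <- consensus_genotypes(genotypes)
  g1 <- g[g$locus == loci[1], ]
  g2 <- g[g$locus == loci[2], ]
  both <- intersect(g1$individual_id, g2$individual_id)
  if (length(both) == 0L) abort("no individuals genotyped at both loci")
  g1 <- g1[match(both, g1$individual_id), ]
  g2 <- g2[match(both, g2$individual_id), ]
  al1 <- sort(unique(c(g1$allele1, g1$allele2)))
  al2 <- sort(unique(c(g2$allele1, g2$allele2)))
  list(
    a1 = match(g1$allele1, al1), a2 = match(g1$allele2, al1),
    b1 = match(g2$allele1, al2), b2 = match(g2$allele2, al2),
    alleles1 = al1, alleles2 = al2, n = length(both)
  )
}

## Aggregate encoded genotypes into distinct classes with weights.
aggregate_classes <- function(enc) {
  k1 <- length(enc$alleles1)
  k2 <- length(enc$alleles2)
  key <- ((enc$a1 - 1) * k1 + (enc$a2 - 1)) * k2 * k2 +
    (enc$b1 - 1) * k2 + (enc$b2 - 1)
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(a1 = enc$a1[u], a2 = enc$a2[u], b1 = enc$b1[u], b2 = enc$b2[u],
       w = as.numeric(tabulate(idx, sum(u))), k1 = k1, k2 = k2, n = enc$n)
}

## Linear indices into the k1 x k2 haplotype matrix for the four haplotype
## resolutions of each genotype class.
class_indices <- function(cl) {
  k1 <- cl$k1
  list(
    l11 = (cl$b1 - 1L) * k1 + cl$a1, l22 = (cl$b2 - 1L) * k1 + cl$a2,
    l12 = (cl$b2 - 1L) * k1 + cl$a1, l21 = (cl$b1 - 1L) * k1 + cl$a2,
    dh = cl$a1 != cl$a2 & cl$b1 != cl$b2,
    hom = cl$a1 == cl$a2 & cl$b1 == cl$b2
  )
}

## Log-likelihood of the aggregated classes under haplotype frequencies h
## (matrix or vector of length k1*k2).
two_locus_loglik <- function(cl, h, ix = class_indices(cl)) {
  hv <- as.vector(h)
  p <- ifelse(ix$dh,
              2 * hv[ix$l11] * hv[ix$l22] + 2 * hv[ix$l12] * hv[ix$l21],
              ifelse(ix$hom, hv[ix$l11]^2, 2 * hv[ix$l11] * hv[ix$l22]))
  sum(cl$w * log(pmax(p, .Machine$double.xmin)))
}

em_core <- function(cl, tol = 1e-6, max_iter = 1000L, trace = FALSE) {
  k1 <- cl$k1; k2 <- cl$k2; K <- k1 * k2
  ix <- class_indices(cl)
  ## start at the product of the marginal allele frequencies
  wi <- rep(seq_along(cl$w), cl$w)
  p1 <- tabulate(c(cl$a1[wi], cl$a2[wi]), k1)
  p2 <- tabulate(c(cl$b1[wi], cl$b2[wi]), k2)
  hv <- as.vector(outer(p1 / sum(p1), p2 / sum(p2)))
  una <- which(!ix$dh)
  amb <- which(ix$dh)
  base_cnt <- numeric(K)
  if (length(una) > 0L) {
    rs <- rowsum(c(cl$w[una], cl$w[una]), c(ix$l11[una], ix$l22[una]))
    base_cnt[as.integer(rownames(rs))] <- rs[, 1]
  }
  ll <- two_locus_loglik(cl, hv, ix)
  ll_trace <- ll
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    cnt <- base_cnt
    if (length(amb) > 0L) {
      r1 <- hv[ix$l11[amb]] * hv[ix$l22[amb]]
      r2 <- hv[ix$l12[amb]] * hv[ix$l21[amb]]
      tot <- r1 + r2
      q <- ifelse(tot > 0, r1 / tot, 0.5)
      wq <- cl$w[amb] * q
      wo <- cl$w[amb] * (1 - q)
      rs <- rowsum(c(wq, wq, wo, wo),
                   c(ix$l11[amb], ix$l22[amb], ix$l12[amb], ix$l21[amb]))
      at <- as.integer(rownames(rs))
      cnt[at] <- cnt[at] + rs[, 1]
    }
    hv_new <- cnt / (2 * cl$n)
    delta <- max(abs(hv_new - hv))
    hv <- hv_new
    ll <- two_locus_loglik(cl, hv, ix)
    if (trace) ll_trace <- c(ll_trace, ll)
    if (delta < tol) { converged <- TRUE; break }
  }
  list(h = matrix(hv, k1, k2), loglik = ll, iterations = iter,
       converged = converged, loglik_trace = if (trace) ll_trace else NULL)
}

#' EM estimation of two-locus haplotype frequencies
#'
#' Maximum-likelihood haplotype frequencies from unphased two-locus
#' genotypes via expectation-maximisation: double heterozygotes are split
#' between their two phase resolutions in proportion to the current
#' haplotype frequencies.  Starting from the product of the single-locus
#' allele frequencies, the log-likelihood is non-decreasing at every
#' iteration and the haplotype marginals stay equal to the observed allele
#' frequencies.
#'
#' @param genotypes Genotype tibble covering two loci.
#' @param loci Character vector of the two locus names; default the first
#'   two in the data.
#' @param tol Convergence tolerance on the largest frequency change.
#' @param max_iter Iteration cap.
#' @param trace Keep the per-iteration log-likelihood.
#' @return A `haplotype_em` object: `haplotypes` (tibble `allele_1`,
#'   `allele_2`, `frequency`), `loglik`, `loglik_equilibrium`, `iterations`,
#'   `converged`, `n`.
#' @export
em_haplotypes <- function(genotypes, loci = NULL, tol = 1e-6,
                          max_iter = 1000L, trace = FALSE) {
  loci <- loci %||% unique(genotypes$locus)[1:2]
  enc <- encode_two_locus(genotypes, loci)
  cl <- aggregate_classes(enc)
  fit <- em_core(cl, tol = tol, max_iter = max_iter, trace = trace)
  p1 <- tabulate(c(cl$a1[rep(seq_along(cl$w), cl$w)],
                   cl$a2[rep(seq_along(cl$w), cl$w)]), cl$k1)
  p2 <- tabulate(c(cl$b1[rep(seq_along(cl$w), cl$w)],
                   cl$b2[rep(seq_along(cl$w), cl$w)]), cl$k2)
  h0 <- outer(p1 / sum(p1), p2 / sum(p2))
  structure(list(
    haplotypes = tibble(
      allele_1 = rep(enc$alleles1, times = cl$k2),
      allele_2 = rep(enc$alleles2, each = cl$k1),
      frequency = as.vector(fit$h)
    ),
    loci = loci, loglik = fit$loglik,
    loglik_equilibrium = two_locus_loglik(cl, h0),
    iterations = fit$iterations, converged = fit$converged,
    loglik_trace = fit$loglik_trace, n = cl$n
  ), class = "haplotype_em")
}

#' @export
print.haplotype_em <- function(x, ...) {
  cat("<haplotype_em> ", x$n, " individuals, logLik ",
      format(x$loglik, digits = 6), " (equilibrium ",
      format(x$loglik_equilibrium, digits = 6), "), ",
      x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' Likelihood-ratio permutation test of linkage disequilibrium
#'
#' Compares the likelihood of the two-locus sample when association between
#' loci is allowed (EM haplotype frequencies) with the likelihood under
#' linkage equilibrium (haplotype frequencies equal to products of
#' single-locus allele frequencies).  The null distribution of
#' `LR = 2 (lnL_assoc - lnL_equilibrium)` is generated by shuffling one
#' locus's genotypes across individuals; the p-value uses the `(b+1)/(m+1)`
#' correction.  No chi-squared reference distribution is asserted.
#'
#' @inheritParams em_haplotypes
#' @param n_permutations Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return An `ld_test` object: `lr`, `p`, `n_permutations`, `fit` (the
#'   observed `haplotype_em`).
#' @export
ld_test <- function(genotypes, loci = NULL, n_permutations = 1000L,
                    seed = NULL, tol = 1e-6, max_iter = 1000L) {
  if (n_permutations < 1L) abort("n_permutations must be >= 1")
  loci <- loci %||% unique(genotypes$locus)[1:2]
  enc <- encode_two_locus(genotypes, loci)
  if (length(enc$alleles1) < 2L || length(enc$alleles2) < 2L) {
    abort("both loci must have at least 2 alleles")
  }
  fit_of <- function(e) {
    cl <- aggregate_classes(e)
    fit <- em_core(cl, tol = tol, max_iter = max_iter)
    p1 <- tabulate(c(e$a1, e$a2), cl$k1)
    p2 <- tabulate(c(e$b1, e$b2), cl$k2)
    h0 <- outer(p1 / sum(p1), p2 / sum(p2))
    ll0 <- two_locus_loglik(cl, h0)
    list(fit = fit, ll0 = ll0, lr = 2 * (fit$loglik - ll0))
  }
  obs <- fit_of(enc)
  lr_obs <- max(0, obs$lr)
  b <- 0L
  with_seed_if(seed, {
    for (i in seq_len(n_permutations)) {
      idx <- sample.int(enc$n)
      ep <- enc
      ep$b1 <- enc$b1[idx]
      ep$b2 <- enc$b2[idx]
      if (max(0, fit_of(ep)$lr) >= lr_obs) b <- b + 1L
    }
  })
  fit_obs <- structure(list(
    haplotypes = tibble(
      allele_1 = rep(enc$alleles1, times = length(enc$alleles2)),
      allele_2 = rep(enc$alleles2, each = length(enc$alleles1)),
      frequency = as.vector(obs$fit$h)
    ),
    loci = loci, loglik = obs$fit$loglik, loglik_equilibrium = obs$ll0,
    iterations = obs$fit$iterations, converged = obs$fit$converged,
    loglik_trace = NULL, n = enc$n
  ), class = "haplotype_em")
  structure(list(lr = lr_obs, p = (b + 1) / (n_permutations + 1),
                 n_permutations = as.integer(n_permutations),
                 loci = loci, fit = fit_obs),
            class = "ld_test")
}

#' @export
print.ld_test <- function(x, ...) {
  cat("LD likelihood-ratio permutation test (", paste(x$loci, collapse = " x "),
      "): LR = ", format(x$lr, digits = 5), ", p = ",
      format(x$p, digits = 4), " (", x$n_permutations, " permutations)\n",
      sep = "")
  invisible(x)
}

#' Rarefaction of allelic richness
#'
#' Samples individuals without replacement at increasing sample sizes and
#' counts the distinct alleles detected, replicating each sampling effort to
#' obtain a mean and SD; the curve's approach to an asymptote indicates how
#' much of the population's allelic richness the census has captured.
#' `expected_allelic_richness()` gives the exact expectation of the same
#' quantity in closed form (hypergeometric over individuals by default, or
#' over the 2N gene copies).
#'
#' @param genotypes Genotype tibble.
#' @param locus Locus name.
#' @param step Increment between sample sizes (default 20 individuals).
#' @param max_n Largest sample size; default the full census.
#' @param reps Replicates per sampling effort (default 100).
#' @param seed Integer seed.
#' @return A `rarefaction_curve` tibble: `locus`, `sample_size`,
#'   `mean_alleles`, `sd_alleles`, `reps`.
#' @export
rarefaction_curve <- function(genotypes, locus, step = 20L, max_n = NULL,
                              reps = 100L, seed = NULL) {
  if (step <= 0L) abort("step must be positive")
  gm <- locus_matrix(genotypes, locus)
  n <- nrow(gm)
  max_n <- max_n %||% n
  if (max_n > n) abort("max_n exceeds the number of genotyped individuals")
  sizes <- unique(c(seq(min(step, max_n), max_n, by = step), max_n))
  out <- with_seed_if(seed, {
    purrr::map(sizes, function(s) {
      counts <- vapply(seq_len(reps), function(r) {
        idx <- sample.int(n, s)
        length(unique(c(gm[idx, 1], gm[idx, 2])))
      }, numeric(1))
      tibble(locus = locus, sample_size = s,
             mean_alleles = mean(counts), sd_alleles = sd(counts),
             reps = as.integer(reps))
    }) |> list_rbind()
  })
  class(out) <- c("rarefaction_curve", class(out))
  out
}

#' @rdname rarefaction_curve
#' @param sample_sizes Sizes at which to evaluate the expectation.
#' @param unit `"individuals"` (exact for the resampling design of
#'   [rarefaction_curve()]) or `"genes"` (classic rarefaction over 2N gene
#'   copies).
#' @export
expected_allelic_richness <- function(genotypes, locus, sample_sizes,
                                      unit = c("individuals", "genes")) {
  unit <- match.arg(unit)
  gm <- locus_matrix(genotypes, locus)
  n <- nrow(gm)
  alleles <- unique(c(gm[, 1], gm[, 2]))
  expect <- vapply(sample_sizes, function(s) {
    if (unit == "individuals") {
      carriers <- vapply(alleles, function(a) {
        sum(gm[, 1] == a | gm[, 2] == a)
      }, numeric(1))
      sum(1 - exp(lchoose(n - carriers, s) - lchoose(n, s)))
    } else {
      cnt <- vapply(alleles, function(a) {
        sum(gm[, 1] == a) + sum(gm[, 2] == a)
      }, numeric(1))
      sum(1 - exp(lchoose(2 * n - cnt, 2 * s) - lchoose(2 * n, 2 * s)))
    }
  }, numeric(1))
  tibble(locus = locus, sample_size = sample_sizes,
         expected_alleles = expect, unit = unit)
}
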
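#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for test and fit objects
#'
#' Broom-style methods: `tidy()` returns the per-component table of an
#' object (haplotype frequencies for an EM fit), `glance()` a one-row model
#' summary.
#'
#' @param x An `hwe_test`, `ld_test` or `haplotype_em` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.hwe_test <- function(x, ...) {
  tibble(locus = x$locus, statistic = x$U, p.value = x$p, method = x$method,
         n = x$n, k = x$k)
}

#' @rdname tidiers
#' @export
glance.hwe_test <- function(x, ...) tidy(x)

#' @rdname tidiers
#' @export
tidy.ld_test <- function(x, ...) {
  tibble(loci = paste(x$loci, collapse = ":"), statistic = x$lr,
         p.value = x$p, n_permutations = x$n_permutations)
}

#' @rdname tidiers
#' @export
glance.ld_test <- function(x, ...) {
  tibble(statistic = x$lr, p.value = x$p,
         logLik = x$fit$loglik, logLik_equilibrium = x$fit$loglik_equilibrium,
         n = x$fit$n, n_permutations = x$n_permutations)
}

#' @rdname tidiers
#' @export
tidy.haplotype_em <- function(x, ...) {
  x$haplotypes |> arrange(desc(.data$frequency))
}

#' @rdname tidiers
#' @export
glance.haplotype_em <- function(x, ...) {
  tibble(logLik = x$loglik, logLik_equilibrium = x$loglik_equilibrium,
         iterations = x$iterations, converged = x$converged, n = x$n)
}
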
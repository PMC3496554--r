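codon_aa <- function(codon) {
  tab <- get_genetic_code()
  unname(tab[codon])
}

get_genetic_code <- function() {
  if (is.null(.ng_env$code)) .ng_env$code <- Biostrings::GENETIC_CODE
  .ng_env$code
}

.ng_env <- new.env(parent = emptyenv())

#' Jukes-Cantor correction of a proportion of differences
#'
#' `d = -(3/4) * log(1 - (4/3) * p)`; undefined (`NA`) for `p >= 0.75`.
#'
#' @param p Proportion of differing sites.
#' @return Corrected distance; monotone in `p` and approaching `p` as
#'   `p -> 0`.
#' @export
jc_correct <- function(p) {
  out <- p
  out[] <- NA_real_
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  out
}

#' Pairwise distances among aligned sequences
#'
#' p-distances (mismatch proportion over pairwise-comparable sites) with
#' optional Jukes-Cantor correction for nucleotide data.  Sites where either
#' sequence carries a gap or an ambiguous symbol are deleted pairwise.
#'
#' @param alignment Named character vector or tibble (`allele_id`,
#'   `sequence`) of equal-length sequences.
#' @param level `"nucleotide"` or `"amino_acid"`.
#' @param model `"p"` or `"jukes_cantor"` (nucleotide only).
#' @return Symmetric distance matrix with zero diagonal; `NA` where the
#'   Jukes-Cantor correction is undefined (p >= 0.75).
#' @export
pairwise_distances <- function(alignment, level = c("nucleotide", "amino_acid"),
                               model = c("p", "jukes_cantor")) {
  level <- match.arg(level)
  model <- match.arg(model)
  if (level == "amino_acid" && model == "jukes_cantor") {
    abort("the Jukes-Cantor correction applies to nucleotide distances")
  }
  seqs <- as_alignment(alignment)
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  valid <- if (level == "nucleotide") {
    matrix(chars %in% DNA_BASES, nrow = nrow(chars))
  } else {
    matrix(chars %in% LETTERS & chars != "X", nrow = nrow(chars))
  }
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- valid[i, ] & valid[j, ]
      if (!any(ok)) { d[i, j] <- d[j, i] <- NA_real_; next }
      p <- mean(chars[i, ok] != chars[j, ok])
      val <- if (model == "jukes_cantor") jc_correct(p) else p
      d[i, j] <- d[j, i] <- val
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbour joining (via [ape::nj()]); for two taxa the
#' single separating path of length `d` is returned as two half-length
#' branches around one internal node.
#'
#' @param d Symmetric distance matrix with labelled rows and columns.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    abort("distance matrix must be symmetric")
  }
  if (any(is.na(d))) abort("distance matrix contains undefined entries")
  n <- nrow(d)
  if (n < 2L) abort("need at least two taxa")
  if (n == 2L) {
    tr <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
               edge.length = rep(d[1, 2] / 2, 2),
               tip.label = rownames(d), Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  ape::nj(stats::as.dist(d))
}

#' Bootstrap support for a neighbour-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate and reports, for each internal edge of the full-data tree,
#' the percentage of replicates containing the same bipartition.  Sequences
#' are ordered by label internally, so supports do not depend on input
#' order.
#'
#' @inheritParams pairwise_distances
#' @param reps Bootstrap replicates (default 500).
#' @param seed Integer seed.
#' @param model Distance model passed to [pairwise_distances()].
#' @return The full-data `phylo` tree with `node.label` set to percentage
#'   supports (the root node label is `NA`).
#' @export
bootstrap_support <- function(alignment, reps = 500L, seed = NULL,
                              model = "jukes_cantor") {
  if (reps < 1L) abort("reps must be >= 1")
  seqs <- as_alignment(alignment)
  seqs <- seqs[order(names(seqs))]
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(chars) <- names(seqs)
  build <- function(x) {
    aln <- setNames(apply(x, 1, paste, collapse = ""), rownames(x))
    nj_tree(pairwise_distances(aln, "nucleotide", model))
  }
  full <- build(chars)
  counts <- with_seed_if(seed, {
    ape::boot.phylo(full, chars, build, B = reps, quiet = TRUE,
                    trees = FALSE)
  })
  supp <- round(100 * counts / reps, 1)
  supp[1] <- NA # root of the unrooted representation carries no bipartition
  full$node.label <- supp
  full
}

#' Variability summary of an alignment
#'
#' @inheritParams pairwise_distances
#' @return Tibble: `n_sites`, `variable_sites` (columns with at least two
#'   states among non-gap symbols), `prop_variable`, `mean_pairwise_diff`,
#'   `sd_pairwise_diff` (counts of differing comparable sites per pair).
#' @export
variability_summary <- function(alignment, level = c("nucleotide", "amino_acid")) {
  level <- match.arg(level)
  seqs <- as_alignment(alignment)
  chars <- do.call(rbind, strsplit(toupper(seqs), ""))
  valid <- if (level == "nucleotide") {
    matrix(chars %in% DNA_BASES, nrow = nrow(chars))
  } else {
    matrix(chars %in% LETTERS & chars != "X", nrow = nrow(chars))
  }
  n_var <- sum(vapply(seq_len(ncol(chars)), function(j) {
    states <- unique(chars[valid[, j], j])
    length(states) >= 2L
  }, logical(1)))
  n <- length(seqs)
  diffs <- c()
  if (n >= 2L) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ok <- valid[i, ] & valid[j, ]
        diffs <- c(diffs, sum(chars[i, ok] != chars[j, ok]))
      }
    }
  }
  tibble(
    n_sequences = n, n_sites = ncol(chars), variable_sites = n_var,
    prop_variable = n_var / ncol(chars),
    mean_pairwise_diff = if (length(diffs)) mean(diffs) else NA_real_,
    sd_pairwise_diff = if (length(diffs) > 1) sd(diffs) else NA_real_
  )
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' For each codon position, the fraction of the three possible single-base
#' changes that are synonymous, with changes to termination codons excluded
#' from the denominator; the synonymous site count `s` sums these fractions
#' and the nonsynonymous count is `n = 3 - s`.
#'
#' @param codon A sense codon (3 letters, standard genetic code).
#' @return Named numeric vector `c(s = , n = )`.
#' @export
count_syn_nonsyn_sites <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon)) {
    abort("codon must be 3 bases of A/C/G/T")
  }
  if (is_stop_codon(codon)) abort("site counting is undefined for stop codons")
  aa0 <- codon_aa(codon)
  s <- 0
  x <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    syn <- 0L
    tot <- 0L
    for (b in setdiff(DNA_BASES, x[pos])) {
      y <- x
      y[pos] <- b
      mut <- paste(y, collapse = "")
      if (is_stop_codon(mut)) next
      tot <- tot + 1L
      if (codon_aa(mut) == aa0) syn <- syn + 1L
    }
    if (tot > 0L) s <- s + syn / tot
  }
  c(s = s, n = 3 - s)
}

## Pathway-averaged (Sd, Nd) between two sense codons: all orderings of the
## differing positions are equally probable, orderings passing through a
## stop codon are excluded (if every ordering is blocked, all are used).
codon_pair_changes <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  x1 <- strsplit(c1, "")[[1]]
  x2 <- strsplit(c2, "")[[1]]
  pos <- which(x1 != x2)
  perms <- if (length(pos) == 1L) {
    list(pos)
  } else if (length(pos) == 2L) {
    list(pos, rev(pos))
  } else {
    list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
         pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
  }
  walk <- function(ord) {
    cur <- x1
    s <- 0L; n <- 0L
    for (p in ord) {
      nxt <- cur
      nxt[p] <- x2[p]
      ncod <- paste(nxt, collapse = "")
      if (is_stop_codon(ncod)) return(NULL)
      if (codon_aa(paste(cur, collapse = "")) == codon_aa(ncod)) {
        s <- s + 1L
      } else {
        n <- n + 1L
      }
      cur <- nxt
    }
    c(s, n)
  }
  res <- purrr::compact(lapply(perms, walk))
  if (length(res) == 0L) { # every pathway blocked by a stop: keep all
    res <- lapply(perms, function(ord) {
      cur <- x1; s <- 0L; n <- 0L
      for (p in ord) {
        nxt <- cur
        nxt[p] <- x2[p]
        if (codon_aa(paste(cur, collapse = "")) ==
              codon_aa(paste(nxt, collapse = ""))) s <- s + 1L else n <- n + 1L
        cur <- nxt
      }
      c(s, n)
    })
  }
  m <- do.call(rbind, res)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

## Lazily built lookup tables over the 64 codons: per-codon site counts and
## per-ordered-pair pathway change counts.
ng_tables <- function() {
  if (!is.null(.ng_env$tables)) return(.ng_env$tables)
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES)[, 3:1], 1,
                  paste, collapse = "")
  sense <- codons[!is_stop_codon(codons)]
  s_sites <- setNames(rep(NA_real_, length(codons)), codons)
  for (cod in sense) s_sites[cod] <- count_syn_nonsyn_sites(cod)[["s"]]
  nc <- length(codons)
  sd_tab <- matrix(NA_real_, nc, nc, dimnames = list(codons, codons))
  nd_tab <- sd_tab
  for (a in sense) {
    for (b in sense) {
      ch <- codon_pair_changes(a, b)
      sd_tab[a, b] <- ch[["sd"]]
      nd_tab[a, b] <- ch[["nd"]]
    }
  }
  .ng_env$tables <- list(s_sites = s_sites, sd = sd_tab, nd = nd_tab)
  .ng_env$tables
}

## Per-codon (sd, nd, s, n) contributions for one aligned sequence pair.
## Codons containing gaps/ambiguity or stop codons are NA (skipped pairwise).
ng_pair_profile <- function(codonsA, codonsB) {
  tab <- ng_tables()
  ok <- !grepl("[^ACGT]", codonsA) & !grepl("[^ACGT]", codonsB) &
    !is_stop_codon(codonsA) & !is_stop_codon(codonsB)
  k <- length(codonsA)
  out <- matrix(NA_real_, k, 4, dimnames = list(NULL, c("sd", "nd", "s", "n")))
  if (any(ok)) {
    ia <- codonsA[ok]
    ib <- codonsB[ok]
    out[ok, "sd"] <- tab$sd[cbind(ia, ib)]
    out[ok, "nd"] <- tab$nd[cbind(ia, ib)]
    out[ok, "s"] <- (tab$s_sites[ia] + tab$s_sites[ib]) / 2
    out[ok, "n"] <- 3 - out[ok, "s"]
  }
  out
}

#' Nei-Gojobori pathway counts and distances for one sequence pair
#'
#' Counts synonymous (`Sd`) and nonsynonymous (`Nd`) differences by
#' averaging over all equally probable stop-free orderings of the changes
#' within each differing codon, together with the synonymous (`S`) and
#' nonsynonymous (`N`) site totals averaged over the two sequences, the
#' proportions `pS = Sd/S`, `pN = Nd/N`, and their Jukes-Cantor corrections
#' `dS`, `dN` (undefined when the proportion reaches 3/4).
#'
#' @param seq_a,seq_b In-frame aligned nucleotide sequences of equal length;
#'   codons containing gaps or ambiguity codes are skipped pairwise.
#' @return Named numeric vector `Sd, Nd, S, N, pS, pN, dS, dN`.
#' @export
nei_gojobori_pair <- function(seq_a, seq_b) {
  ca <- split_codons(toupper(seq_a))
  cb <- split_codons(toupper(seq_b))
  if (length(ca) != length(cb)) abort("sequences must have equal length")
  prof <- ng_pair_profile(ca, cb)
  ok <- !is.na(prof[, "sd"])
  Sd <- sum(prof[ok, "sd"]); Nd <- sum(prof[ok, "nd"])
  S <- sum(prof[ok, "s"]); N <- sum(prof[ok, "n"])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  c(Sd = Sd, Nd = Nd, S = S, N = N, pS = pS, pN = pN,
    dS = jc_correct(pS), dN = jc_correct(pN))
}

#' Codon site partitions for selection tests
#'
#' Builds the partition list used by [selection_test()]: antigen-binding
#' sites (ABS) versus non-ABS, positively selected sites (PSS, supplied as
#' input from codon-model inference) versus non-PSS, and all codons.
#'
#' @param n_codons Number of codons in the alignment.
#' @param abs_codons,pss_codons 1-based codon positions.
#' @return Named list of codon index vectors.
#' @export
site_partition <- function(n_codons, abs_codons = integer(0),
                           pss_codons = integer(0)) {
  all_cod <- seq_len(n_codons)
  stopifnot(all(abs_codons %in% all_cod), all(pss_codons %in% all_cod))
  out <- list(all = all_cod)
  if (length(abs_codons)) {
    out$ABS <- sort(unique(abs_codons))
    out$non_ABS <- setdiff(all_cod, abs_codons)
  }
  if (length(pss_codons)) {
    out$PSS <- sort(unique(pss_codons))
    out$non_PSS <- setdiff(all_cod, pss_codons)
  }
  out
}

#' Z-test of selection on codon partitions
#'
#' For each codon partition, computes the mean pairwise `dN` and `dS`
#' (Nei-Gojobori pathway counts with Jukes-Cantor correction) restricted to
#' the partition's codons, their standard errors by codon bootstrap, the
#' ratio `omega = dN/dS` (reported as `NA` when `dS = 0`), and
#' `Z = (dN - dS) / sqrt(Var(dN) + Var(dS))` with a normal p-value.
#'
#' @param alignment In-frame nucleotide alignment (named character vector or
#'   tibble).
#' @param partitions Named list of codon index vectors (see
#'   [site_partition()]); default a single `all` partition.
#' @param reps Codon-bootstrap replicates for the standard errors.
#' @param seed Integer seed for the bootstrap.
#' @param alternative `"two.sided"` (are dN and dS similar) or `"greater"`
#'   (positive selection, dN > dS).
#' @return Tibble: `partition`, `n_codons`, `dn`, `dn_se`, `ds`, `ds_se`,
#'   `omega`, `z`, `p`.  Partitions with no codons are skipped with a
#'   warning.
#' @export
selection_test <- function(alignment, partitions = NULL, reps = 1000L,
                           seed = NULL,
                           alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  seqs <- as_alignment(alignment)
  if (length(seqs) < 2L) abort("need at least 2 sequences")
  codons <- lapply(seqs, function(s) split_codons(toupper(s)))
  k <- length(codons[[1]])
  partitions <- partitions %||% list(all = seq_len(k))
  n <- length(seqs)
  pairs <- utils::combn(n, 2)

  ## per-pair per-codon contribution arrays
  profs <- lapply(seq_len(ncol(pairs)), function(j) {
    ng_pair_profile(codons[[pairs[1, j]]], codons[[pairs[2, j]]])
  })
  arr <- function(comp) {
    do.call(rbind, lapply(profs, function(p) p[, comp]))
  }
  SDm <- arr("sd"); NDm <- arr("nd"); Sm <- arr("s"); Nm <- arr("n")

  mean_d <- function(cols, weights = NULL) {
    ## weights: codon multiplicities (bootstrap); NULL = observed
    wsum <- function(M) {
      sub <- M[, cols, drop = FALSE]
      if (is.null(weights)) {
        rowSums(sub, na.rm = TRUE)
      } else {
        as.vector(ifelse(is.na(sub), 0, sub) %*% weights)
      }
    }
    Sd <- wsum(SDm); Nd <- wsum(NDm); S <- wsum(Sm); N <- wsum(Nm)
    dS <- jc_correct(ifelse(S > 0, Sd / S, NA_real_))
    dN <- jc_correct(ifelse(N > 0, Nd / N, NA_real_))
    c(dn = mean(dN, na.rm = TRUE), ds = mean(dS, na.rm = TRUE))
  }

  with_seed_if(seed, {
    purrr::imap(partitions, function(cols, name) {
      if (length(cols) == 0L) {
        warn(paste0("partition '", name, "' has no codons; skipped"))
        return(NULL)
      }
      obs <- mean_d(cols)
      boot <- matrix(NA_real_, reps, 2)
      w <- rmultinom(reps, length(cols), rep(1 / length(cols), length(cols)))
      for (r in seq_len(reps)) {
        boot[r, ] <- mean_d(cols, weights = w[, r])
      }
      dn_se <- sd(boot[, 1], na.rm = TRUE)
      ds_se <- sd(boot[, 2], na.rm = TRUE)
      z <- (obs[["dn"]] - obs[["ds"]]) / sqrt(dn_se^2 + ds_se^2)
      p <- switch(alternative,
        two.sided = 2 * pnorm(-abs(z)),
        greater = pnorm(z, lower.tail = FALSE)
      )
      tibble(
        partition = name, n_codons = length(cols),
        dn = obs[["dn"]], dn_se = dn_se, ds = obs[["ds"]], ds_se = ds_se,
        omega = ifelse(obs[["ds"]] > 0, obs[["dn"]] / obs[["ds"]], NA_real_),
        z = z, p = p
      )
    }) |> purrr::compact() |> list_rbind()
  })
}
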
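# Independent oracles and small fixture builders, written without reusing the
# package's internal machinery.

ORACLE_CODE <- Biostrings::GENETIC_CODE
ORACLE_STOPS <- names(ORACLE_CODE)[ORACLE_CODE == "*"]

oracle_aa <- function(codon) unname(ORACLE_CODE[codon])

# Exhaustive 9-change enumeration of synonymous/nonsynonymous sites.
oracle_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  x <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0
    denom <- 0
    for (b in setdiff(bases, x[pos])) {
      y <- x
      y[pos] <- b
      mut <- paste(y, collapse = "")
      if (mut %in% ORACLE_STOPS) next
      denom <- denom + 1
      if (oracle_aa(mut) == oracle_aa(codon)) syn <- syn + 1
    }
    if (denom > 0) s <- s + syn / denom
  }
  c(s = s, n = 3 - s)
}

# All permutations of a vector, recursively.
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# Pathway-enumeration count of synonymous/nonsynonymous differences between
# two sense codons; stop-blocked orderings excluded (all used if every one
# is blocked).
oracle_codon_changes <- function(c1, c2) {
  x1 <- strsplit(c1, "")[[1]]
  x2 <- strsplit(c2, "")[[1]]
  pos <- which(x1 != x2)
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  paths <- list()
  blocked <- list()
  for (ord in oracle_perms(pos)) {
    cur <- x1
    sy <- 0
    ns <- 0
    hit_stop <- FALSE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- x2[p]
      if (paste(nxt, collapse = "") %in% ORACLE_STOPS) hit_stop <- TRUE
      if (oracle_aa(paste(cur, collapse = "")) ==
            oracle_aa(paste(nxt, collapse = ""))) sy <- sy + 1 else ns <- ns + 1
      cur <- nxt
    }
    rec <- c(sy, ns)
    if (hit_stop) blocked <- c(blocked, list(rec)) else
      paths <- c(paths, list(rec))
  }
  if (length(paths) == 0) paths <- blocked
  m <- do.call(rbind, paths)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# Full Nei-Gojobori pair oracle (counts only, no correction).
oracle_ng_pair <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  Sd <- 0; Nd <- 0; S <- 0; N <- 0
  for (i in seq_along(ca)) {
    ch <- oracle_codon_changes(ca[i], cb[i])
    Sd <- Sd + ch[["sd"]]
    Nd <- Nd + ch[["nd"]]
    sa <- oracle_sites(ca[i])[["s"]]
    sb <- oracle_sites(cb[i])[["s"]]
    S <- S + (sa + sb) / 2
    N <- N + 3 - (sa + sb) / 2
  }
  c(Sd = Sd, Nd = Nd, S = S, N = N)
}

SENSE_CODONS <- names(ORACLE_CODE)[ORACLE_CODE != "*"]

random_coding_seq <- function(n_codons) {
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

# A mutated copy of a coding sequence that stays stop-free.
mutate_coding_seq <- function(seq, n_mut) {
  x <- strsplit(seq, "")[[1]]
  for (i in seq_len(n_mut)) {
    repeat {
      p <- sample(length(x), 1)
      old <- x[p]
      x[p] <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      cod <- ((p - 1) %/% 3) * 3 + 1
      if (!(paste(x[cod:(cod + 2)], collapse = "") %in% ORACLE_STOPS)) break
      x[p] <- old
    }
  }
  paste(x, collapse = "")
}

# Random-mating genotype table at one locus.
make_genotypes <- function(n, k, locus = "L1", freqs = NULL,
                           ids = sprintf("I%04d", seq_len(n))) {
  freqs <- if (is.null(freqs)) rep(1 / k, k) else freqs
  al <- sprintf("%s.A%02d", locus, seq_len(k))
  a <- matrix(sample(al, 2 * n, replace = TRUE, prob = freqs), n, 2)
  tibble::tibble(individual_id = ids, locus = locus,
                 allele1 = pmin(a[, 1], a[, 2]), allele2 = pmax(a[, 1], a[, 2]))
}

# Variant tibble builder for validation/genotyping unit tests: `spec` is a
# list of amplicons, each a named numeric vector of copy counts by sequence.
make_variants <- function(spec, locus = "DRB") {
  rows <- lapply(names(spec), function(amp) {
    v <- spec[[amp]]
    tibble::tibble(
      amplicon_id = paste(amp, locus, sep = ":"), sample_id = amp,
      individual_id = sub("_rep[0-9]+$", "", amp), locus = locus,
      sequence = names(v), copy_count = as.integer(v),
      total_reads = as.integer(sum(v))
    )
  })
  dplyr::bind_rows(rows)
}
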
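#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows n n_distinct row_number desc
#'   rename count distinct across pull first slice_head
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_chr map_int map2 pmap imap list_rbind
#' @importFrom stats setNames rbinom rpois rnbinom runif cor.test pbinom
#'   dmultinom sd var quantile pnorm rmultinom
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Run `code` under a fixed RNG state when `seed` is given, without touching
## the caller's RNG; all stochastic entry points funnel through this.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  withr::with_seed(as.integer(seed), force(code))
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
  }, character(1))
}

## Unordered tag-pair key (forward/reverse interchangeable).
tag_pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

## All single-crossover recombinants prefix(a) + suffix(b), crossover after
## position k, k = 1 .. nchar(a) - 1.  Used both by the simulator (to keep
## allele pools recombination-distinct) and by the chimera screen.
crossover_products <- function(a, b) {
  ka <- nchar(a)
  if (ka < 2L) return(character(0))
  k <- seq_len(ka - 1L)
  paste0(substr(rep(a, length(k)), 1L, k),
         substr(rep(b, length(k)), k + 1L, nchar(b)))
}

is_stop_codon <- function(codon) codon %in% c("TAA", "TAG", "TGA")

## Split an in-frame sequence into codons.
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    abort("sequence length must be a multiple of 3 for codon analyses")
  }
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

has_internal_stop <- function(seq) {
  any(is_stop_codon(split_codons(seq)))
}

## Coerce an alignment given as a named character vector or a tibble with
## columns (allele_id | id | name, sequence) into a named character vector.
as_alignment <- function(alignment) {
  if (is.character(alignment)) {
    seqs <- alignment
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  } else if (is.data.frame(alignment)) {
    idcol <- intersect(c("allele_id", "id", "name"), names(alignment))[1]
    if (is.na(idcol) || !"sequence" %in% names(alignment)) {
      abort("alignment data frame needs an id column and a 'sequence' column")
    }
    seqs <- setNames(alignment$sequence, alignment[[idcol]])
  } else {
    abort("alignment must be a named character vector or a data frame")
  }
  if (length(unique(nchar(seqs))) > 1L) {
    abort("aligned sequences must all have the same length")
  }
  seqs
}

#' Read or write a multi-FASTA file as a tibble
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] keeping reads in the tabular form the rest
#' of the pipeline uses.
#'
#' @param path File path.
#' @param reads Tibble with columns `read_id`, `sequence`.
#' @return `read_fasta()` returns a tibble with columns `read_id`,
#'   `sequence`; `write_fasta()` returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(read_id = names(x), sequence = as.character(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  Biostrings::writeXStringSet(x, path, width = 10000L)
  invisible(path)
}
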
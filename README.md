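# mhctyper

Stepwise variant validation and population genetics for amplicon-sequenced
MHC class II loci.

## What it does

Large-scale genotyping of the MHC class II loci DRB and DQB from tagged,
pooled amplicon sequencing (454-style chemistry) is limited not by
throughput but by artefacts: point errors and homopolymer indels, PCR
chimeras, and reads leaking between amplicons. When both loci are
non-duplicated — each individual carries at most two true alleles per locus
— a stepwise validation procedure can separate true alleles (TA) from
artefactual ones (AA) and call genotypes with pedigree-grade accuracy.
`mhctyper` implements that procedure end to end, for anyone genotyping
highly polymorphic, co-amplified loci with tag-based demultiplexing:

- **Pre-processing**: demultiplexing by *unordered* 10-bp tag pairs with
  zero-mismatch primer matching, exact dereplication, a ≥5-copies-per-
  amplicon variant filter, a ≥18-reads amplicon filter backed by an exact
  multinomial inclusion–exclusion coverage model (the probability that `n`
  reads show all `m` variants at least `r` times each), and trimming both
  loci to a common alignable core.
- **Allele validation**: the mean per-amplicon frequency
  `MPAF(a) = mean over carrier amplicons of (reads of a / amplicon reads)`
  with a strict 5% elimination threshold, plus a within-amplicon artefact
  screen classifying each minor variant as a *point mutant* (edit distance
  1 to a more-common variant) or a *chimera* (exact single-crossover
  recombinant of two more-common variants), and the MPAF-vs-carrier-count
  correlation diagnostic.
- **Genotyping**: the two most common validated alleles (TMCA) per
  amplicon, replicate concordance with a dropout-aware consensus, Mendelian
  dyad/triad checks, and an excess-allele report that traces extra
  sequences to cross-amplicon contamination.
- **Population genetics**: allele frequencies, Weir–Cockerham Fis, the
  Rousset–Raymond heterozygote-excess U test (exact or Monte Carlo,
  conditional on allele counts), EM haplotype frequencies with a
  likelihood-ratio permutation test of linkage disequilibrium, a
  Brookfield null-allele estimate, and allelic-richness rarefaction with
  its exact hypergeometric expectation.
- **Molecular evolution**: p/Jukes–Cantor distances
  (`d = −(3/4)·ln(1 − (4/3)p)`), neighbour-joining trees with bootstrap
  supports, and Nei–Gojobori pathway counting of synonymous and
  nonsynonymous substitutions (all stop-free orderings of within-codon
  changes equally probable) with codon-bootstrap standard errors and the
  selection Z-test `Z = (dN − dS)/√(Var dN + Var dS)` on ABS/PSS site
  partitions.
- **Synthetic data**: a simulator producing tagged bidirectional read
  libraries with known truth — divergent allele pools on a wide frequency
  spectrum, tunable two-locus linkage, parent–offspring triads,
  overdispersed coverage, and every artefact class above — so the whole
  pipeline is testable without any external data.

Everything is tibble-in/tibble-out and pipe-friendly; test objects have
`tidy()`/`glance()` methods and result types have `autoplot()`/`plot_*()`
helpers.

## Worked example

```r
library(mhctyper)

truth <- simulate_population(100, n_alleles = c(30, 30), spectrum = "wide",
                             ld = "intermediate", theta = 0.7, seed = 1)
reads <- simulate_reads(truth, error_model(), seed = 2)
pipe  <- genotype_pipeline(reads)
pipe$summary
#> # A tibble: 6 × 5
#>   step               reads amplicons individuals variants
#> 1 input              20751        NA          NA       NA
#> 2 demultiplexed      20751       198         100       NA
#> 3 dereplicated       20751       198         100     6230
#> 4 copy_filter_5      12386       179         100       46
#> 5 amplicon_filter_18 12054       149          95       43
#> 6 common_region      12054       149          95       43

evaluate_against_truth(pipe, truth)$accuracy
#> # A tibble: 2 × 6
#>   locus n_simulated n_called n_correct accuracy call_rate
#> 1 DQB           100       72        72        1      0.72
#> 2 DRB           100       77        77        1      0.77
```

Reading: the 5-copy filter collapses 6,230 raw variant sequences (mostly
singleton error reads) to 46, and the 18-read amplicon filter discards the
low tail of the heavily overdispersed coverage distribution (hence a call
rate near 0.75 at mean coverage 100); every genotype that *is* called
matches the simulated truth exactly, and the validated catalog contains no
artefact sequences.

```r
allele_frequencies(pipe$genotypes)$stats
#> # A tibble: 2 × 7
#>   locus     n     k    ho    he fis_naive fis_wc
#> 1 DQB      72    19 0.861 0.895    0.0379 0.0381
#> 2 DRB      77    21 0.883 0.893    0.0108 0.0109

glance(ld_test(pipe$genotypes, c("DQB", "DRB"), n_permutations = 999, seed = 3))
#> # A tibble: 1 × 6
#>   statistic p.value logLik logLik_equilibrium     n n_permutations
#> 1      348.   0.001  -298.              -472.    54            999
```

The two loci were simulated in tight linkage (`theta = 0.7`), and the
likelihood-ratio permutation test finds the association at the smallest
p-value its 999 permutations allow, `(0 + 1)/(999 + 1)`.

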
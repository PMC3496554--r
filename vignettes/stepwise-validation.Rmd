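---
title: "Stepwise variant validation for co-amplified MHC class II loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise variant validation for co-amplified MHC class II loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genotyping the MHC class II loci DRB and DQB from pooled, tagged amplicon
sequencing is dominated by one difficulty: a large fraction of the unique
read sequences are artefacts — point errors of the sequencing chemistry
(substitutions, and indels concentrated in homopolymer runs), PCR chimeras
recombining two template sequences, and reads that leak between amplicons
(cross-amplicon contamination). When the two loci are non-duplicated, every
individual carries at most two true alleles per locus, which makes a
single-locus system an unusually good testbed for artefact filtering: the
expected number of sequences per amplicon is known.

`mhctyper` implements the full stepwise variant validation procedure for
this setting, together with its downstream population-genetic and
molecular-evolution analyses, and a first-class synthetic-data module that
simulates tagged read libraries with known truth so that every stage of the
pipeline is verifiable end to end.

## The pipeline

An *amplicon* is the pool of reads amplified from one individual at one
locus in one PCR, identified by its unordered pair of 10-bp tags (forward
and reverse tags are interchangeable, which quadratically reduces the number
of tags needed). The stages are:

1. **Demultiplexing** (`demultiplex_reads()`): a read is kept only if both
   tags are fully present and both template-specific primers match with
   zero mismatches, in either orientation. The locus is assigned from the
   primer pair; a read carrying the DRB forward and the DQB reverse primer
   is a *cross-locus chimera* and is rejected with its own reason code.
2. **Dereplication** (`dereplicate_reads()`): only perfectly identical reads
   merge into a variant record with a copy count.
3. **Copy filter** (`filter_min_copies()`): variants seen fewer than 5 times
   within an amplicon are removed ("less than" is strict; a count of exactly
   5 survives). Within-amplicon frequencies downstream use the surviving
   copy total as denominator; this choice is configurable by recomputing
   totals externally, but it is the default because the frequencies the
   procedure interprets are frequencies among retained reads.
4. **Coverage filter** (`filter_min_reads()`): amplicons with fewer than 18
   surviving reads are discarded. The companion confidence model
   (`min_reads_required()`, `coverage_confidence()`) gives the exact
   probability, by multinomial inclusion–exclusion, that `n` reads contain
   all `m` variants at least `r` times each. Under equal sampling of
   `m = 2` variants with `r = 3` and confidence 0.95 the exact answer is
   `n = 12`; the widely used operational threshold of 18 reads corresponds
   to a stricter model (e.g. unequal amplification of the two alleles —
   the `probs` argument reproduces that regime). We keep 18 as the
   pipeline default because it is the established operating point, while
   reporting the model's own exact values.
5. **Common region** (`trim_common_region()`): per-locus trim rules cut both
   loci back to the same alignable core (first bases of DQB, last bases of
   DRB), re-merging variants that become identical.
6. **Allele validation** (`validate_alleles()`): the *mean per-amplicon
   frequency* (MPAF) of a variant is its within-amplicon read proportion
   averaged over the amplicons that carry it. True alleles of a
   heterozygote sit near 0.5, artefacts near 0. Variants with MPAF < 0.05
   are eliminated; the boundary is strict. Surviving variants are screened
   within every carrier amplicon against the variants of strictly higher
   copy count there ("parentals"): edit distance 1 (one substitution *or*
   one indel, the dominant homopolymer error) marks a point mutant, an
   exact single-crossover decomposition into two distinct parentals marks a
   chimera, and the single-event explanation wins ties. A variant explained
   in *all* of its carrier amplicons is eliminated; requiring all amplicons
   (rather than any) prevents a coincidental one-amplicon explanation from
   deleting a real allele, and the screen is applied at every MPAF level
   above the threshold. Single-carrier survivors are kept but flagged.
   MPAF is computed once, before elimination (`iterative = TRUE` enables
   recomputation for sensitivity analysis).
7. **Genotype calling** (`call_genotypes()`): the genotype is the two most
   common validated alleles (TMCA). A second-ranked allele whose
   within-amplicon frequency falls below the MPAF threshold is judged a
   contamination trace and the call becomes a homozygote — the package's
   own rule, chosen because no published numeric rule exists for accepting
   homozygotes without duplicates. More than two above-threshold validated
   alleles raise `excess_alleles` (the cross-amplicon contamination
   signature, examined by `multi_allele_report()`); rank-2 ties break
   deterministically by frequency then sequence and are flagged.

Quality control mirrors the validation arms of the original design:
`replicate_concordance()` compares independent amplifications of the same
individual (a heterozygote call overrides a homozygote call, assuming
allelic dropout; two distinct heterozygotes stay unresolved), and
`pedigree_consistency()` checks Mendelian sharing in dyads and triads,
reporting mismatches that co-occur at both loci separately because those
indicate parentage errors rather than genotyping errors.

## The diagnostic correlation

`mpaf_carrier_correlation()` reproduces the catalogue-level diagnostic: a
given artefact rarely recurs in many amplicons, so before sorting, MPAF and
carrier count correlate positively (artefacts are low on both); after
sorting the correlation should collapse. Two caveats learned from
simulation are worth recording. First, the diagnostic has power only when
artefacts actually reach the copy filter's threshold, which happens in
high-coverage amplicons; with perfectly even coverage at 100 reads the
stage-7 catalogue is already almost clean and there is nothing to
correlate. Second, on clean simulated data the *validated* alleles retain
a weak positive correlation of purely biological origin: common alleles are
carried homozygously more often, and a homozygous amplicon contributes a
within-amplicon frequency near 1 to the allele's MPAF. In real data this
effect is buried under per-amplicon frequency noise (amplification bias
between alleles, which the error model deliberately does not include).
Restricting to heterozygous carrier amplicons removes it entirely.

## The synthetic-data module

`simulate_population()` draws two-locus genotypes by random union of
haplotypes. Allele pools emulate deeply divergent MHC allelic lineages:
every pair of allele cores differs by at least 3 substitutions and no
allele equals a single-crossover recombinant of two others, so true alleles
are never confusable with each other's point mutants or chimeras — the
identifiability assumption the validation procedure itself relies on. The
`"wide"` frequency spectrum spans 0.001–0.21 with a median near 0.015,
the wide spectrum characteristic of large wild-population MHC surveys.
Linkage between the loci ranges from independence to complete coupling
(`ld`, `theta`); `simulate_pedigree()` adds triads transmitting whole
two-locus haplotypes (no recombination, matching the tight physical linkage
of DRB and DQB).

`simulate_reads()` then emits tagged, bidirectional reads with, per read:
cross-amplicon contamination (template copied from another individual),
between-locus chimeras (locus-1 prefix, locus-2 suffix, carrying the
mismatched primer pair), within-locus chimeras (uniform crossover between
the individual's two alleles), substitutions at 1e-3/bp and indels whose
per-site probability is multiplied by the homopolymer run length. Errors
are applied to the template only: tag or primer errors would merely remove
the read at demultiplexing, adding nothing verifiable. Per-amplicon depth
is negative-binomial with mean 100 and size 0.85 by default; the size is
anchored to the empirically observed dispersion of pooled amplicon runs
(SD slightly above the mean, coefficient of variation ≈ 1.1). That heavy
tail matters twice: high-coverage amplicons are where artefacts survive the
copy filter (giving the validation stage real work), and the low tail
discards 25–30% of amplicons at the 18-read threshold, so genotype
recovery is reported as accuracy among called genotypes alongside the call
rate. What the simulator does *not* model: base qualities and flowgrams,
amplification bias between a heterozygote's alleles, tag jumping, and
multi-run structure. Consequently, passing end-to-end tests demonstrates
the logic of the procedure, not its error rates on a real instrument.

## Statistical components

* **Heterozygote excess** (`hwe_excess_test()`): the U score is the score
  statistic of the inbreeding model at `f = 0`,
  `U = n_het − Σ_hom (1−p)/p`, with the null conditioned on allele counts:
  exact enumeration of the heterozygote-count distribution for biallelic
  samples up to 50 individuals, Monte Carlo permutation of the 2n allele
  copies otherwise. All resampling p-values use `(b+1)/(m+1)`, so p = 0 is
  impossible.
* **Haplotypes and LD** (`em_haplotypes()`, `ld_test()`): EM over the phase
  ambiguity of double heterozygotes, started from the product of single
  -locus allele frequencies — which guarantees the associated model's
  likelihood is at least the equilibrium likelihood, hence `LR ≥ 0`, and
  keeps haplotype marginals exactly equal to observed allele frequencies at
  every iteration. Convergence is declared when the largest frequency
  change drops below `tol` (default 1e-6). The LR's null distribution comes
  from permuting one locus's genotypes across individuals; no chi-squared
  reference is asserted, because the permutation procedure makes the
  asymptotic distribution unnecessary.
* **Fis** (`allele_frequencies()`): Weir & Cockerham's single-population
  estimator next to the naive `1 − Ho/He`; He is the unbiased small-sample
  form.
* **Null alleles** (`null_allele_frequency()`): Brookfield's equation 1,
  `(He − Ho)/(1 + He)`, floored at zero — chosen because it is the standard
  homozygote-excess estimator when true null homozygotes go ungenotyped.
* **Rarefaction** (`rarefaction_curve()`): individuals resampled without
  replacement in steps of 20, 100 replicates per effort;
  `expected_allelic_richness()` provides the exact hypergeometric
  expectation, by default over individuals (which is the exact expectation
  of the Monte Carlo design; the classic gene-copy formula is available via
  `unit = "genes"`).
* **Distances and trees** (`pairwise_distances()`, `nj_tree()`,
  `bootstrap_support()`): p-distances with pairwise deletion,
  Jukes–Cantor correction `d = −(3/4)·ln(1 − (4/3)p)` (undefined at
  p ≥ 0.75 and reported as such), Saitou–Nei neighbour joining, and column
  bootstrap supports; sequences are ordered by label internally so supports
  do not depend on input order.
* **Selection** (`count_syn_nonsyn_sites()`, `nei_gojobori_pair()`,
  `selection_test()`): the pathway-counting method with all stop-free
  orderings of within-codon changes equally weighted; changes to stop
  codons are excluded from site denominators. Standard errors of the mean
  pairwise dN and dS come from a codon bootstrap (default 1000 replicates)
  — assumption-light where an analytic variance would need the covariance
  of pathway counts — and `Z = (dN − dS)/√(Var dN + Var dS)` is tested
  two-sided by default ("are dN and dS similar"), with a one-sided
  positive-selection option. ω is reported as `NA` when dS = 0, never
  coerced to a large number. The 6-bp insertion some DQB alleles carry is
  handled by excluding the insertion columns from codon analyses (the
  default alignment is the common 162-bp core), since equal-length,
  in-frame sequences are required.

## Worked example

```{r, eval = FALSE}
library(mhctyper)

truth <- simulate_population(100, n_alleles = c(30, 30), spectrum = "wide",
                             ld = "intermediate", theta = 0.7, seed = 1)
reads <- simulate_reads(truth, error_model(), seed = 2)
pipe  <- genotype_pipeline(reads)
pipe$summary                       # per-stage filter table
evaluate_against_truth(pipe, truth)$accuracy

allele_frequencies(pipe$genotypes)$stats
ld_test(pipe$genotypes, c("DQB", "DRB"), n_permutations = 999, seed = 3)

val <- subset(pipe$catalog, status == "validated" & locus == "DRB")
selection_test(setNames(val$sequence, val$allele_id), reps = 500, seed = 4)
```

## Numerical choices and limitations

Problem sizes in the test suite were chosen to exercise each property at
meaningful scale: 200 individuals with 60-allele pools for the end-to-end
run, 10^6 Monte Carlo replicates against the exact coverage model, 1000
random codon-sequence pairs against the pathway-enumeration oracle, 1000
null simulations for the type-I error of the HWE and LD tests, and 100
replicates of n = 500 for EM recovery (reported as the mean over replicates
of the largest absolute haplotype-frequency error, since the extreme over
all replicates and haplotypes scales with the multinomial sampling noise
rather than with estimator quality). Seeds are explicit everywhere;
rerunning any stochastic component with the same seed is bit-identical.

Known limitations: artefact classification assumes parental sequences are
present in the same amplicon (a contaminant's parents are not, so
contaminated amplicons are caught by the excess-allele report instead);
`min_reads_required()` grows combinatorially in `m` for unequal
probabilities (guarded at m ≤ 12); and the chimera screen allows no
mismatches in either arm, so a chimera that also carries a point error
survives to the MPAF stage, where its low frequency eliminates it.
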
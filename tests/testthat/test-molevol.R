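test_that("p and Jukes-Cantor distances follow their closed forms", {
  expect_equal(jc_correct(0.3), -0.75 * log(1 - 0.4), tolerance = 1e-12)
  expect_true(is.na(jc_correct(0.75)))
  p <- seq(0.01, 0.7, by = 0.01)
  expect_true(all(diff(jc_correct(p)) > 0)) # monotone
  expect_lt(abs(jc_correct(1e-6) - 1e-6), 1e-11)

  aln <- c(s1 = "ACGTACGTAC", s2 = "ACGTACGTAC", s3 = "TCGTACGTAA")
  d <- pairwise_distances(aln, "nucleotide", "p")
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], 0.2)
  dj <- pairwise_distances(aln, "nucleotide", "jukes_cantor")
  expect_equal(dj["s1", "s3"], -0.75 * log(1 - 0.8 / 3), tolerance = 1e-12)
  # gaps are deleted pairwise
  alng <- c(a = "AC-TA", b = "ACGTT")
  dg <- pairwise_distances(alng, "nucleotide", "p")
  expect_equal(dg["a", "b"], 0.25)
})

test_that("nucleotide distances agree with ape's implementation", {
  set.seed(55)
  base <- random_coding_seq(40)
  seqs <- vapply(1:6, function(i) mutate_coding_seq(base, 10), character(1))
  names(seqs) <- paste0("t", 1:6)
  mine <- pairwise_distances(seqs, "nucleotide", "jukes_cantor")
  bin <- ape::as.DNAbin(t(sapply(seqs, function(s) strsplit(tolower(s), "")[[1]])))
  theirs <- as.matrix(ape::dist.dna(bin, model = "JC69",
                                    pairwise.deletion = TRUE))
  expect_equal(mine, theirs[rownames(mine), colnames(mine)],
               tolerance = 1e-10)
})

test_that("NJ recovers additive trees exactly and handles tiny cases", {
  # three-point formulas
  d3 <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- nj_tree(d3)
  cp <- ape::cophenetic.phylo(tr3)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(cp, d3, tolerance = 1e-10)
  # two taxa: single path of length d
  tr2 <- nj_tree(matrix(c(0, 3, 3, 0), 2, 2,
                        dimnames = list(c("x", "y"), c("x", "y"))))
  expect_equal(sum(tr2$edge.length), 3)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2,
                              dimnames = list(c("x", "y"), c("x", "y")))),
               "symmetric")

  set.seed(66)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n)
    dm <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(dm)
    cp <- ape::cophenetic.phylo(rec)[rownames(dm), colnames(dm)]
    expect_equal(cp, dm, tolerance = 1e-8)
  }
})

test_that("bootstrap supports are deterministic and saturate on strong signal", {
  set.seed(77)
  base1 <- random_coding_seq(40)
  base2 <- mutate_coding_seq(base1, 40) # deeply divergent second clade
  aln <- c(
    a1 = mutate_coding_seq(base1, 2), a2 = mutate_coding_seq(base1, 2),
    b1 = mutate_coding_seq(base2, 2), b2 = mutate_coding_seq(base2, 2)
  )
  tr <- bootstrap_support(aln, reps = 50, seed = 11)
  expect_true(any(stats::na.omit(tr$node.label) >= 95))
  tr2 <- bootstrap_support(aln, reps = 50, seed = 11)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  # reps = 1 can only give 0 or 100
  tr1 <- bootstrap_support(aln, reps = 1, seed = 12)
  expect_true(all(stats::na.omit(tr1$node.label) %in% c(0, 100)))
  # supports invariant to taxon input order
  tr3 <- bootstrap_support(aln[c(3, 1, 4, 2)], reps = 50, seed = 11)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr3))
})

test_that("variability summaries count variable sites and differences", {
  aln <- c(a = "ACGTACGTACGT", b = "ACGTACGTACGT")
  v <- variability_summary(aln)
  expect_equal(v$variable_sites, 0)
  aln2 <- c(a = "ACGTACGTACGT", b = "TCGTACGAACGA")
  v2 <- variability_summary(aln2)
  expect_equal(v2$variable_sites, 3)
  expect_equal(v2$mean_pairwise_diff, 3)
})

test_that("site counts match the enumeration oracle for every sense codon", {
  expect_equal(count_syn_nonsyn_sites("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(count_syn_nonsyn_sites("GGG"), c(s = 1, n = 2))
  expect_equal(count_syn_nonsyn_sites("TGG"), c(s = 0, n = 3))
  for (cod in SENSE_CODONS) {
    expect_equal(count_syn_nonsyn_sites(cod), oracle_sites(cod),
                 tolerance = 1e-12)
  }
  expect_error(count_syn_nonsyn_sites("TAA"), "stop")
})

test_that("pathway counting matches explicit enumeration and is symmetric", {
  expect_equal(nei_gojobori_pair("TTT", "TTT")[c("Sd", "Nd", "dS", "dN")],
               c(Sd = 0, Nd = 0, dS = 0, dN = 0))
  expect_equal(nei_gojobori_pair("TTT", "TTC")[c("Sd", "Nd")],
               c(Sd = 1, Nd = 0))
  # TTT -> GTA: via GTT (nonsyn, then syn) or TTA (nonsyn, then nonsyn)
  expect_equal(nei_gojobori_pair("TTT", "GTA")[c("Sd", "Nd")],
               c(Sd = 0.5, Nd = 1.5))
  set.seed(88)
  for (i in 1:40) {
    a <- random_coding_seq(sample(3:12, 1))
    b <- mutate_coding_seq(a, sample(1:6, 1))
    mine <- nei_gojobori_pair(a, b)
    orc <- oracle_ng_pair(a, b)
    expect_equal(mine[c("Sd", "Nd", "S", "N")], orc, tolerance = 1e-12)
    rev <- nei_gojobori_pair(b, a)
    expect_equal(mine[c("Sd", "Nd", "S", "N")], rev[c("Sd", "Nd", "S", "N")],
                 tolerance = 1e-12)
    # per-pair Sd + Nd equals the number of differing positions when no
    # pathway is stop-blocked asymmetrically; always within the codon count
    nd_diff <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(unname(mine["Sd"] + mine["Nd"]), nd_diff, tolerance = 1e-12)
  }
})

test_that("selection Z-test separates synonymous-only from amino-acid-changing data", {
  # all differences synonymous (fourfold third positions): dN = 0, Z < 0
  aln_syn <- c(s1 = "GGAGGAGGAGGAGGAGGA", s2 = "GGCGGAGGAGGTGGAGGA",
               s3 = "GGAGGCGGAGGAGGTGGA")
  st <- selection_test(aln_syn, reps = 200, seed = 21)
  expect_equal(st$dn, 0)
  expect_lt(st$z, 0)
  expect_true(is.na(st$omega) || st$omega == 0)

  # first-position changes in AAA codons are all nonsynonymous
  aln_ns <- c(s1 = "AAAAAAAAAAAAAAAAAA", s2 = "CAAAAAGAAAAAAAACAA",
              s3 = "GAACAAAAAGAAAAAAAA")
  st2 <- selection_test(aln_ns, reps = 200, seed = 22)
  expect_equal(st2$ds, 0)
  expect_gt(st2$z, 0)
  expect_true(is.na(st2$omega))

  parts <- site_partition(6, abs_codons = 1:3)
  st3 <- selection_test(aln_ns, parts, reps = 100, seed = 23)
  expect_setequal(st3$partition, c("all", "ABS", "non_ABS"))
  expect_warning(selection_test(aln_ns, list(empty = integer(0),
                                             all = 1:6), reps = 50, seed = 1),
                 "skipped")
})
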
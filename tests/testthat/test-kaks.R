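# The Nei-Gojobori core: site fractions, pathway averaging, Jukes-Cantor
# correction and the assembled estimator, checked against hand-derived values
# and the independent brute-force oracle.

test_that("codon site fractions match hand enumeration for canonical codons", {
  expect_equal(codon_site_fractions("TTT")[["s"]], 1 / 3)
  expect_equal(codon_site_fractions("CTT")[["s"]], 1)
  expect_equal(codon_site_fractions("ATG")[["s"]], 0)
  # s + n = 3 exactly and N/gap codons are uncountable
  expect_equal(sum(codon_site_fractions("TTT")), 3)
  expect_true(all(is.na(codon_site_fractions("ATN"))))
  expect_true(all(is.na(codon_site_fractions("---"))))
  expect_error(codon_site_fractions("TAA"), "stop")
})

test_that("site fractions agree with the enumeration oracle for all sense codons", {
  gc <- oracle_code()
  for (codon in names(gc)[gc != "*"]) {
    expect_equal(codon_site_fractions(codon)[["s"]],
                 oracle_site_fractions(codon, gc)[["s"]],
                 info = codon)
  }
})

test_that("pathway differences average over mutational orderings", {
  expect_equal(pathway_differences("TTT", "TTT"), c(sd = 0, nd = 0))
  expect_equal(pathway_differences("TTT", "TTA"), c(sd = 0, nd = 1))
  # two differing positions: via GTT (1 syn + 1 nonsyn) and via TTA (0 + 2)
  expect_equal(pathway_differences("TTT", "GTA"), c(sd = 0.5, nd = 1.5))
  expect_error(pathway_differences("TAA", "TTT"), "sense")
})

test_that("pathway differences match the ordering-enumeration oracle on random pairs", {
  gc <- oracle_code()
  set.seed(42)
  sense <- names(gc)[gc != "*"]
  for (i in 1:200) {
    a <- sample(sense, 1); b <- sample(sense, 1)
    expect_equal(unname(pathway_differences(a, b)),
                 unname(oracle_pathway(a, b, gc)),
                 info = paste(a, b))
  }
})

test_that("the include policy averages over all orderings", {
  gc <- oracle_code()
  set.seed(43)
  sense <- names(gc)[gc != "*"]
  for (i in 1:50) {
    a <- sample(sense, 1); b <- sample(sense, 1)
    expect_equal(
      unname(pathway_differences(a, b, stop_policy = "include")),
      unname(oracle_pathway(a, b, gc, exclude_stops = FALSE)),
      info = paste(a, b)
    )
  }
})

test_that("jukes_cantor matches the closed form and is strictly increasing", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.5), 0.75 * log(3))
  expect_true(is.na(jukes_cantor(0.75)))
  expect_true(is.na(jukes_cantor(0.9)))
  expect_error(jukes_cantor(-0.1), "non-negative")
  p <- seq(0, 0.74, by = 0.01)
  d <- jukes_cantor(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p)) # correction never shrinks the proportion
})

test_that("compute_kaks reproduces the four-codon worked example exactly", {
  ca <- codon_alignment(c("TTT", "CTT", "CTC", "GGG"),
                        c("TTC", "CTT", "CTC", "GGG"))
  r <- compute_kaks(ca)
  expect_equal(r$S, 10 / 3, tolerance = 1e-12)
  expect_equal(r$N, 26 / 3, tolerance = 1e-12)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$pS, 0.3, tolerance = 1e-12)
  expect_equal(r$ks, -0.75 * log(0.6), tolerance = 1e-12)
  expect_equal(r$ka, 0)
  expect_equal(r$kaks, 0)
})

test_that("identical sequences give zero variation and undefined ratio", {
  ca <- codon_alignment(c("ATG", "CCC", "GGA"), c("ATG", "CCC", "GGA"))
  r <- compute_kaks(ca)
  expect_true(r$zero_variation)
  expect_equal(r$ka, 0)
  expect_equal(r$ks, 0)
  expect_true(is.na(r$kaks))
  expect_true(r$valid)
})

test_that("gapped, ambiguous and stop columns are excluded from counting", {
  ca <- codon_alignment(c("TTT", "---", "ATN", "TAA", "CTT"),
                        c("TTC", "GGG", "ATG", "TAA", "CTT"))
  r <- compute_kaks(ca)
  expect_equal(r$n_codons, 2) # only TTT/TTC and CTT/CTT counted
  expect_equal(r$Sd, 1)
  # all-uncountable alignment errors
  expect_error(compute_kaks(codon_alignment("---", "ATG")), "countable")
})

test_that("compute_kaks is symmetric and conserves difference counts", {
  set.seed(7)
  for (i in 1:50) {
    a <- random_sense_codons(30)
    b <- random_sense_codons(30)
    r1 <- compute_kaks(codon_alignment(a, b))
    r2 <- compute_kaks(codon_alignment(b, a))
    expect_identical(as.data.frame(r1), as.data.frame(r2))
    nt_hamming <- sum(mapply(function(x, y) {
      sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    }, a, b))
    expect_equal(r1$Sd + r1$Nd, nt_hamming)
  }
})

test_that("invalid Ka/Ks is flagged when proportions leave the JC domain", {
  # maximally different codons at every column push pN past 3/4
  ca <- codon_alignment(rep("ATG", 20), rep("TGC", 20))
  r <- compute_kaks(ca)
  expect_false(r$valid_ka)
  expect_true(is.na(r$ka))
  expect_true(is.na(r$kaks))
})

test_that("Ka/Ks error shrinks with sequence length at low divergence", {
  # consistency of the estimator: longer genes estimate omega better
  set.seed(101)
  code <- genetic_code(11)
  err_for <- function(n_codons, reps) {
    mean(vapply(seq_len(reps), function(i) {
      cds <- random_cds(n_codons, code)
      hom <- evolve_codon_sequence(cds, omega = 0.5, divergence = 0.04, code)
      abs(gene_pair_kaks(cds, hom, code)$kaks - 0.5)
    }, numeric(1)), na.rm = TRUE)
  }
  expect_lt(err_for(3000, 5), err_for(300, 5))
})
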
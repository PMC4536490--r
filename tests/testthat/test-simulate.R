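test_that("random_cds emits stop-free sense codons plus a terminal stop", {
  cds <- random_cds(10, seed = 1)
  expect_equal(nchar(cds), 33)
  expect_equal(nchar(translate_cds(cds)), 10) # no internal stop anywhere
  expect_identical(random_cds(10, seed = 1), cds)
  expect_false(identical(random_cds(10, seed = 2), cds))
})

test_that("evolution respects the divergence and omega limits", {
  cds <- random_cds(100, seed = 3)
  expect_identical(evolve_codon_sequence(cds, 0.3, 0, seed = 4), cds)

  # omega -> 0: every nonsynonymous proposal rejected, protein unchanged
  hom <- evolve_codon_sequence(cds, 1e-12, 0.2, seed = 5)
  expect_false(identical(hom, cds))
  expect_equal(translate_cds(hom), translate_cds(cds))
  r <- gene_pair_kaks(cds, hom)
  expect_equal(r$Nd, 0)
  expect_gt(r$ks, 0)

  expect_identical(evolve_codon_sequence(cds, 0.3, 0.2, seed = 6),
                   evolve_codon_sequence(cds, 0.3, 0.2, seed = 6))
})

test_that("neutral evolution recovers Ka/Ks near 1 on long sequences", {
  set.seed(61)
  est <- vapply(1:8, function(i) {
    cds <- random_cds(3000)
    gene_pair_kaks(cds, evolve_codon_sequence(cds, 1, 0.2))$kaks
  }, numeric(1))
  expect_gt(mean(est), 0.85)
  expect_lt(mean(est), 1.15)
})

test_that("class omegas are recovered across seeds at panel defaults", {
  # 20 seeds x 5 genes per class at the generator defaults, pooled per class
  est <- lapply(1:20, function(s) {
    set.seed(100 + s)
    sapply(1:5, function(i) {
      cds <- random_cds(300)
      c(e = gene_pair_kaks(cds, evolve_codon_sequence(cds, 0.05, 0.2))$kaks,
        ne = gene_pair_kaks(cds, evolve_codon_sequence(cds, 0.3, 0.2))$kaks)
    })
  })
  est <- do.call(cbind, est)
  expect_lt(abs(stats::median(est["e", ]) - 0.05) / 0.05, 0.25)
  expect_lt(abs(stats::median(est["ne", ]) - 0.3) / 0.3, 0.25)
})

test_that("generate_panel writes a consistent, reproducible file set", {
  cfg <- sim_config(n_organisms = 3, genes_per_organism = 20,
                    codons_per_gene = 60, pne_fraction = 0.1, seed = 17)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- generate_panel(cfg, d1)
  p2 <- generate_panel(cfg, d2)

  # byte-identical regeneration from the same config
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }

  # class sizes follow the config
  tr <- p1$ground_truth
  expect_equal(sum(tr$essential), 3 * round(20 * 0.2))
  expect_equal(nrow(tr), 60)

  # PNE-flagged genes are exactly the zero-divergence ones with 2+ homologs
  org1 <- tr[tr$organism_id == "org01", ]
  cds <- read_fasta(file.path(d1, "org01.cds.fasta"))
  hom <- read_fasta(file.path(d1, "org01.homolog_cds.fasta"))
  identical_cds <- vapply(org1$gene_id, function(g) {
    cds[[g]] == hom[[paste0(g, "_h")]]
  }, logical(1), USE.NAMES = FALSE)
  expect_equal(identical_cds, org1$is_pne)
  expect_equal(sum(org1$is_pne), round(16 * 0.1))
  expect_true(all(org1$homolog_count[org1$is_pne] >= 2))

  # proteins on disk match the CDS
  prot <- read_fasta(file.path(d1, "org01.protein.fasta"))
  expect_equal(unname(vapply(cds, translate_cds, "")), unname(prot))

  # hit table is readable and one hit per gene
  hits <- read_hit_table(file.path(d1, "org01.hits.tsv"))
  expect_equal(sort(hits$query_id), sort(org1$gene_id))
  expect_true(all(hits$evalue < 1e-5))
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(fraction_essential = 1, pne_fraction = 0.1),
               "inconsistent")
  expect_error(sim_config(divergence = 0), "divergence")
  expect_error(sim_config(omega_essential = 0), "omega")
})
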
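pne_input <- function() {
  tibble::tibble(
    gene_id = c("e1", "n1", "n2", "n3", "n4"),
    organism_id = "orgA",
    essential = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    ka = c(0, 0, 0, 0.1, 0),
    ks = c(0, 0, 0.01, 0.2, 0)
  )
}

hom_input <- function() {
  tibble::tibble(gene_id = c("e1", "n1", "n2", "n3", "n4"),
                 homolog_count = c(5L, 2L, 5L, 5L, 1L))
}

test_that("PNE calls require zero variation plus homologs in 2+ organisms", {
  p <- classify_pne(pne_input(), hom_input())
  rec <- p$records
  expect_true(rec$is_pne[rec$gene_id == "n1"])
  # Ks > 0 disqualifies even with many homologs
  expect_false(rec$is_pne[rec$gene_id == "n2"])
  # diverged gene is not PNE
  expect_false(rec$is_pne[rec$gene_id == "n3"])
  # homolog count 1 disqualifies despite zero variation
  expect_false(rec$is_pne[rec$gene_id == "n4"])
  # essential genes are never PNE (e1 is zero-variation with 5 homologs)
  expect_false(rec$is_pne[rec$gene_id == "e1"])
  expect_equal(p$n_pne, 1)
  expect_equal(p$n_nonessential, 4)
  expect_equal(p$proportion, 0.25)
})

test_that("PNE proportion uses nonessential genes as denominator", {
  res <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:100),
    essential = c(rep(TRUE, 6), rep(FALSE, 94)),
    ka = c(rep(0.1, 6), 0, 0, rep(0.1, 92)),
    ks = c(rep(0.2, 6), 0, 0, rep(0.2, 92))
  )
  hom <- tibble::tibble(gene_id = res$gene_id, homolog_count = 3L)
  p <- classify_pne(res, hom)
  expect_equal(p$n_pne, 2)
  expect_equal(p$percent, 100 * 2 / 94, tolerance = 1e-12)
  # no nonessential genes: proportion undefined
  p2 <- classify_pne(res[res$essential, ], hom)
  expect_true(is.na(p2$proportion))
})

test_that("PNE classification is invariant to gene order", {
  set.seed(12)
  base <- classify_pne(pne_input(), hom_input())$records
  for (i in 1:5) {
    shuffled <- pne_input()[sample(5), ]
    expect_identical(classify_pne(shuffled, hom_input())$records, base)
  }
})

cog_input <- function(n_e = 8, n_ne = 8, letter = "J", organism = "orgA",
                      ess_lo = TRUE) {
  ratios_e <- seq(0.01, 0.05, length.out = n_e)
  ratios_ne <- seq(0.3, 0.5, length.out = n_ne)
  if (!ess_lo) {
    tmp <- ratios_e; ratios_e <- ratios_ne; ratios_ne <- tmp
  }
  tibble::tibble(
    organism_id = organism,
    essential = c(rep(TRUE, n_e), rep(FALSE, n_ne)),
    kaks = c(ratios_e, ratios_ne),
    cog_letters = as.list(rep(letter, n_e + n_ne))
  )
}

test_that("fully separated categories are called in the right direction", {
  m <- cog_significance_matrix(cog_input(5, 5, "J"))
  expect_equal(nrow(m), 1)
  # complete separation at 5 vs 5: exact p = 2 / C(10, 5) < 0.01
  expect_equal(m$p_value, 2 / choose(10, 5), tolerance = 1e-9)
  expect_equal(m$direction, "essential_conserved")

  m2 <- cog_significance_matrix(cog_input(5, 5, "J", ess_lo = FALSE))
  expect_equal(m2$direction, "nonessential_conserved")
})

test_that("cells above alpha get direction none", {
  # complete separation at 2 vs 2 gives exact p = 2/6 = 1/3 > 0.01
  m <- cog_significance_matrix(cog_input(2, 2, "K"))
  expect_equal(m$direction, "none")
  # but is significant at a permissive alpha
  m2 <- cog_significance_matrix(cog_input(2, 2, "K"), alpha = 0.5)
  expect_equal(m2$direction, "essential_conserved")
})

test_that("multi-letter genes count in every category; R and S are dropped", {
  d <- cog_input(8, 8, "J")
  d$cog_letters <- rep(list(c("J", "L")), 16)
  m <- cog_significance_matrix(d)
  expect_setequal(m$category, c("J", "L"))
  expect_true(all(m$direction == "essential_conserved"))

  d$cog_letters <- rep(list(c("R", "S")), 16)
  expect_equal(nrow(cog_significance_matrix(d)), 0)
})

test_that("a category with an empty class yields an NA cell", {
  d <- cog_input(4, 4, "J")
  d$cog_letters[d$essential] <- list("L") # L has no nonessential genes
  m <- cog_significance_matrix(d)
  l_cell <- m[m$category == "L", ]
  expect_true(is.na(l_cell$p_value))
  expect_equal(l_cell$direction, "none")
  # genes without a defined ratio never enter the tests
  d2 <- cog_input(4, 4, "J")
  d2$kaks[1] <- NA
  m2 <- cog_significance_matrix(d2)
  expect_equal(m2$n_essential[m2$category == "J"], 3)
})

test_that("matrix cells are order-independent", {
  set.seed(33)
  d <- dplyr::bind_rows(cog_input(6, 6, "J"), cog_input(5, 7, "L"))
  ref <- cog_significance_matrix(d)
  for (i in 1:4) {
    expect_identical(cog_significance_matrix(d[sample(nrow(d)), ]), ref)
  }
})

test_that("the conserved-subcategory rule takes a strict majority of all organisms", {
  cell <- function(org, letter, dir) {
    tibble::tibble(organism_id = org, category = letter,
                   n_essential = 5, n_nonessential = 5,
                   p_value = ifelse(dir == "none", 0.5, 0.001),
                   direction = dir)
  }
  m <- dplyr::bind_rows(
    lapply(1:12, function(i) cell(paste0("o", i), "J", "essential_conserved")),
    lapply(13:22, function(i) cell(paste0("o", i), "J", "none")),
    lapply(1:11, function(i) cell(paste0("o", i), "L", "essential_conserved")),
    lapply(12:22, function(i) cell(paste0("o", i), "L", "none"))
  )
  # 12 of 22 organisms: conserved; 11 of 22: not (strict majority)
  expect_equal(conserved_subcategories(m, 22), "J")

  # opposite-direction cells do not subtract: 15 conserved + 2 opposite of 22
  m2 <- dplyr::bind_rows(
    lapply(1:15, function(i) cell(paste0("o", i), "H", "essential_conserved")),
    lapply(16:17, function(i) cell(paste0("o", i), "H",
                                   "nonessential_conserved"))
  )
  expect_equal(conserved_subcategories(m2, 22), "H")
})
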
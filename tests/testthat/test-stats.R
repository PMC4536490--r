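test_that("MWU exact p matches hand enumeration on the separated 3v3 case", {
  r <- mwu_test(c(0.05, 0.06, 0.07), c(0.2, 0.3, 0.4))
  # complete separation: 2 of the C(6,3)=20 rank arrangements are as extreme
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact")
})

test_that("MWU agrees with exhaustive permutation enumeration for small n", {
  set.seed(21)
  sizes <- list(c(1, 1), c(2, 3), c(3, 3), c(4, 4), c(5, 5), c(3, 7))
  for (sz in sizes) {
    for (rep in 1:5) {
      # draws from a small integer pool guarantee ties
      x <- sample(1:4, sz[1], replace = TRUE)
      y <- sample(1:4, sz[2], replace = TRUE)
      expect_equal(mwu_test(x, y)$p_value, oracle_mwu_p(x, y),
                   info = paste(sz, collapse = "v"))
    }
  }
})

test_that("MWU agrees with wilcox.test exact p for tie-free samples", {
  set.seed(22)
  x <- rnorm(5); y <- rnorm(5) + 1
  expect_equal(mwu_test(x, y)$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value)
})

test_that("MWU large-sample path is two-sided and tie-corrected", {
  set.seed(23)
  x <- rnorm(30); y <- rnorm(40) + 0.8
  r <- mwu_test(x, y)
  expect_equal(r$method, "normal")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
  # identical constant samples: variance 0, p = 1
  expect_equal(mwu_test(rep(1, 8), rep(1, 9))$p_value, 1)
})

test_that("summarize_organism applies the per-metric inclusion rules", {
  results <- tibble::tibble(
    organism_id = "orgA",
    essential = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    ka = c(0.05, 0.06, 0.07, 0.2, 0.3, 0.4),
    ks = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    kaks = c(0.05, 0.06, 0.07, 0.2, 0.3, 0.4),
    valid_ka = TRUE, valid_ks = TRUE
  )
  s <- summarize_organism(results)
  kk <- s[s$metric == "KaKs", ]
  expect_equal(kk$mean_essential, 0.06)
  expect_equal(kk$mean_nonessential, 0.3)
  expect_equal(kk$p_value, 0.1) # exact MWU on 3 vs 3

  # a nonessential gene with undefined ratio leaves the ratio mean
  # but stays in the Ka mean (zero-variation genes carry value 0)
  results$kaks[4] <- NA
  results$ka[4] <- 0
  s2 <- summarize_organism(results)
  kk2 <- s2[s2$metric == "KaKs", ]
  expect_equal(kk2$mean_nonessential, 0.35)
  expect_equal(kk2$n_nonessential, 2)
  expect_equal(s2$mean_nonessential[s2$metric == "Ka"], mean(c(0, 0.3, 0.4)))

  # identical value sets: equal means, p = 1
  same <- tibble::tibble(
    essential = rep(c(TRUE, FALSE), each = 3),
    ka = rep(c(0.1, 0.2, 0.3), 2), ks = rep(c(0.1, 0.2, 0.3), 2),
    kaks = rep(c(0.1, 0.2, 0.3), 2), valid_ka = TRUE, valid_ks = TRUE
  )
  s3 <- summarize_organism(same, "orgB")
  expect_equal(s3$mean_essential, s3$mean_nonessential)
  expect_true(all(s3$p_value == 1))

  # empty class: NA summary with one warning per metric
  w <- testthat::capture_warnings(
    s4 <- summarize_organism(results[results$essential, ], "orgC")
  )
  expect_length(w, 3)
  expect_true(all(grepl("empty class", w)))
  expect_true(all(is.na(s4$p_value)))
})

test_that("bootstrap draws half-size resamples reproducibly", {
  b <- bootstrap_means(rep(0.2, 10), reps = 50, seed = 1)
  expect_true(all(b$replicate_means == 0.2))
  expect_equal(b$half_n, 5)

  b2 <- bootstrap_means(rnorm(101), reps = 1000, seed = 9)
  expect_length(b2$replicate_means, 1000)
  expect_equal(b2$half_n, 50)
  # determinism: a fixed seed fixes the draw
  v <- rnorm(30)
  expect_identical(bootstrap_means(v, 200, seed = 4)$replicate_means,
                   bootstrap_means(v, 200, seed = 4)$replicate_means)
  # replicate means stay within the data range
  bb <- bootstrap_means(v, 200, seed = 5)
  expect_true(all(bb$replicate_means >= min(v) & bb$replicate_means <= max(v)))
  # a single value resamples itself
  expect_equal(bootstrap_means(0.7, reps = 10, seed = 2)$half_n, 1)
  expect_error(bootstrap_means(1:5, reps = 0), "positive")
})

test_that("bootstrap grand mean concentrates at the data mean", {
  b <- bootstrap_means(rep(c(0, 1), 50), reps = 10000, seed = 3)
  expect_lt(abs(mean(b$replicate_means) - 0.5), 0.02)
})

test_that("bootstrap intervals bracket the true mean in most experiments", {
  # loose anti-bug coverage check, not a calibration claim
  set.seed(31)
  covered <- vapply(1:40, function(i) {
    v <- rnorm(25, mean = 2)
    q <- stats::quantile(bootstrap_means(v, reps = 300)$replicate_means,
                         c(0.025, 0.975))
    q[1] <= 2 && 2 <= q[2]
  }, logical(1))
  expect_gte(mean(covered), 0.8)
})

test_that("cross-organism t-test matches the one-sample closed form", {
  summaries <- tibble::tibble(
    organism_id = paste0("o", 1:4), metric = "KaKs",
    mean_essential = c(0.1, 0.1, 0.1, 0.1),
    mean_nonessential = c(0.2, 0.3, 0.4, 0.5),
    p_value = NA, n_essential = 10, n_nonessential = 10
  )
  r <- cross_organism_ttest(summaries, "KaKs")
  d <- c(0.1, 0.2, 0.3, 0.4) # nonessential - essential
  t_ref <- -mean(d) / (stats::sd(d) / sqrt(4))
  expect_equal(r$statistic, t_ref)
  expect_equal(r$p_value, 2 * stats::pt(-abs(t_ref), df = 3))

  # antisymmetry: swapping the classes flips t, keeps p
  swapped <- summaries
  swapped$mean_essential <- summaries$mean_nonessential
  swapped$mean_nonessential <- summaries$mean_essential
  r2 <- cross_organism_ttest(swapped, "KaKs")
  expect_equal(r2$statistic, -r$statistic)
  expect_equal(r2$p_value, r$p_value)

  # equal means: degenerate limit t = 0, p = 1
  eq <- summaries
  eq$mean_nonessential <- eq$mean_essential
  r3 <- cross_organism_ttest(eq, "KaKs")
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p_value, 1)

  expect_error(cross_organism_ttest(summaries[1:2, ], "KaKs"), "at least 3")
})
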
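# Per-organism essential-vs-nonessential statistics: Mann-Whitney U tests,
# class means, the half-sampling bootstrap and the cross-organism paired
# t-test.

# Run expr with a temporarily-seeded RNG, restoring the caller's RNG state.
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. For small samples
#' (`n1 + n2 <= exact_limit`) the p-value is computed by exhaustive
#' enumeration of all group assignments of the (mid)ranks — exact even in the
#' presence of ties; larger samples use the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param x,y Numeric samples for the two groups.
#' @param exact_limit Largest combined sample size for exhaustive
#'   enumeration (default 10).
#' @return A list with `statistic` (U for the `x` sample), `p_value`, and
#'   `method` (`"exact"` or `"normal"`).
#' @export
mwu_test <- function(x, y, exact_limit = 10) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L) {
    return(list(statistic = NA_real_, p_value = NA_real_, method = "none"))
  }
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  if (m + n <= exact_limit) {
    idx <- utils::combn(m + n, m)
    Uperm <- colSums(matrix(r[idx], nrow = m)) - m * (m + 1) / 2
    p <- mean(abs(Uperm - mu) >= abs(U - mu) - 1e-9)
    return(list(statistic = U, p_value = p, method = "exact"))
  }
  N <- m + n
  ties <- table(r)
  sigma2 <- (m * n / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) {
    return(list(statistic = U, p_value = 1, method = "normal"))
  }
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  list(statistic = U, p_value = p, method = "normal")
}

#' Summarize essential-vs-nonessential conservation in one organism
#'
#' For each metric (Ka, Ks, Ka/Ks) computes the essential-class and
#' nonessential-class means and a two-sided Mann-Whitney U p-value on the
#' per-gene values. Ka and Ks means include zero-variation genes (value 0);
#' Ka/Ks means cover only genes with a defined ratio (valid Ka and Ks with
#' Ks > 0). Genes with an invalid metric are excluded from that metric.
#'
#' @param results Per-gene tibble with columns `essential`, `ka`, `ks`,
#'   `kaks`, `valid_ka`, `valid_ks` (e.g. the Ka/Ks stage output of
#'   [run_pipeline()]).
#' @param organism_id Optional organism label; taken from an `organism_id`
#'   column when present.
#' @return Tibble with one row per metric: `organism_id`, `metric`,
#'   `mean_essential`, `mean_nonessential`, `p_value`, `n_essential`,
#'   `n_nonessential`. Empty classes yield `NA` with a warning.
#' @export
summarize_organism <- function(results, organism_id = NULL) {
  results <- tibble::as_tibble(results)
  if (is.null(organism_id)) {
    organism_id <- if ("organism_id" %in% names(results)) {
      results$organism_id[1]
    } else {
      NA_character_
    }
  }
  metric_values <- list(
    Ka = function(d) d$ka[d$valid_ka],
    Ks = function(d) d$ks[d$valid_ks],
    KaKs = function(d) d$kaks[!is.na(d$kaks)]
  )
  ess <- results[results$essential, ]
  non <- results[!results$essential, ]
  purrr::imap_dfr(metric_values, function(getter, metric) {
    ve <- getter(ess); vn <- getter(non)
    if (!length(ve) || !length(vn)) {
      warning("organism ", organism_id, ": empty class for metric ", metric,
              call. = FALSE)
      return(tibble::tibble(
        organism_id = organism_id, metric = metric,
        mean_essential = if (length(ve)) mean(ve) else NA_real_,
        mean_nonessential = if (length(vn)) mean(vn) else NA_real_,
        p_value = NA_real_,
        n_essential = length(ve), n_nonessential = length(vn)
      ))
    }
    mw <- mwu_test(ve, vn)
    tibble::tibble(
      organism_id = organism_id, metric = metric,
      mean_essential = mean(ve), mean_nonessential = mean(vn),
      p_value = mw$p_value,
      n_essential = length(ve), n_nonessential = length(vn)
    )
  })
}

#' Half-sampling bootstrap of a metric mean
#'
#' Each replicate draws `floor(n/2)` values (minimum 1) with replacement
#' from the input and records their mean — the resampling scheme used to
#' guard the class means against extreme values. Genes with an invalid
#' metric must already be excluded.
#'
#' @param values Numeric vector of per-gene metric values.
#' @param reps Number of replicates (default 1000).
#' @param seed Optional integer seed; fixed seed gives identical replicates.
#' @return A list of class `bootstrap_result`: `replicate_means`, `reps`,
#'   `half_n`, `n`, `seed`.
#' @export
bootstrap_means <- function(values, reps = 1000, seed = NULL) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to resample", call. = FALSE)
  if (reps <= 0) stop("reps must be positive", call. = FALSE)
  half_n <- max(1L, length(values) %/% 2L)
  means <- with_rng_seed(seed, {
    vapply(seq_len(reps), function(i) {
      mean(sample(values, half_n, replace = TRUE))
    }, numeric(1))
  })
  structure(
    list(replicate_means = means, reps = as.integer(reps), half_n = half_n,
         n = length(values), seed = seed),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result>", x$reps, "replicates of", x$half_n, "of", x$n,
      "values (with replacement)\n")
  cat("  mean of replicate means:", format(mean(x$replicate_means)), "\n")
  invisible(x)
}

#' @rdname bootstrap_means
#' @param x A `bootstrap_result`.
#' @param ... Unused.
#' @export
tidy.bootstrap_result <- function(x, ...) {
  tibble::tibble(replicate = seq_len(x$reps),
                 replicate_mean = x$replicate_means)
}

#' @rdname bootstrap_means
#' @export
glance.bootstrap_result <- function(x, ...) {
  q <- stats::quantile(x$replicate_means, c(0.025, 0.975), names = FALSE)
  tibble::tibble(
    n = x$n, half_n = x$half_n, reps = x$reps,
    mean = mean(x$replicate_means),
    conf_low = q[1], conf_high = q[2]
  )
}

#' Paired t-test of class means across organisms
#'
#' Two-sided paired Student's t-test of the essential-class versus
#' nonessential-class mean of one metric, pairing by organism — the
#' cross-organism test of whether essential genes are systematically more
#' conserved.
#'
#' @param summaries Tibble of per-organism summaries
#'   (rows from [summarize_organism()]).
#' @param metric One of `"Ka"`, `"Ks"`, `"KaKs"`.
#' @return One-row tibble: `metric`, `statistic` (t), `df`, `p_value`,
#'   `n_organisms`.
#' @export
cross_organism_ttest <- function(summaries, metric = c("KaKs", "Ka", "Ks")) {
  metric <- match.arg(metric)
  d <- summaries |>
    dplyr::filter(.data$metric == !!metric,
                  !is.na(.data$mean_essential),
                  !is.na(.data$mean_nonessential))
  if (nrow(d) < 3) {
    stop("paired t-test needs at least 3 organisms with both class means; ",
         "got ", nrow(d), call. = FALSE)
  }
  diffs <- d$mean_essential - d$mean_nonessential
  if (isTRUE(all.equal(stats::sd(diffs), 0)) || stats::sd(diffs) == 0) {
    # degenerate: constant differences (t.test refuses); the limit is exact
    t_stat <- if (mean(diffs) == 0) 0 else sign(mean(diffs)) * Inf
    p <- if (mean(diffs) == 0) 1 else 0
    return(tibble::tibble(metric = metric, statistic = t_stat,
                          df = length(diffs) - 1, p_value = p,
                          n_organisms = nrow(d)))
  }
  tt <- stats::t.test(d$mean_essential, d$mean_nonessential, paired = TRUE)
  tibble::tibble(
    metric = metric,
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    n_organisms = nrow(d)
  )
}
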
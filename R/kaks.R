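# Nei-Gojobori (1986) pathway-counting Ka/Ks estimator.
#
# Site counts are accumulated in exact integer units (thirds for site
# fractions, sixtieths for pathway-averaged differences: every per-codon
# average has a denominator dividing 60 = lcm(1..6)) and converted to floating
# point only at the Jukes-Cantor step, so results are bit-stable.

.kaks_cache <- new.env(parent = emptyenv())

# All permutations of 1..n for n <= 3 (pathway orderings).
.perms <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

#' Synonymous and nonsynonymous site fractions of a codon
#'
#' For each of the three codon positions, the fraction of the three possible
#' single-nucleotide changes that are synonymous contributes to `s`; the
#' remainder contributes to `n`, so `s + n = 3` exactly. Changes that create a
#' stop codon count as nonsynonymous.
#'
#' @param codon A sense codon (3 nucleotides over A, C, G, T).
#' @param code A [genetic_code()] object or table id.
#' @return Named numeric vector `c(s = , n = )`. A codon containing an
#'   ambiguous base or gap character returns `c(s = NA, n = NA)` (uncountable;
#'   callers exclude such columns).
#' @examples
#' codon_site_fractions("TTT")  # s = 1/3
#' codon_site_fractions("CTT")  # s = 1 (third position fully synonymous)
#' @export
codon_site_fractions <- function(codon, code = genetic_code(11)) {
  code <- as_genetic_code(code)
  codon <- toupper(codon)
  if (!codon %in% code$codons) {
    return(c(s = NA_real_, n = NA_real_))
  }
  if (codon %in% code$stops) {
    stop("codon ", codon, " is a stop codon in table ", code$table_id,
         call. = FALSE)
  }
  tab <- ng86_tables(code)
  i <- match(codon, tab$codons)
  c(s = tab$syn_thirds[i] / 3, n = (9L - tab$syn_thirds[i]) / 3)
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' Differences at k positions are resolved by averaging the
#' synonymous/nonsynonymous step classification over the k! mutational
#' orderings. Under the default policy, orderings passing through a stop-codon
#' intermediate are excluded from the average; if every ordering is excluded
#' the average falls back to all orderings (stop-involving steps classed as
#' nonsynonymous).
#'
#' @param codon_a,codon_b Sense codons.
#' @inheritParams codon_site_fractions
#' @param stop_policy `"exclude"` (default: drop orderings through stop
#'   intermediates, with all-excluded fallback) or `"include"` (average over
#'   all orderings).
#' @return Named numeric vector `c(sd = , nd = )`; `sd + nd` equals the number
#'   of differing positions exactly.
#' @examples
#' pathway_differences("TTT", "GTA")  # c(sd = 0.5, nd = 1.5)
#' @export
pathway_differences <- function(codon_a, codon_b, code = genetic_code(11),
                                stop_policy = c("exclude", "include")) {
  code <- as_genetic_code(code)
  stop_policy <- match.arg(stop_policy)
  tab <- ng86_tables(code, stop_policy)
  ia <- match(toupper(codon_a), tab$codons)
  ib <- match(toupper(codon_b), tab$codons)
  if (is.na(ia) || is.na(ib) ||
      !toupper(codon_a) %in% code$sense || !toupper(codon_b) %in% code$sense) {
    stop("pathway_differences() requires two sense codons", call. = FALSE)
  }
  c(sd = tab$sd60[ia, ib] / 60, nd = tab$nd60[ia, ib] / 60)
}

#' Jukes-Cantor correction for multiple hits
#'
#' Converts an observed proportion of differences per site into an estimated
#' number of substitutions per site: `d = -(3/4) log(1 - 4p/3)`.
#'
#' @param p Proportion(s) of differences, `0 <= p`. Values at or above 3/4 are
#'   outside the model's domain and return `NA` (the caller marks the gene's
#'   Ka or Ks invalid and excludes it downstream).
#' @return Corrected distance(s), `NA` where undefined.
#' @examples
#' jukes_cantor(0.5)  # 0.75 * log(3)
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0, na.rm = TRUE)) stop("p must be non-negative", call. = FALSE)
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  out
}

# Precomputed per-code NG86 lookup tables, memoised by (table_id, policy).
#   syn_thirds: integer, 3*s per codon (NA for stops)
#   sd60, nd60: 64x64 integer matrices, 60 * pathway-averaged sd/nd
ng86_tables <- function(code, stop_policy = "exclude") {
  code <- as_genetic_code(code)
  key <- paste0("t", code$table_id, "_", stop_policy)
  if (!is.null(.kaks_cache[[key]])) return(.kaks_cache[[key]])

  codons <- code$codons
  aa <- code$aa
  nts <- c("A", "C", "G", "T")
  cmat <- do.call(rbind, strsplit(codons, ""))

  # site fractions: count synonymous single-nt changes per codon (units of 1/3)
  syn_thirds <- rep(NA_integer_, 64L)
  for (i in seq_along(codons)) {
    if (aa[i] == "*") next
    cnt <- 0L
    for (pos in 1:3) {
      for (nt in setdiff(nts, cmat[i, pos])) {
        mut <- cmat[i, ]
        mut[pos] <- nt
        maa <- aa[[paste(mut, collapse = "")]]
        # change to a stop codon counts as nonsynonymous
        if (maa != "*" && maa == aa[i]) cnt <- cnt + 1L
      }
    }
    syn_thirds[i] <- cnt
  }

  # pathway-averaged differences for every ordered sense-codon pair
  sd60 <- matrix(NA_integer_, 64L, 64L, dimnames = list(codons, codons))
  nd60 <- sd60
  step_class <- function(from, to) {
    # 1 = synonymous, 0 = nonsynonymous (stop-involving steps nonsynonymous)
    fa <- aa[[from]]; ta <- aa[[to]]
    if (fa != "*" && fa == ta) 1L else 0L
  }
  for (i in seq_along(codons)) {
    if (aa[i] == "*") next
    for (j in seq_along(codons)) {
      if (aa[j] == "*") next
      diffpos <- which(cmat[i, ] != cmat[j, ])
      k <- length(diffpos)
      if (k == 0L) {
        sd60[i, j] <- 0L; nd60[i, j] <- 0L
        next
      }
      sd_sum_ok <- 0L; nd_sum_ok <- 0L; n_ok <- 0L
      sd_sum_all <- 0L; nd_sum_all <- 0L
      for (ord in .perms[[k]]) {
        cur <- cmat[i, ]
        sd_i <- 0L; nd_i <- 0L; through_stop <- FALSE
        for (step in seq_len(k)) {
          pos <- diffpos[ord[step]]
          nxt <- cur
          nxt[pos] <- cmat[j, pos]
          from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
          if (step_class(from, to) == 1L) sd_i <- sd_i + 1L else nd_i <- nd_i + 1L
          if (step < k && aa[[to]] == "*") through_stop <- TRUE
          cur <- nxt
        }
        sd_sum_all <- sd_sum_all + sd_i; nd_sum_all <- nd_sum_all + nd_i
        if (!through_stop) {
          sd_sum_ok <- sd_sum_ok + sd_i; nd_sum_ok <- nd_sum_ok + nd_i
          n_ok <- n_ok + 1L
        }
      }
      if (stop_policy == "exclude" && n_ok > 0L) {
        sd60[i, j] <- as.integer(sd_sum_ok * (60L / n_ok))
        nd60[i, j] <- as.integer(nd_sum_ok * (60L / n_ok))
      } else {
        n_all <- length(.perms[[k]])
        sd60[i, j] <- as.integer(sd_sum_all * (60L / n_all))
        nd60[i, j] <- as.integer(nd_sum_all * (60L / n_all))
      }
    }
  }

  tab <- list(codons = codons, aa = aa, syn_thirds = syn_thirds,
              sd60 = sd60, nd60 = nd60,
              sense = match(code$sense, codons))
  .kaks_cache[[key]] <- tab
  tab
}

# Numeric core shared by compute_kaks() and kaks_table(): takes codon
# character vectors, returns an unnamed numeric vector
# (n_codons, S, N, Sd, Nd, pS, pN, ka, ks, kaks, valid_ka, valid_ks, valid,
# zero_variation) or NULL when no column is countable.
ng86_core <- function(a, b, tab) {
  ia <- match(a, tab$codons)
  ib <- match(b, tab$codons)
  ok_a <- !is.na(ia); ok_b <- !is.na(ib)
  countable <- ok_a & ok_b
  countable[countable] <- !is.na(tab$syn_thirds[ia[countable]]) &
    !is.na(tab$syn_thirds[ib[countable]])
  ia <- ia[countable]; ib <- ib[countable]
  m <- length(ia)
  if (m == 0L) return(NULL)
  S <- (sum(tab$syn_thirds[ia]) + sum(tab$syn_thirds[ib])) / 6
  N <- 3 * m - S
  Sd <- sum(tab$sd60[cbind(ia, ib)]) / 60
  Nd <- sum(tab$nd60[cbind(ia, ib)]) / 60
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  valid_ks <- !is.na(pS) && pS < 0.75
  valid_ka <- !is.na(pN) && pN < 0.75
  ks <- if (valid_ks) -0.75 * log(1 - 4 * pS / 3) else NA_real_
  ka <- if (valid_ka) -0.75 * log(1 - 4 * pN / 3) else NA_real_
  kaks <- if (valid_ka && valid_ks && ks > 0) ka / ks else NA_real_
  c(m, S, N, Sd, Nd, pS, pN, ka, ks, kaks,
    valid_ka, valid_ks, valid_ka && valid_ks, Sd == 0 && Nd == 0)
}

kaks_core_names <- c("n_codons", "S", "N", "Sd", "Nd", "pS", "pN", "ka",
                     "ks", "kaks", "valid_ka", "valid_ks", "valid",
                     "zero_variation")

kaks_core_tibble <- function(mat) {
  out <- tibble::as_tibble(as.data.frame(mat))
  names(out) <- kaks_core_names
  out$n_codons <- as.integer(out$n_codons)
  for (cl in c("valid_ka", "valid_ks", "valid", "zero_variation")) {
    out[[cl]] <- !is.na(out[[cl]]) & out[[cl]] > 0
  }
  out
}

#' Nei-Gojobori Ka/Ks for one codon alignment
#'
#' Columns containing a gap, an ambiguous base or a stop codon are excluded.
#' Synonymous (S) and nonsynonymous (N) site totals are the average of the two
#' sequences' per-codon site fractions over the counted columns; observed
#' differences Sd, Nd are summed via [pathway_differences()]; proportions
#' `pS = Sd/S`, `pN = Nd/N` are Jukes-Cantor corrected to Ks and Ka. The ratio
#' Ka/Ks is defined only when both corrections are valid (`p < 3/4` with a
#' positive site total) and `Ks > 0`.
#'
#' @param ca A [codon_alignment()] (or any list with character vectors
#'   `codons_a` and `codons_b` of equal length; gaps as `"---"`).
#' @inheritParams pathway_differences
#' @return A one-row tibble (class `kaks_result`): `n_codons`, `S`, `N`, `Sd`,
#'   `Nd`, `pS`, `pN`, `ka`, `ks`, `kaks`, `valid_ka`, `valid_ks`, `valid`,
#'   `zero_variation`.
#' @examples
#' ca <- codon_alignment(c("TTT", "CTT", "CTC", "GGG"),
#'                       c("TTC", "CTT", "CTC", "GGG"))
#' compute_kaks(ca)
#' @export
compute_kaks <- function(ca, code = genetic_code(11),
                         stop_policy = c("exclude", "include")) {
  code <- as_genetic_code(code)
  stop_policy <- match.arg(stop_policy)
  tab <- ng86_tables(code, stop_policy)
  a <- toupper(ca$codons_a)
  b <- toupper(ca$codons_b)
  if (length(a) != length(b)) {
    stop("codon alignment rows have unequal length", call. = FALSE)
  }
  core <- ng86_core(a, b, tab)
  if (is.null(core)) {
    stop("no countable codon columns (all gapped, ambiguous or stop)",
         call. = FALSE)
  }
  out <- kaks_core_tibble(matrix(core, nrow = 1))
  class(out) <- c("kaks_result", class(out))
  out
}
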
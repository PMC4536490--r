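# Independent brute-force oracles, written without reusing any package
# internals: translation comes straight from Biostrings::getGeneticCode and
# every enumeration is spelled out naively.

oracle_code <- function(id = "11") Biostrings::getGeneticCode(as.character(id))

oracle_mutants <- function(codon) {
  # all nine single-nucleotide neighbors of a codon
  out <- character(0)
  for (pos in 1:3) {
    for (nt in c("A", "C", "G", "T")) {
      if (substr(codon, pos, pos) != nt) {
        m <- codon
        substr(m, pos, pos) <- nt
        out <- c(out, m)
      }
    }
  }
  out
}

oracle_site_fractions <- function(codon, gc = oracle_code()) {
  syn <- 0
  for (m in oracle_mutants(codon)) {
    if (gc[[m]] != "*" && gc[[m]] == gc[[codon]]) syn <- syn + 1
  }
  c(s = syn / 3, n = (9 - syn) / 3)
}

oracle_orderings <- function(v) {
  # all permutations of v, by naive recursion
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_orderings(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

oracle_pathway <- function(a, b, gc = oracle_code(), exclude_stops = TRUE) {
  diffpos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(diffpos)) return(c(sd = 0, nd = 0))
  walk <- function(ord) {
    cur <- a
    sd <- 0; nd <- 0; stopped <- FALSE
    for (k in seq_along(ord)) {
      nxt <- cur
      substr(nxt, ord[k], ord[k]) <- substr(b, ord[k], ord[k])
      if (gc[[cur]] != "*" && gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      if (k < length(ord) && gc[[nxt]] == "*") stopped <- TRUE
      cur <- nxt
    }
    list(sd = sd, nd = nd, stopped = stopped)
  }
  walks <- lapply(oracle_orderings(diffpos), walk)
  ok <- if (exclude_stops) Filter(function(w) !w$stopped, walks) else walks
  if (!length(ok)) ok <- walks
  c(sd = mean(vapply(ok, `[[`, 0, "sd")),
    nd = mean(vapply(ok, `[[`, 0, "nd")))
}

oracle_jc <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -3 / 4 * log(1 - 4 * p / 3)
}

# Whole-pipeline oracle on two codon vectors (no gaps/ambiguity assumed
# beyond what the countable filter removes).
oracle_kaks <- function(cods_a, cods_b, gc = oracle_code()) {
  keep <- logical(length(cods_a))
  for (i in seq_along(cods_a)) {
    keep[i] <- cods_a[i] %in% names(gc) && cods_b[i] %in% names(gc) &&
      gc[[cods_a[i]]] != "*" && gc[[cods_b[i]]] != "*"
  }
  a <- cods_a[keep]; b <- cods_b[keep]
  if (!length(a)) return(NULL)
  Sa <- 0; Sb <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(a)) {
    Sa <- Sa + oracle_site_fractions(a[i], gc)[["s"]]
    Sb <- Sb + oracle_site_fractions(b[i], gc)[["s"]]
    pw <- oracle_pathway(a[i], b[i], gc)
    Sd <- Sd + pw[["sd"]]; Nd <- Nd + pw[["nd"]]
  }
  S <- (Sa + Sb) / 2
  N <- 3 * length(a) - S
  pS <- if (S > 0) Sd / S else NA
  pN <- if (N > 0) Nd / N else NA
  ks <- oracle_jc(pS); ka <- oracle_jc(pN)
  kaks <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       ka = ka, ks = ks, kaks = kaks)
}

# Two-sided Mann-Whitney p by exhaustive bitmask enumeration of all group
# assignments (midranks).
oracle_mwu_p <- function(x, y) {
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  u_of <- function(sel) sum(r[sel]) - m * (m + 1) / 2
  u_obs <- u_of(seq_len(m))
  dev_obs <- abs(u_obs - m * n / 2)
  hits <- 0; total <- 0
  for (mask in 0:(2^N - 1)) {
    sel <- which(bitwAnd(bitwShiftR(mask, 0:(N - 1)), 1L) == 1L)
    if (length(sel) != m) next
    total <- total + 1
    if (abs(u_of(sel) - m * n / 2) >= dev_obs - 1e-9) hits <- hits + 1
  }
  hits / total
}

# Brute-force optimal global alignment score by enumerating every alignment
# (op strings over M / gap-in-a / gap-in-b), affine gaps charged
# opening + extension * run_length per gap run.
oracle_align_score <- function(a, b, submat, gap_opening, gap_extension) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, ops) {
    if (i > length(ca) && j > length(cb)) {
      s <- 0; run <- ""
      ii <- 1; jj <- 1
      for (op in ops) {
        if (op == "M") {
          s <- s + submat[ca[ii], cb[jj]]; ii <- ii + 1; jj <- jj + 1
        } else {
          s <- s - gap_extension - if (op != run) gap_opening else 0
          if (op == "A") jj <- jj + 1 else ii <- ii + 1
        }
        run <- op
      }
      best <<- max(best, s)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) rec(i + 1, j + 1, c(ops, "M"))
    if (j <= length(cb)) rec(i, j + 1, c(ops, "A")) # gap in a
    if (i <= length(ca)) rec(i + 1, j, c(ops, "B")) # gap in b
  }
  rec(1, 1, character(0))
  best
}

# random sense-codon vector for property tests
random_sense_codons <- function(n, gc = oracle_code()) {
  sample(names(gc)[gc != "*"], n, replace = TRUE)
}
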
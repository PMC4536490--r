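# Ortholog pairing: best-hit selection from BLAST-tabular hits (the rule used
# with real data) and a built-in all-vs-all global-alignment pairer for
# offline/synthetic inputs.

#' Select the best orthologous hit per query
#'
#' Hits with `evalue >= evalue_max` are discarded; among the survivors each
#' query keeps the hit with the highest bit score. Ties are broken by lower
#' e-value, then by lexicographically smallest subject id, so the result is
#' independent of input order. Queries with no surviving hit are absent.
#'
#' @param hits Tibble of hits as returned by [read_hit_table()] or
#'   [built_in_pairing()].
#' @param evalue_max E-value threshold (default `1e-5`, strict `<`).
#' @return Tibble with one row per retained query: `query_id`, `subject_id`,
#'   `bit_score`, `evalue`, `percent_identity`, `aligned_fraction` (query
#'   residues aligned / query length, when query length is derivable from the
#'   hit, else `NA`), sorted by `query_id`.
#' @export
select_best_hits <- function(hits, evalue_max = 1e-5) {
  hits <- tibble::as_tibble(hits)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(
      query_id = character(0), subject_id = character(0),
      bit_score = numeric(0), evalue = numeric(0),
      percent_identity = numeric(0), aligned_fraction = numeric(0)
    ))
  }
  af <- if ("aligned_fraction" %in% names(hits)) {
    hits$aligned_fraction
  } else {
    rep(NA_real_, nrow(hits))
  }
  hits$aligned_fraction <- af
  hits |>
    dplyr::filter(.data$evalue < evalue_max) |>
    dplyr::arrange(.data$query_id, dplyr::desc(.data$bit_score),
                   .data$evalue, .data$subject_id) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE) |>
    dplyr::select("query_id", "subject_id", "bit_score", "evalue",
                  "percent_identity", "aligned_fraction")
}

#' All-vs-all protein pairing by global alignment
#'
#' Offline substitute for an external BLASTP search: aligns every query
#' protein against every subject protein with the package's global aligner
#' and emits one BLAST-tabular-style hit per pair whose alignment score
#' exceeds `score_floor`. The `bit_score` column carries the raw alignment
#' score and `evalue` a simple length-normalized transform of it
#' (`m * n * 2^(-score/2)`), monotone in the score; it is a ranking device,
#' not a BLAST statistic.
#'
#' @param query_proteins,subject_proteins Named character vectors of protein
#'   sequences.
#' @param scoring A [protein_scoring()] list.
#' @param score_floor Minimum alignment score for a pair to be reported.
#' @return Tibble in [read_hit_table()] layout plus an `aligned_fraction`
#'   column (fraction of query residues aligned opposite a subject residue).
#' @export
built_in_pairing <- function(query_proteins, subject_proteins,
                             scoring = protein_scoring(), score_floor = 50) {
  if (!length(query_proteins) || !length(subject_proteins)) {
    stop("empty protein set", call. = FALSE)
  }
  if (any(!nzchar(query_proteins)) || any(!nzchar(subject_proteins))) {
    stop("empty protein sequence", call. = FALSE)
  }
  grid <- tidyr::expand_grid(q = names(query_proteins),
                             s = names(subject_proteins))
  rows <- purrr::pmap(grid, function(q, s) {
    al <- align_protein_pair(query_proteins[[q]], subject_proteins[[s]],
                             scoring)
    if (al$score <= score_floor) return(NULL)
    ca <- strsplit(al$aligned_a, "")[[1]]
    cb <- strsplit(al$aligned_b, "")[[1]]
    both <- ca != "-" & cb != "-"
    qlen <- nchar(query_proteins[[q]])
    slen <- nchar(subject_proteins[[s]])
    tibble::tibble(
      query_id = q, subject_id = s,
      percent_identity = round(100 * sum(ca == cb & both) / sum(both), 2),
      alignment_length = length(ca),
      mismatches = sum(both & ca != cb),
      gap_opens = count_gap_opens(ca) + count_gap_opens(cb),
      query_start = 1, query_end = qlen,
      subject_start = 1, subject_end = slen,
      evalue = qlen * slen * 2^(-al$score / 2),
      bit_score = al$score,
      aligned_fraction = sum(both) / qlen
    )
  })
  dplyr::bind_rows(rows)
}

count_gap_opens <- function(chars) {
  gaps <- chars == "-"
  sum(gaps & !c(FALSE, gaps[-length(gaps)]))
}

#' Quality-control summary of ortholog pairs
#'
#' Flags each pair as passing when amino-acid identity exceeds 30% (strict)
#' and at least half of the query residues are aligned, and reports the
#' fraction passing — the sanity check that the e-value-thresholded best hits
#' are predominantly genuine orthologs.
#'
#' @param pairs Tibble with `percent_identity` and `aligned_fraction`
#'   columns (e.g. from [select_best_hits()] on [built_in_pairing()] output).
#' @return A list of class `pair_qc`: `n`, `n_pass`, `fraction_pass` (`NA`
#'   for empty input) and `pairs` (the input with a logical `qc_pass`
#'   column).
#' @export
pair_qc_report <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  pass <- pairs$percent_identity > 30 & pairs$aligned_fraction >= 0.5
  pairs$qc_pass <- pass
  structure(
    list(
      n = nrow(pairs),
      n_pass = sum(pass, na.rm = TRUE),
      fraction_pass = if (nrow(pairs)) mean(pass, na.rm = TRUE) else NA_real_,
      pairs = pairs
    ),
    class = "pair_qc"
  )
}

#' @export
print.pair_qc <- function(x, ...) {
  cat("<pair_qc>", x$n_pass, "of", x$n, "pairs pass (identity > 30%,",
      "coverage >= 50%)\n")
  if (!is.na(x$fraction_pass)) {
    cat("  fraction passing:", sprintf("%.3f", x$fraction_pass), "\n")
  }
  invisible(x)
}
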
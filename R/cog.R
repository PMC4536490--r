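# COG-subcategory significance matrix, the conserved-subcategory rule and
# the persistent-nonessential (PNE) gene classifier.

#' Classify persistent nonessential (PNE) genes
#'
#' A PNE gene is a nonessential gene whose ortholog pair shows no nucleotide
#' variation at all (Ka = Ks = 0) and whose protein has homologs in at least
#' two other organisms — conserved across distant bacteria yet dispensable in
#' the laboratory essentiality assay. The reported proportion has the
#' nonessential genes with an ortholog pair as its denominator.
#'
#' @param results Per-gene tibble with columns `gene_id`, `essential`, `ka`,
#'   `ks` (and optionally `organism_id`).
#' @param dataset An `organism_dataset` from [read_annotations()], or any
#'   tibble with `gene_id` and `homolog_count` columns.
#' @return A list of class `pne_result`: `records` (tibble `gene_id`,
#'   `organism_id`, `essential`, `ka`, `ks`, `homolog_count`, `is_pne`),
#'   `n_pne`, `n_nonessential`, `proportion` (`NA` when there are no
#'   nonessential genes) and `percent`.
#' @export
classify_pne <- function(results, dataset) {
  results <- tibble::as_tibble(results)
  hom <- if (inherits(dataset, "organism_dataset")) {
    dataset$genes[, c("gene_id", "homolog_count")]
  } else {
    tibble::as_tibble(dataset)[, c("gene_id", "homolog_count")]
  }
  if (!"organism_id" %in% names(results)) {
    results$organism_id <- NA_character_
  }
  results$homolog_count <- NULL # the dataset is authoritative
  rec <- results |>
    dplyr::left_join(hom, by = "gene_id") |>
    dplyr::mutate(
      homolog_count = dplyr::coalesce(.data$homolog_count, 0L),
      is_pne = !.data$essential &
        !is.na(.data$ka) & !is.na(.data$ks) &
        .data$ka == 0 & .data$ks == 0 &
        .data$homolog_count >= 2L
    ) |>
    dplyr::select("gene_id", "organism_id", "essential", "ka", "ks",
                  "homolog_count", "is_pne") |>
    dplyr::arrange(.data$gene_id)
  n_ne <- sum(!rec$essential)
  n_pne <- sum(rec$is_pne)
  prop <- if (n_ne > 0) n_pne / n_ne else NA_real_
  structure(
    list(records = rec, n_pne = n_pne, n_nonessential = n_ne,
         proportion = prop, percent = 100 * prop),
    class = "pne_result"
  )
}

#' @export
print.pne_result <- function(x, ...) {
  cat("<pne_result>", x$n_pne, "PNE of", x$n_nonessential,
      "nonessential genes")
  if (!is.na(x$proportion)) cat(sprintf(" (%.2f%%)", x$percent))
  cat("\n")
  invisible(x)
}

#' @rdname classify_pne
#' @param x A `pne_result`.
#' @param ... Unused.
#' @export
tidy.pne_result <- function(x, ...) x$records

#' @rdname classify_pne
#' @export
glance.pne_result <- function(x, ...) {
  tibble::tibble(n_pne = x$n_pne, n_nonessential = x$n_nonessential,
                 proportion = x$proportion, percent = x$percent)
}

#' COG-subcategory significance matrix
#'
#' For every (organism, COG letter) with at least one gene in each
#' essentiality class, runs a Mann-Whitney U test on the per-gene Ka/Ks
#' values within the category and assigns a direction: essential genes
#' significantly more conserved (lower Ka/Ks), nonessential genes
#' significantly more conserved, or none (p >= alpha). Genes annotated with
#' several letters contribute to each; letters R and S (general prediction /
#' unknown function) are excluded. Genes without a defined Ka/Ks ratio
#' (including zero-variation genes) do not enter the tests.
#'
#' @param results Per-gene tibble with columns `organism_id`, `essential`,
#'   `kaks` and a `cog_letters` list-column.
#' @param alpha Significance level (default 0.01).
#' @param exclude_letters Categories dropped from the analysis
#'   (default `c("R", "S")`).
#' @return Tibble of class `cog_matrix`: `organism_id`, `category`,
#'   `n_essential`, `n_nonessential`, `p_value`, `direction`. Cells with an
#'   empty class carry `p_value = NA` and direction `"none"`.
#' @export
cog_significance_matrix <- function(results, alpha = 0.01,
                                    exclude_letters = c("R", "S")) {
  stopifnot(alpha > 0, alpha < 1)
  results <- tibble::as_tibble(results)
  long <- results |>
    dplyr::select("organism_id", "essential", "kaks", "cog_letters") |>
    tidyr::unnest_longer("cog_letters", values_to = "category") |>
    dplyr::filter(!is.na(.data$category),
                  !.data$category %in% exclude_letters)
  if (!nrow(long)) {
    out <- tibble::tibble(
      organism_id = character(0), category = character(0),
      n_essential = integer(0), n_nonessential = integer(0),
      p_value = numeric(0), direction = character(0)
    )
    class(out) <- c("cog_matrix", class(out))
    return(out)
  }
  out <- long |>
    dplyr::group_by(.data$organism_id, .data$category) |>
    dplyr::group_modify(function(d, key) {
      ve <- d$kaks[d$essential & !is.na(d$kaks)]
      vn <- d$kaks[!d$essential & !is.na(d$kaks)]
      if (!length(ve) || !length(vn)) {
        return(tibble::tibble(
          n_essential = length(ve), n_nonessential = length(vn),
          p_value = NA_real_, direction = "none"
        ))
      }
      mw <- mwu_test(ve, vn)
      dir <- if (!is.na(mw$p_value) && mw$p_value < alpha) {
        if (mean(ve) < mean(vn)) "essential_conserved" else "nonessential_conserved"
      } else {
        "none"
      }
      tibble::tibble(
        n_essential = length(ve), n_nonessential = length(vn),
        p_value = mw$p_value, direction = dir
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$organism_id, .data$category)
  class(out) <- c("cog_matrix", class(out))
  out
}

#' Conserved function subcategories
#'
#' A COG letter is a conserved function subcategory when essential genes are
#' significantly more conserved than nonessential genes in more than half of
#' all organisms in the run (strict majority against the fixed organism
#' count; cells in the opposite direction do not subtract).
#'
#' @param matrix A `cog_matrix` from [cog_significance_matrix()].
#' @param n_organisms Total number of organisms in scope (the fixed
#'   denominator of the majority rule).
#' @return Sorted character vector of conserved COG letters.
#' @export
conserved_subcategories <- function(matrix, n_organisms) {
  stopifnot(n_organisms >= 1)
  counts <- matrix |>
    dplyr::filter(.data$direction == "essential_conserved") |>
    dplyr::count(.data$category)
  sort(counts$category[counts$n > n_organisms / 2])
}
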
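# Protein-guided codon alignment: pairwise global protein alignment
# (replacing ClustalW2 for the two-sequence case) and back-translation of the
# protein alignment onto the coding sequences (the Pal2Nal step).

#' Construct a codon alignment
#'
#' @param codons_a,codons_b Equal-length character vectors of codons
#'   (3 nucleotides) or gaps (`"---"`).
#' @return A list of class `codon_alignment`.
#' @export
codon_alignment <- function(codons_a, codons_b) {
  if (length(codons_a) != length(codons_b)) {
    stop("codon alignment rows must have equal length", call. = FALSE)
  }
  bad <- nchar(codons_a) != 3L | nchar(codons_b) != 3L
  if (any(bad)) {
    stop("codon alignment entries must be 3 characters (codon or '---'); ",
         "offending column ", which(bad)[1], call. = FALSE)
  }
  structure(list(codons_a = toupper(codons_a), codons_b = toupper(codons_b)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment>", length(x$codons_a), "columns\n")
  cat(" a:", paste(utils::head(x$codons_a, 20), collapse = " "),
      if (length(x$codons_a) > 20) "..." else "", "\n")
  cat(" b:", paste(utils::head(x$codons_b, 20), collapse = " "),
      if (length(x$codons_b) > 20) "..." else "", "\n")
  invisible(x)
}

#' @export
length.codon_alignment <- function(x) length(x$codons_a)

# Default protein scoring: BLOSUM62 with affine gap penalties (open 10,
# extend 0.5), the classical global-alignment defaults.
protein_scoring <- function(matrix = "BLOSUM62", gap_opening = 10,
                            gap_extension = 0.5) {
  submat <- if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    get(matrix, envir = e)
  } else {
    matrix
  }
  list(submat = submat, gap_opening = gap_opening,
       gap_extension = gap_extension)
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch-style global alignment with a standard substitution
#' matrix and affine gap penalties, used as the deterministic pairwise
#' replacement for a multiple-alignment program when only two sequences are
#' compared.
#'
#' @param a,b Protein sequences (strings over the 20 amino acids plus X).
#' @param scoring A [protein_scoring()] list (substitution matrix, gap
#'   opening/extension penalties).
#' @return A list of class `protein_alignment` with `aligned_a`, `aligned_b`
#'   (equal-length strings with `-` gaps), `score`, and `identity`
#'   (percent identical columns of the alignment).
#' @examples
#' align_protein_pair("MKV", "MV")
#' @export
align_protein_pair <- function(a, b, scoring = protein_scoring()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence", call. = FALSE)
  ok <- rownames(scoring$submat)
  for (s in c(a, b)) {
    bad <- setdiff(strsplit(s, "")[[1]], ok)
    if (length(bad)) {
      stop("non-amino-acid character in protein sequence: ",
           paste(unique(bad), collapse = ""), call. = FALSE)
    }
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = scoring$submat,
    gapOpening = scoring$gap_opening, gapExtension = scoring$gap_extension
  )
  aligned_a <- as.character(Biostrings::alignedPattern(pa))
  aligned_b <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  structure(
    list(
      aligned_a = aligned_a, aligned_b = aligned_b,
      score = Biostrings::score(pa),
      identity = 100 * sum(ca == cb & ca != "-") / length(ca)
    ),
    class = "protein_alignment"
  )
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("<protein_alignment> score", format(x$score), " identity",
      sprintf("%.1f%%", x$identity), "\n")
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Back-translate a protein alignment onto its coding sequences
#'
#' Maps each amino-acid column of the protein alignment to the corresponding
#' codon of each CDS (protein gap -> codon gap `"---"`), after trimming any
#' terminal stop codons. The CDS must translate exactly to the ungapped
#' protein rows.
#'
#' @param pa A `protein_alignment` (or list with `aligned_a`, `aligned_b`).
#' @param cds_a,cds_b The coding sequences underlying the two proteins.
#' @param code A [genetic_code()] object or table id.
#' @return A [codon_alignment()].
#' @export
backtranslate_alignment <- function(pa, cds_a, cds_b,
                                    code = genetic_code(11)) {
  code <- as_genetic_code(code)
  row_a <- strsplit(pa$aligned_a, "")[[1]]
  row_b <- strsplit(pa$aligned_b, "")[[1]]
  cods_a <- codon_split(trim_terminal_stop(cds_a, code))
  cods_b <- codon_split(trim_terminal_stop(cds_b, code))
  place <- function(row, cods, which) {
    res <- sum(row != "-")
    if (res != length(cods)) {
      stop("CDS/protein length mismatch for sequence ", which, ": ",
           length(cods), " codons vs ", res, " residues", call. = FALSE)
    }
    out <- rep("---", length(row))
    out[row != "-"] <- cods
    # verify translation consistency, naming the first offending position
    aa_cds <- unname(code$aa[cods])
    aa_cds[is.na(aa_cds)] <- "X"
    aa_row <- row[row != "-"]
    mism <- which(aa_cds != aa_row)
    if (length(mism)) {
      stop("CDS does not translate to aligned protein for sequence ", which,
           " at residue ", mism[1], " (", aa_row[mism[1]], " vs codon ",
           cods[mism[1]], ")", call. = FALSE)
    }
    out
  }
  codon_alignment(place(row_a, cods_a, "a"), place(row_b, cods_b, "b"))
}

#' Align a gene pair and estimate Ka/Ks
#'
#' Convenience wrapper for one ortholog pair: translate both CDS, build the
#' optimal global protein alignment, back-translate to codons and run the
#' Nei-Gojobori estimator.
#'
#' @param cds_a,cds_b Coding sequences of the two orthologs.
#' @inheritParams compute_kaks
#' @param scoring A [protein_scoring()] list.
#' @return A one-row `kaks_result` tibble (see [compute_kaks()]).
#' @export
gene_pair_kaks <- function(cds_a, cds_b, code = genetic_code(11),
                           stop_policy = c("exclude", "include"),
                           scoring = protein_scoring()) {
  stop_policy <- match.arg(stop_policy)
  pa <- align_protein_pair(translate_cds(cds_a, code),
                           translate_cds(cds_b, code), scoring)
  compute_kaks(backtranslate_alignment(pa, cds_a, cds_b, code),
               code, stop_policy)
}
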
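#' Build a genetic code object
#'
#' Wraps an NCBI translation table as used throughout the package. The default
#' is table 11 (bacterial, archaeal and plant plastid code); table 4 is needed
#' for e.g. *Mycoplasma* genomes where TGA encodes tryptophan, which is why the
#' code is configurable per organism.
#'
#' @param table_id NCBI genetic-code table identifier (integer or string),
#'   e.g. `11` (bacterial, the default), `4`, `1`.
#' @return An object of class `genetic_code`: a list with `table_id`, `codons`
#'   (the 64 codons), `aa` (named character vector codon -> amino acid, `*`
#'   for stop), `stops` (stop codons) and `sense` (the sense codons).
#' @examples
#' code <- genetic_code(11)
#' code$aa[["ATG"]]
#' @export
genetic_code <- function(table_id = 11) {
  aa <- Biostrings::getGeneticCode(as.character(table_id))
  # getGeneticCode() returns the 64 codons in TCAG order; keep its order.
  codons <- names(aa)
  stops <- codons[aa == "*"]
  structure(
    list(
      table_id = as.integer(table_id),
      codons = codons,
      aa = aa,
      stops = stops,
      sense = codons[aa != "*"]
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> NCBI translation table", x$table_id, "\n")
  cat("  ", length(x$sense), "sense codons; stops:",
      paste(x$stops, collapse = " "), "\n")
  invisible(x)
}

as_genetic_code <- function(code) {
  if (inherits(code, "genetic_code")) return(code)
  genetic_code(code)
}

#' Translate a coding sequence
#'
#' Translates a CDS codon by codon. A terminal stop codon is silently trimmed;
#' an internal stop is an error because it indicates an annotation problem
#' that would corrupt synonymous/nonsynonymous site counting downstream.
#' Codons containing an ambiguous base (`N`) translate to `X`.
#'
#' @param cds Nucleotide string over A, C, G, T, N.
#' @param code A [genetic_code()] object or table id.
#' @return Amino-acid string, one residue per (non-terminal-stop) codon.
#' @examples
#' translate_cds("ATGGGGTAA", 11)  # "MG": terminal stop trimmed
#' @export
translate_cds <- function(cds, code = genetic_code(11)) {
  code <- as_genetic_code(code)
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length ", nchar(cds), " is not a multiple of 3", call. = FALSE)
  }
  cods <- codon_split(cds)
  if (length(cods) && cods[length(cods)] %in% code$stops) {
    cods <- cods[-length(cods)]
  }
  if (!length(cods)) stop("CDS contains no codons after terminal-stop trimming",
                          call. = FALSE)
  aa <- unname(code$aa[cods])
  aa[is.na(aa)] <- "X" # ambiguous codon (contains N or similar)
  internal_stop <- which(aa == "*")
  if (length(internal_stop)) {
    stop("internal stop codon at codon ", internal_stop[1], call. = FALSE)
  }
  paste(aa, collapse = "")
}

# Split a nucleotide string into codons (no validation).
codon_split <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return(character(0))
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# Trim a terminal stop codon if present; error on non-multiple-of-3 length.
trim_terminal_stop <- function(cds, code) {
  code <- as_genetic_code(code)
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length ", nchar(cds), " is not a multiple of 3", call. = FALSE)
  }
  n <- nchar(cds)
  if (n >= 3L && substring(cds, n - 2L, n) %in% code$stops) {
    cds <- substring(cds, 1L, n - 3L)
  }
  cds
}
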
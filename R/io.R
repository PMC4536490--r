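# Readers and writers for the external formats the pipeline touches:
# FASTA (CDS and protein), essentiality / COG / homolog-presence TSVs and the
# 12-column BLAST tabular hit format.

#' Read a FASTA file into a named character vector
#'
#' Record ids are the first whitespace-delimited token of each header;
#' sequences are uppercased and internal whitespace is removed.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, id -> sequence.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         " in ", path, call. = FALSE)
  }
  out <- toupper(gsub("\\s", "", as.character(seqs)))
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector, id -> sequence.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

blast_columns <- c(
  "query_id", "subject_id", "percent_identity", "alignment_length",
  "mismatches", "gap_opens", "query_start", "query_end",
  "subject_start", "subject_end", "evalue", "bit_score"
)

#' Read a 12-column BLAST tabular hit file
#'
#' Tab-separated, one hit per line, `#` comment lines ignored; columns follow
#' BLAST `outfmt 6` exactly (1-based inclusive coordinates).
#'
#' @param path Path to the hit table.
#' @return A tibble with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `query_start`, `query_end`, `subject_start`, `subject_end`, `evalue`,
#'   `bit_score`, in file order.
#' @export
read_hit_table <- function(path) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(tibble::as_tibble(stats::setNames(
      c(rep(list(character(0)), 2), rep(list(numeric(0)), 10)),
      blast_columns
    )))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1]
    stop("line ", lineno[i], " of ", path, " has ", nf[i],
         " columns (expected 12)", call. = FALSE)
  }
  m <- do.call(rbind, parts)
  num <- function(col, name) {
    v <- suppressWarnings(as.numeric(m[, col]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("non-numeric ", name, " ('", m[bad[1], col], "') at line ",
           lineno[bad[1]], " of ", path, call. = FALSE)
    }
    v
  }
  tibble::tibble(
    query_id = m[, 1], subject_id = m[, 2],
    percent_identity = num(3, "percent_identity"),
    alignment_length = num(4, "alignment_length"),
    mismatches = num(5, "mismatches"),
    gap_opens = num(6, "gap_opens"),
    query_start = num(7, "query_start"), query_end = num(8, "query_end"),
    subject_start = num(9, "subject_start"),
    subject_end = num(10, "subject_end"),
    evalue = num(11, "evalue"), bit_score = num(12, "bit_score")
  )
}

#' Write a result table as TSV
#'
#' Tab-separated with a header row; undefined values are rendered `NA`;
#' numeric columns keep full precision (at least 6 significant digits).
#'
#' @param records A data frame (or coercible) of rows to write.
#' @param path Output path.
#' @param columns Ordered character vector of column names to write; every
#'   record must have every named column.
#' @export
write_table <- function(records, path, columns = names(records)) {
  records <- tibble::as_tibble(records)
  missing <- setdiff(columns, names(records))
  if (length(missing)) {
    stop("record(s) missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_tsv(records[, columns, drop = FALSE], path, na = "NA")
  invisible(path)
}

#' Assemble a gene table from CDS and protein sequences
#'
#' Joins per-gene CDS and protein sequences, checks that each CDS translates
#' to its protein (after terminal-stop trimming), and drops genes whose CDS
#' contains an internal stop codon (annotation artifacts that would corrupt
#' site counting), with a warning naming them.
#'
#' @param cds Named character vector of coding sequences.
#' @param proteins Named character vector of protein sequences (same ids).
#' @param organism_id Organism identifier attached to every gene.
#' @param code A [genetic_code()] object or table id.
#' @return A tibble with columns `gene_id`, `organism_id`, `cds`, `protein`.
#' @export
gene_table <- function(cds, proteins, organism_id, code = genetic_code(11)) {
  code <- as_genetic_code(code)
  if (!setequal(names(cds), names(proteins))) {
    only_cds <- setdiff(names(cds), names(proteins))
    only_prot <- setdiff(names(proteins), names(cds))
    stop("CDS/protein id mismatch",
         if (length(only_cds)) paste0("; CDS only: ",
                                      paste(utils::head(only_cds, 5), collapse = ", ")),
         if (length(only_prot)) paste0("; protein only: ",
                                       paste(utils::head(only_prot, 5), collapse = ", ")),
         call. = FALSE)
  }
  ids <- names(cds)
  translated <- character(length(ids))
  dropped <- character(0)
  for (i in seq_along(ids)) {
    tr <- tryCatch(translate_cds(cds[[i]], code), error = function(e) e)
    if (inherits(tr, "error")) {
      dropped <- c(dropped, ids[i])
      translated[i] <- NA_character_
    } else {
      translated[i] <- tr
    }
  }
  if (length(dropped)) {
    warning("dropped ", length(dropped), " gene(s) with untranslatable CDS ",
            "(internal stop or bad length): ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...", call. = FALSE)
  }
  keep <- !ids %in% dropped
  bad <- which(keep & translated != toupper(unname(proteins[ids])))
  if (length(bad)) {
    stop("CDS of gene ", ids[bad[1]], " does not translate to its protein",
         call. = FALSE)
  }
  tibble::tibble(
    gene_id = ids[keep],
    organism_id = organism_id,
    cds = toupper(unname(cds[keep])),
    protein = toupper(unname(proteins[ids[keep]]))
  )
}

#' Attach essentiality, COG and homolog-presence annotations
#'
#' Reads the three annotation TSVs and joins them onto a gene table built by
#' [gene_table()]. Every gene must appear in the essentiality table (labels
#' `E` / `NE`); genes missing from the COG table get an empty letter set
#' (absence of COG annotation is legal, as for organisms with no COG release);
#' genes missing from the homolog-presence table get count 0.
#'
#' @param genes Gene tibble from [gene_table()].
#' @param ess_path Essentiality TSV with columns `gene_id`, `label`.
#' @param cog_path COG TSV with columns `gene_id`, `letters` (a string of
#'   single-letter categories, e.g. `"JL"`), or `NULL` when the organism has
#'   no COG annotation.
#' @param homolog_path Homolog-presence TSV with columns `gene_id`,
#'   `n_organisms`, or `NULL`.
#' @return An `organism_dataset`: list with `organism_id`, `genes` (tibble
#'   with `essential`, `cog_letters` list-column and `homolog_count` added)
#'   and `cog_available` flag.
#' @export
read_annotations <- function(genes, ess_path, cog_path = NULL,
                             homolog_path = NULL) {
  ess <- readr::read_tsv(ess_path, col_types = readr::cols(.default = "c"))
  if (!all(c("gene_id", "label") %in% names(ess))) {
    stop("essentiality table needs columns gene_id, label", call. = FALSE)
  }
  unknown <- setdiff(ess$gene_id, genes$gene_id)
  if (length(unknown)) {
    stop("essentiality table names unknown gene(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  bad_label <- setdiff(unique(ess$label), c("E", "NE"))
  if (length(bad_label)) {
    stop("unknown essentiality label(s): ",
         paste(bad_label, collapse = ", "), " (expected E or NE)",
         call. = FALSE)
  }
  unlabeled <- setdiff(genes$gene_id, ess$gene_id)
  if (length(unlabeled)) {
    stop("gene(s) without essentiality label: ",
         paste(utils::head(unlabeled, 5), collapse = ", "), call. = FALSE)
  }

  cog_available <- !is.null(cog_path)
  cog_map <- list()
  if (cog_available) {
    cog <- readr::read_tsv(cog_path, col_types = readr::cols(.default = "c"))
    if (!all(c("gene_id", "letters") %in% names(cog))) {
      stop("COG table needs columns gene_id, letters", call. = FALSE)
    }
    cog <- cog[!is.na(cog$letters) & nzchar(cog$letters), ]
    cog_map <- stats::setNames(strsplit(toupper(cog$letters), ""), cog$gene_id)
  }

  hom_map <- integer(0)
  if (!is.null(homolog_path)) {
    hom <- readr::read_tsv(homolog_path,
                           col_types = readr::cols(.default = "c"))
    if (!all(c("gene_id", "n_organisms") %in% names(hom))) {
      stop("homolog-presence table needs columns gene_id, n_organisms",
           call. = FALSE)
    }
    n <- suppressWarnings(as.integer(hom$n_organisms))
    if (any(is.na(n)) || any(n < 0)) {
      stop("homolog-presence counts must be non-negative integers",
           call. = FALSE)
    }
    hom_map <- stats::setNames(n, hom$gene_id)
    extra <- setdiff(names(hom_map), genes$gene_id)
    if (length(extra)) {
      stop("homolog-presence table names unknown gene(s): ",
           paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
    }
  }

  lab <- stats::setNames(ess$label, ess$gene_id)
  genes$essential <- unname(lab[genes$gene_id]) == "E"
  genes$cog_letters <- lapply(genes$gene_id, function(g) {
    l <- cog_map[[g]]
    if (is.null(l)) character(0) else unique(l)
  })
  genes$homolog_count <- ifelse(genes$gene_id %in% names(hom_map),
                                unname(hom_map[genes$gene_id]), 0L)
  structure(
    list(
      organism_id = genes$organism_id[1],
      genes = genes,
      cog_available = cog_available
    ),
    class = "organism_dataset"
  )
}

#' @export
print.organism_dataset <- function(x, ...) {
  cat("<organism_dataset>", x$organism_id, "-", nrow(x$genes), "genes (",
      sum(x$genes$essential), "essential ),",
      if (x$cog_available) "COG annotated" else "no COG annotation", "\n")
  invisible(x)
}
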
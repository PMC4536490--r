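# End-to-end orchestration: configuration, the per-stage driver and the
# result-table writer. Only the bootstrap stage is stochastic; it draws from
# a stream seeded once from the configuration, so a rerun with the same
# configuration is byte-identical.

#' Pipeline configuration
#'
#' @param organisms Tibble with one row per organism and columns
#'   `organism_id`, `cds_fasta`, `protein_fasta`, `homolog_cds_fasta`,
#'   `homolog_protein_fasta`, `essentiality_tsv`, `cog_tsv`, `homolog_tsv`,
#'   `hits_tsv`. `cog_tsv` may be `NA` (organism excluded from the COG
#'   analysis, with a warning); `homolog_tsv` may be `NA` (all homolog
#'   counts 0); `hits_tsv` may be `NA` (hits computed by
#'   [built_in_pairing()]).
#' @param evalue_max Ortholog e-value threshold (default `1e-5`).
#' @param alpha COG-test significance level (default `0.01`).
#' @param bootstrap_reps Bootstrap replicates (default `1000`).
#' @param seed Integer seed for every stochastic stage.
#' @param genetic_code NCBI table id, scalar or named vector by
#'   `organism_id` (default 11).
#' @param stop_policy Pathway stop-codon policy, see [pathway_differences()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(organisms, evalue_max = 1e-5, alpha = 0.01,
                            bootstrap_reps = 1000, seed = 1,
                            genetic_code = 11,
                            stop_policy = c("exclude", "include")) {
  organisms <- tibble::as_tibble(organisms)
  needed <- c("organism_id", "cds_fasta", "protein_fasta",
              "homolog_cds_fasta", "homolog_protein_fasta",
              "essentiality_tsv")
  missing <- setdiff(needed, names(organisms))
  if (length(missing)) {
    stop("organisms table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (opt in c("cog_tsv", "homolog_tsv", "hits_tsv")) {
    if (!opt %in% names(organisms)) organisms[[opt]] <- NA_character_
  }
  structure(
    list(
      organisms = organisms,
      evalue_max = evalue_max, alpha = alpha,
      bootstrap_reps = as.integer(bootstrap_reps),
      seed = as.integer(seed),
      genetic_code = genetic_code,
      stop_policy = match.arg(stop_policy)
    ),
    class = "pipeline_config"
  )
}

org_code_id <- function(config, organism_id) {
  gc <- config$genetic_code
  if (!is.null(names(gc)) && organism_id %in% names(gc)) {
    return(gc[[organism_id]])
  }
  gc[[1]]
}

#' Ka/Ks for a set of ortholog pairs
#'
#' Runs the protein-guided codon-alignment + Nei-Gojobori estimator for each
#' pair: global protein alignment, back-translation onto the coding
#' sequences, then [compute_kaks()]. Pairs whose alignment leaves no
#' countable codon column get `NA` results with `valid = FALSE`.
#'
#' @param pairs Tibble with `query_id` and `subject_id` columns.
#' @param query_cds,query_proteins,subject_cds,subject_proteins Named
#'   character vectors of sequences.
#' @inheritParams compute_kaks
#' @param scoring A [protein_scoring()] list.
#' @return `pairs` with the [compute_kaks()] columns appended.
#' @export
kaks_table <- function(pairs, query_cds, query_proteins,
                       subject_cds, subject_proteins,
                       code = genetic_code(11),
                       stop_policy = c("exclude", "include"),
                       scoring = protein_scoring()) {
  code <- as_genetic_code(code)
  stop_policy <- match.arg(stop_policy)
  pairs <- tibble::as_tibble(pairs)
  if (!nrow(pairs)) {
    stop("no pairs to analyze", call. = FALSE)
  }
  unknown_q <- setdiff(pairs$query_id, names(query_proteins))
  unknown_s <- setdiff(pairs$subject_id, names(subject_proteins))
  if (length(unknown_q) || length(unknown_s)) {
    stop("pair references unknown sequence id(s): ",
         paste(utils::head(c(unknown_q, unknown_s), 5), collapse = ", "),
         call. = FALSE)
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(unname(query_proteins[pairs$query_id])),
    Biostrings::AAStringSet(unname(subject_proteins[pairs$subject_id])),
    type = "global", substitutionMatrix = scoring$submat,
    gapOpening = scoring$gap_opening, gapExtension = scoring$gap_extension
  )
  # for type = "global" the gapped pattern/subject views equal the aligned
  # rows, and extracting them scales far better than alignedPattern()
  al_a <- as.character(Biostrings::pattern(al))
  al_b <- as.character(Biostrings::subject(al))
  tab <- ng86_tables(code, stop_policy)
  mat <- matrix(NA_real_, nrow(pairs), length(kaks_core_names))
  for (i in seq_len(nrow(pairs))) {
    ca <- backtranslate_alignment(
      list(aligned_a = al_a[i], aligned_b = al_b[i]),
      query_cds[[pairs$query_id[i]]], subject_cds[[pairs$subject_id[i]]],
      code
    )
    core <- ng86_core(ca$codons_a, ca$codons_b, tab)
    if (!is.null(core)) {
      mat[i, ] <- core
    } else {
      mat[i, 1] <- 0 # no countable column: NA result, valid = FALSE
      mat[i, 11:14] <- 0
    }
  }
  dplyr::bind_cols(pairs, kaks_core_tibble(mat))
}

#' Run the full conservation pipeline
#'
#' Executes, for every organism: sequence and annotation loading, best-hit
#' ortholog pairing, Ka/Ks estimation, the essential-vs-nonessential
#' summaries with bootstrap, the COG significance matrix and conserved
#' subcategories, the PNE classification and the pair QC report. All result
#' tables are written as TSV under `out_dir`, together with a JSON run
#' manifest (configuration echo, package version, seed) sufficient to
#' reproduce the run. A failure in any stage aborts with the stage name and
#' removes partial outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return An object of class `kaks_pipeline`: list with the result tibbles
#'   (`pairs`, `kaks`, `summary`, `ttest`, `bootstrap`, `cog_matrix`,
#'   `conserved_letters`, `pne`, `pne_summary`, `qc`), `counts` (per-stage
#'   bookkeeping), `out_dir` and `config`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  fail <- function(stage, e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) fail(name, e))
  }
  emit <- function(tbl, file) {
    path <- file.path(out_dir, file)
    write_table(tbl, path)
    written <<- c(written, path)
    path
  }

  orgs <- config$organisms
  n_org <- nrow(orgs)

  # -- load ----------------------------------------------------------------
  datasets <- stage("read", {
    purrr::map(seq_len(n_org), function(i) {
      row <- orgs[i, ]
      code <- genetic_code(org_code_id(config, row$organism_id))
      genes <- gene_table(read_fasta(row$cds_fasta),
                          read_fasta(row$protein_fasta),
                          row$organism_id, code)
      cog_path <- if (is.na(row$cog_tsv)) NULL else row$cog_tsv
      if (is.null(cog_path)) {
        warning("organism ", row$organism_id,
                " has no COG annotation; excluded from the COG analysis",
                call. = FALSE)
      }
      ds <- read_annotations(
        genes, row$essentiality_tsv, cog_path,
        if (is.na(row$homolog_tsv)) NULL else row$homolog_tsv
      )
      ds$code <- code
      ds$homolog_cds <- read_fasta(row$homolog_cds_fasta)
      ds$homolog_proteins <- read_fasta(row$homolog_protein_fasta)
      ds
    })
  })

  # -- pair ----------------------------------------------------------------
  pairs_all <- stage("pair", {
    purrr::map_dfr(seq_len(n_org), function(i) {
      row <- orgs[i, ]
      ds <- datasets[[i]]
      prot <- stats::setNames(ds$genes$protein, ds$genes$gene_id)
      hits <- if (is.na(row$hits_tsv)) {
        built_in_pairing(prot, ds$homolog_proteins)
      } else {
        h <- read_hit_table(row$hits_tsv)
        qlen <- nchar(prot)[h$query_id]
        h$aligned_fraction <- (h$query_end - h$query_start + 1) / qlen
        h
      }
      hits <- hits[hits$query_id %in% ds$genes$gene_id, ]
      best <- select_best_hits(hits, config$evalue_max)
      dplyr::mutate(best, organism_id = row$organism_id, .before = 1)
    })
  })

  # -- Ka/Ks ---------------------------------------------------------------
  kaks_all <- stage("kaks", {
    purrr::map_dfr(seq_len(n_org), function(i) {
      ds <- datasets[[i]]
      p <- pairs_all[pairs_all$organism_id == ds$organism_id, ]
      if (!nrow(p)) {
        stop("no ortholog pairs for organism ", ds$organism_id)
      }
      res <- kaks_table(
        p[, c("query_id", "subject_id")],
        stats::setNames(ds$genes$cds, ds$genes$gene_id),
        stats::setNames(ds$genes$protein, ds$genes$gene_id),
        ds$homolog_cds, ds$homolog_proteins,
        ds$code, config$stop_policy
      )
      ann <- ds$genes[, c("gene_id", "essential", "cog_letters",
                          "homolog_count")]
      res |>
        dplyr::rename(gene_id = "query_id") |>
        dplyr::left_join(ann, by = "gene_id") |>
        dplyr::mutate(organism_id = ds$organism_id, .before = 1)
    })
  })

  # -- summarize + bootstrap ----------------------------------------------
  summary_all <- stage("summarize", {
    purrr::map_dfr(split(kaks_all, kaks_all$organism_id), summarize_organism)
  })
  ttest <- stage("summarize", {
    if (n_org >= 3) {
      purrr::map_dfr(c("Ka", "Ks", "KaKs"),
                     function(m) cross_organism_ttest(summary_all, m))
    } else {
      tibble::tibble(metric = character(0), statistic = numeric(0),
                     df = numeric(0), p_value = numeric(0),
                     n_organisms = integer(0))
    }
  })
  boot_all <- stage("bootstrap", {
    getters <- list(
      Ka = function(d) d$ka[d$valid_ka],
      Ks = function(d) d$ks[d$valid_ks],
      KaKs = function(d) d$kaks[!is.na(d$kaks)]
    )
    with_rng_seed(config$seed, {
      purrr::map_dfr(split(kaks_all, kaks_all$organism_id), function(d) {
        purrr::imap_dfr(getters, function(getter, metric) {
          purrr::map_dfr(c(TRUE, FALSE), function(is_e) {
            v <- getter(d[d$essential == is_e, ])
            if (!length(v)) return(NULL)
            b <- bootstrap_means(v, config$bootstrap_reps)
            tibble::tibble(
              organism_id = d$organism_id[1], metric = metric,
              class = if (is_e) "essential" else "nonessential",
              replicate = seq_len(b$reps),
              replicate_mean = b$replicate_means
            )
          })
        })
      })
    })
  })

  # -- COG matrix ----------------------------------------------------------
  cog_orgs <- purrr::map_lgl(datasets, "cog_available")
  cog_matrix <- stage("cogtest", {
    d <- kaks_all[kaks_all$organism_id %in%
                    orgs$organism_id[cog_orgs], ]
    if (nrow(d)) {
      cog_significance_matrix(d, config$alpha)
    } else {
      cog_significance_matrix(kaks_all[0, ], config$alpha)
    }
  })
  conserved <- stage("cogtest", {
    conserved_subcategories(cog_matrix, sum(cog_orgs))
  })

  # -- PNE -----------------------------------------------------------------
  pne_res <- stage("pne", {
    purrr::map(seq_len(n_org), function(i) {
      d <- kaks_all[kaks_all$organism_id == orgs$organism_id[i], ]
      classify_pne(d, datasets[[i]]$genes[, c("gene_id", "homolog_count")])
    })
  })
  pne_records <- purrr::map_dfr(pne_res, "records")
  pne_summary <- purrr::map2_dfr(pne_res, orgs$organism_id, function(p, o) {
    tibble::tibble(organism_id = o, n_pne = p$n_pne,
                   n_nonessential = p$n_nonessential,
                   pne_percent = p$percent)
  })

  # -- QC ------------------------------------------------------------------
  qc <- stage("qc", {
    purrr::map_dfr(split(pairs_all, pairs_all$organism_id), function(p) {
      r <- pair_qc_report(p)
      tibble::tibble(organism_id = p$organism_id[1], n_pairs = r$n,
                     n_pass = r$n_pass, fraction_pass = r$fraction_pass)
    })
  })

  # -- write ---------------------------------------------------------------
  counts <- tibble::tibble(
    organism_id = orgs$organism_id,
    n_genes = purrr::map_int(datasets, ~ nrow(.x$genes)),
    n_pairs = purrr::map_int(orgs$organism_id,
                             ~ sum(pairs_all$organism_id == .x)),
    n_valid = purrr::map_int(orgs$organism_id,
                             ~ sum(kaks_all$valid[kaks_all$organism_id == .x]))
  )
  stage("write", {
    emit(pairs_all, "pairs.tsv")
    kaks_flat <- dplyr::mutate(
      kaks_all,
      cog_letters = purrr::map_chr(.data$cog_letters, paste, collapse = "")
    )
    emit(kaks_flat, "kaks.tsv")
    emit(summary_all, "organism_summary.tsv")
    emit(ttest, "ttest.tsv")
    emit(boot_all, "bootstrap.tsv")
    emit(cog_matrix, "cog_matrix.tsv")
    path <- file.path(out_dir, "conserved_letters.txt")
    writeLines(conserved, path)
    written <<- c(written, path)
    emit(pne_records, "pne.tsv")
    emit(pne_summary, "pne_summary.tsv")
    emit(qc, "qc.tsv")
    emit(counts, "counts.tsv")
    manifest <- list(
      package = "kaksess",
      version = as.character(utils::packageVersion("kaksess")),
      seed = config$seed,
      evalue_max = config$evalue_max,
      alpha = config$alpha,
      bootstrap_reps = config$bootstrap_reps,
      genetic_code = config$genetic_code,
      stop_policy = config$stop_policy,
      organisms = config$organisms
    )
    mpath <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <<- c(written, mpath)
  })

  structure(
    list(
      pairs = pairs_all, kaks = kaks_all, summary = summary_all,
      ttest = ttest, bootstrap = boot_all, cog_matrix = cog_matrix,
      conserved_letters = conserved, pne = pne_records,
      pne_summary = pne_summary, qc = qc, counts = counts,
      out_dir = out_dir, config = config
    ),
    class = "kaks_pipeline"
  )
}

#' @export
print.kaks_pipeline <- function(x, ...) {
  cat("<kaks_pipeline>", nrow(x$config$organisms), "organisms,",
      nrow(x$pairs), "ortholog pairs,", sum(x$kaks$valid), "valid Ka/Ks\n")
  cat("  conserved COG subcategories:",
      if (length(x$conserved_letters)) paste(x$conserved_letters, collapse = " ")
      else "(none)", "\n")
  cat("  outputs in", x$out_dir, "\n")
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `kaks_pipeline`.
#' @param ... Unused.
#' @export
tidy.kaks_pipeline <- function(x, ...) x$summary

#' @rdname run_pipeline
#' @export
glance.kaks_pipeline <- function(x, ...) {
  kk <- x$ttest[x$ttest$metric == "KaKs", ]
  tibble::tibble(
    n_organisms = nrow(x$config$organisms),
    n_pairs = nrow(x$pairs),
    n_valid = sum(x$kaks$valid),
    n_pne = sum(x$pne$is_pne),
    n_conserved_categories = length(x$conserved_letters),
    ttest_p_kaks = if (nrow(kk)) kk$p_value else NA_real_
  )
}

#' Pipeline configuration from a generated panel
#'
#' Builds a [pipeline_config()] whose organism table points at the files
#' written by [generate_panel()].
#'
#' @param panel The list returned by [generate_panel()].
#' @param ... Passed to [pipeline_config()] (thresholds, seed, ...).
#' @export
panel_pipeline_config <- function(panel, ...) {
  pipeline_config(panel$organisms, ...)
}
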
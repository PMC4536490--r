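# Seeded codon-evolution simulator: random coding sequences, a
# rejection-sampling substitution process with a target dN/dS, and a
# multi-organism panel generator that writes the exact file set the readers
# consume, plus a ground-truth table.

# Per-code single-nucleotide neighbor tables for the simulator:
# nb_idx[i, j] = codon index after change j (position (j-1)%/%3 + 1, one of
# the 3 alternative nucleotides); nb_class = 0 stop, 1 synonymous,
# 2 nonsynonymous.
sim_tables <- function(code) {
  code <- as_genetic_code(code)
  key <- paste0("sim_t", code$table_id)
  if (!is.null(.kaks_cache[[key]])) return(.kaks_cache[[key]])
  codons <- code$codons
  aa <- code$aa
  nts <- c("A", "C", "G", "T")
  cmat <- do.call(rbind, strsplit(codons, ""))
  nb_idx <- matrix(0L, 64L, 9L)
  nb_class <- matrix(0L, 64L, 9L)
  for (i in seq_along(codons)) {
    j <- 0L
    for (pos in 1:3) {
      for (nt in setdiff(nts, cmat[i, pos])) {
        j <- j + 1L
        mut <- cmat[i, ]
        mut[pos] <- nt
        mi <- match(paste(mut, collapse = ""), codons)
        nb_idx[i, j] <- mi
        nb_class[i, j] <- if (aa[mi] == "*") 0L else if (aa[mi] == aa[i]) 1L else 2L
      }
    }
  }
  tab <- list(codons = codons, nb_idx = nb_idx, nb_class = nb_class,
              sense_idx = match(code$sense, codons),
              stop_idx = match(code$stops, codons))
  .kaks_cache[[key]] <- tab
  tab
}

#' Random coding sequence
#'
#' Codons are drawn uniformly from the sense codons of the genetic code
#' (so there is never an internal stop) and a terminal stop codon is
#' appended.
#'
#' @param codons Number of sense codons (>= 1).
#' @param code A [genetic_code()] object or table id.
#' @param seed Optional integer seed for reproducibility.
#' @return A nucleotide string of length `3 * (codons + 1)`.
#' @export
random_cds <- function(codons, code = genetic_code(11), seed = NULL) {
  stopifnot(codons >= 1)
  code <- as_genetic_code(code)
  with_rng_seed(seed, {
    body <- sample(code$sense, codons, replace = TRUE)
    stop_cod <- sample(code$stops, 1)
    paste(c(body, stop_cod), collapse = "")
  })
}

#' Evolve a coding sequence under a target dN/dS
#'
#' Rejection-sampling substitution process: single-nucleotide changes are
#' proposed uniformly over all 9L possibilities; changes creating a stop
#' codon are rejected; synonymous changes are accepted with probability 1 and
#' nonsynonymous changes with probability `omega`. The process runs until the
#' number of accepted synonymous substitutions reaches `divergence` times the
#' sequence's synonymous site count, so the realized Nei-Gojobori Ks
#' concentrates around `divergence` and Ka/Ks around `omega` for long
#' sequences. A terminal stop codon, if present, is carried through
#' unchanged.
#'
#' @param cds Coding sequence (no internal stops).
#' @param omega Target dN/dS (> 0; values near 0 suppress nonsynonymous
#'   changes entirely).
#' @param divergence Expected synonymous substitutions per synonymous site
#'   (>= 0; 0 returns the input unchanged).
#' @param code A [genetic_code()] object or table id.
#' @param seed Optional integer seed.
#' @param min_substitutions Lower bound on accepted synonymous substitutions
#'   (used by [generate_panel()] to guarantee that genes meant to be diverged
#'   really are).
#' @return The diverged CDS (same length as the input).
#' @export
evolve_codon_sequence <- function(cds, omega, divergence,
                                  code = genetic_code(11), seed = NULL,
                                  min_substitutions = 0L) {
  stopifnot(omega > 0, divergence >= 0)
  code <- as_genetic_code(code)
  tabs <- sim_tables(code)
  ng <- ng86_tables(code)
  cds <- toupper(cds)
  n <- nchar(cds)
  has_stop <- n >= 3L && substring(cds, n - 2L, n) %in% code$stops
  terminal <- if (has_stop) substring(cds, n - 2L, n) else ""
  body <- if (has_stop) substring(cds, 1L, n - 3L) else cds
  cods <- match(codon_split(body), tabs$codons)
  if (anyNA(cods) || any(cods %in% tabs$stop_idx)) {
    stop("CDS contains an ambiguous or internal stop codon", call. = FALSE)
  }
  L <- length(cods)
  S0 <- sum(ng$syn_thirds[cods]) / 3
  target <- max(as.integer(round(divergence * S0)),
                as.integer(min_substitutions))
  if (target == 0L) return(cds)
  cods <- with_rng_seed(seed, {
    syn <- 0L
    while (syn < target) {
      k <- max(64L, 6L * (target - syn))
      pos <- sample.int(L, k, replace = TRUE)
      chg <- sample.int(9L, k, replace = TRUE)
      u <- stats::runif(k)
      for (t in seq_len(k)) {
        ci <- cods[pos[t]]
        cls <- tabs$nb_class[ci, chg[t]]
        if (cls == 0L) next
        if (cls == 1L) {
          cods[pos[t]] <- tabs$nb_idx[ci, chg[t]]
          syn <- syn + 1L
          if (syn >= target) break
        } else if (u[t] < omega) {
          cods[pos[t]] <- tabs$nb_idx[ci, chg[t]]
        }
      }
    }
    cods
  })
  paste0(paste(tabs$codons[cods], collapse = ""), terminal)
}

#' Simulation configuration for a multi-organism panel
#'
#' Defines the study conditions of the synthetic panel: sample sizes, the
#' class-specific dN/dS targets (essential genes under stronger purifying
#' selection than nonessential ones), the synonymous divergence of the
#' homologous strain, the fraction of zero-divergence PNE-like nonessential
#' genes, and the COG design. By default most letters follow the class
#' omegas (class-differential categories) while the letters in
#' `cog_omega` are overridden; the default overrides make O and T null
#' categories (both classes at the nonessential omega).
#'
#' @param n_organisms Number of organisms in the panel.
#' @param genes_per_organism Genes per organism.
#' @param codons_per_gene Sense codons per gene.
#' @param fraction_essential Fraction of genes labeled essential.
#' @param omega_essential,omega_nonessential Class dN/dS targets.
#' @param divergence Expected synonymous substitutions per synonymous site
#'   between a gene and its homolog (> 0).
#' @param pne_fraction Fraction of nonessential genes emitted with zero
#'   divergence and homolog presence in >= 2 organisms (true PNE genes).
#' @param cog_letters COG letters cycled over the genes of each class.
#' @param cog_omega Named list of per-letter overrides, each a numeric vector
#'   `c(essential = , nonessential = )`; `NULL` entries fall back to the
#'   class defaults.
#' @param genetic_code_id NCBI translation table id.
#' @param seed Integer seed; the whole panel is a deterministic function of
#'   the configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_organisms = 5,
                       genes_per_organism = 200,
                       codons_per_gene = 300,
                       fraction_essential = 0.2,
                       omega_essential = 0.05,
                       omega_nonessential = 0.3,
                       divergence = 0.2,
                       pne_fraction = 0.05,
                       cog_letters = c("J", "L", "C", "E", "G", "H", "O", "T"),
                       cog_omega = NULL,
                       genetic_code_id = 11,
                       seed = 1) {
  if (is.null(cog_omega)) {
    cog_omega <- list(
      O = c(essential = omega_nonessential,
            nonessential = omega_nonessential),
      T = c(essential = omega_nonessential,
            nonessential = omega_nonessential)
    )
    cog_omega <- cog_omega[names(cog_omega) %in% cog_letters]
  }
  cfg <- structure(
    list(
      n_organisms = as.integer(n_organisms),
      genes_per_organism = as.integer(genes_per_organism),
      codons_per_gene = as.integer(codons_per_gene),
      fraction_essential = fraction_essential,
      omega_essential = omega_essential,
      omega_nonessential = omega_nonessential,
      divergence = divergence,
      pne_fraction = pne_fraction,
      cog_letters = cog_letters,
      cog_omega = cog_omega,
      genetic_code_id = as.integer(genetic_code_id),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      n_organisms >= 1, genes_per_organism >= 1, codons_per_gene >= 1,
      fraction_essential >= 0, fraction_essential <= 1,
      omega_essential > 0, omega_nonessential > 0,
      pne_fraction >= 0, pne_fraction <= 1
    )
    if (divergence <= 0) {
      stop("divergence must be positive (zero-divergence genes are ",
           "generated via pne_fraction)", call. = FALSE)
    }
    if (fraction_essential == 1 && pne_fraction > 0) {
      stop("inconsistent config: fraction_essential = 1 leaves no ",
           "nonessential genes to flag as PNE", call. = FALSE)
    }
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_organisms, "organisms x", x$genes_per_organism,
      "genes x", x$codons_per_gene, "codons\n")
  cat("  omega (E/NE):", x$omega_essential, "/", x$omega_nonessential,
      " divergence:", x$divergence, " PNE fraction:", x$pne_fraction, "\n")
  cat("  seed:", x$seed, " genetic code:", x$genetic_code_id, "\n")
  invisible(x)
}

#' Generate a complete synthetic input panel
#'
#' Writes, per organism, CDS and protein FASTA for the original genome and
#' its diverged homolog, essentiality / COG / homolog-presence TSVs and a
#' precomputed hit table (one hit per gene against its known homolog), plus a
#' panel-wide ground-truth TSV. Essential and nonessential genes are evolved
#' at their class (or COG-overridden) omega; PNE-flagged nonessential genes
#' get an identical homolog and a homolog-presence count of at least 2; all
#' other genes receive at least one substitution. COG letters cycle through
#' `cog_letters` within each class so every category is populated in both
#' classes.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `organisms` (tibble of per-organism file
#'   paths), `ground_truth` (tibble and its path) and `config`.
#' @export
generate_panel <- function(config = sim_config(), dir) {
  validate_sim_config(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  code <- genetic_code(config$genetic_code_id)

  org_ids <- sprintf("org%02d", seq_len(config$n_organisms))
  truth_all <- list()
  files <- list()

  with_rng_seed(config$seed, {
    for (o in seq_along(org_ids)) {
      org <- org_ids[o]
      ng <- config$genes_per_organism
      n_e <- round(ng * config$fraction_essential)
      gene_ids <- sprintf("%s_g%04d", org, seq_len(ng))
      essential <- seq_len(ng) <= n_e

      # letters cycle within each class (balanced design)
      letters_of <- function(k) {
        config$cog_letters[(seq_len(k) - 1L) %% length(config$cog_letters) + 1L]
      }
      cog <- character(ng)
      cog[essential] <- letters_of(sum(essential))
      cog[!essential] <- letters_of(sum(!essential))

      n_pne <- round(sum(!essential) * config$pne_fraction)
      is_pne <- logical(ng)
      is_pne[which(!essential)[seq_len(n_pne)]] <- TRUE

      omega <- ifelse(essential, config$omega_essential,
                      config$omega_nonessential)
      for (g in seq_len(ng)) {
        ov <- config$cog_omega[[cog[g]]]
        if (!is.null(ov)) {
          omega[g] <- unname(ov[[if (essential[g]) "essential" else "nonessential"]])
        }
      }

      hom_max <- max(2L, config$n_organisms - 1L)
      pick <- function(v) v[sample.int(length(v), 1L)] # length-1 safe
      homolog_count <- integer(ng)
      cds <- character(ng)
      hom_cds <- character(ng)
      for (g in seq_len(ng)) {
        cds[g] <- random_cds(config$codons_per_gene, code)
        if (is_pne[g]) {
          hom_cds[g] <- cds[g]
          homolog_count[g] <- pick(2:hom_max)
        } else {
          hom_cds[g] <- evolve_codon_sequence(
            cds[g], omega[g], config$divergence, code,
            min_substitutions = 1L
          )
          homolog_count[g] <- pick(0:(config$n_organisms - 1L))
        }
      }
      prot <- vapply(cds, translate_cds, character(1), code = code,
                     USE.NAMES = FALSE)
      hom_prot <- vapply(hom_cds, translate_cds, character(1), code = code,
                         USE.NAMES = FALSE)
      hom_ids <- paste0(gene_ids, "_h")

      p <- function(ext) file.path(dir, paste0(org, ".", ext))
      write_fasta(stats::setNames(cds, gene_ids), p("cds.fasta"))
      write_fasta(stats::setNames(prot, gene_ids), p("protein.fasta"))
      write_fasta(stats::setNames(hom_cds, hom_ids), p("homolog_cds.fasta"))
      write_fasta(stats::setNames(hom_prot, hom_ids),
                  p("homolog_protein.fasta"))
      write_table(
        tibble::tibble(gene_id = gene_ids,
                       label = ifelse(essential, "E", "NE")),
        p("essentiality.tsv")
      )
      write_table(tibble::tibble(gene_id = gene_ids, letters = cog),
                  p("cog.tsv"))
      write_table(
        tibble::tibble(gene_id = gene_ids, n_organisms = homolog_count),
        p("homologs.tsv")
      )

      # one precomputed hit per gene against its known homolog (gap-free,
      # equal length, so identity is a direct position-wise count)
      plen <- nchar(prot)
      matches <- mapply(function(a, b) {
        sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
      }, prot, hom_prot, USE.NAMES = FALSE)
      hits <- tibble::tibble(
        query_id = gene_ids, subject_id = hom_ids,
        percent_identity = round(100 * matches / plen, 2),
        alignment_length = plen,
        mismatches = plen - matches, gap_opens = 0L,
        query_start = 1L, query_end = plen,
        subject_start = 1L, subject_end = plen,
        evalue = 1e-180, bit_score = 2 * matches
      )
      # BLAST outfmt 6 dialect: no header row
      readr::write_tsv(hits, p("hits.tsv"), col_names = FALSE)

      truth_all[[o]] <- tibble::tibble(
        gene_id = gene_ids, organism_id = org, essential = essential,
        cog_letters = cog, omega = omega, is_pne = is_pne,
        homolog_count = homolog_count
      )
      files[[o]] <- tibble::tibble(
        organism_id = org,
        cds_fasta = p("cds.fasta"), protein_fasta = p("protein.fasta"),
        homolog_cds_fasta = p("homolog_cds.fasta"),
        homolog_protein_fasta = p("homolog_protein.fasta"),
        essentiality_tsv = p("essentiality.tsv"), cog_tsv = p("cog.tsv"),
        homolog_tsv = p("homologs.tsv"), hits_tsv = p("hits.tsv")
      )
    }
  })

  truth <- dplyr::bind_rows(truth_all)
  truth_path <- file.path(dir, "ground_truth.tsv")
  write_table(truth, truth_path)
  invisible(list(
    organisms = dplyr::bind_rows(files),
    ground_truth = truth,
    ground_truth_path = truth_path,
    config = config
  ))
}
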
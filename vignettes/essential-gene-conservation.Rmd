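---
title: "Methods: Ka/Ks-based conservation analysis of essential genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Ka/Ks-based conservation analysis of essential genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaksess)
```

## The question and the estimator

Essential genes — genes whose loss is lethal in a genome-wide knockout
screen — are expected to evolve under stronger purifying selection than
dispensable genes. `kaksess` quantifies this with the Ka/Ks (dN/dS) ratio
between each gene and its best ortholog in a closely related strain, and
then asks, per organism and per COG functional category, whether the
essential class has systematically lower ratios.

The estimator is the counting method of Nei and Gojobori (1986):

1. **Sites.** For each sense codon, each of the nine single-nucleotide
   changes is classified as synonymous or nonsynonymous under the genetic
   code; the synonymous fraction (out of 3 per position) gives the codon's
   synonymous site count `s`, with `s + n = 3` exactly. Changes that create
   a stop codon count as nonsynonymous. Per alignment, `S` and `N` are the
   averages of the two sequences' site totals over the counted columns.
2. **Differences.** For a codon pair differing at `k` positions, the
   `k!` mutational orderings are walked; each step is classified
   synonymous/nonsynonymous and the counts are averaged over orderings, so
   `Sd + Nd` always equals the nucleotide Hamming distance of the column.
   Orderings passing through a stop-codon intermediate are excluded from
   the average (with a fallback to all orderings if every one is excluded).
3. **Correction.** The proportions `pS = Sd/S` and `pN = Nd/N` are
   corrected for multiple hits with the one-parameter Jukes–Cantor formula
   `d = -(3/4) log(1 - 4p/3)`. A proportion at or above 3/4 is outside the
   model's domain; the corresponding Ka or Ks is flagged invalid and the
   gene is excluded from downstream means. The ratio Ka/Ks additionally
   requires `Ks > 0`, so zero-variation genes (Ka = Ks = 0) carry no ratio.

The method deliberately has no transition/transversion or codon-frequency
correction — those belong to other estimators (LWL85, YN00, ML) that are
out of scope here. Its assumptions are therefore: equal mutability of all
sites, no selection on synonymous codon usage, and divergence low enough
for the Jukes–Cantor correction to be meaningful.

### Numerical choices

All site and difference arithmetic is carried out in exact integer units —
thirds for site fractions, sixtieths for pathway averages (every per-codon
denominator divides 60 = lcm(1..6)) — and converted to floating point only
at the correction step. This makes results bit-stable, symmetric in the two
sequences by construction, and lets the conservation laws (`s + n = 3`,
`Sd + Nd` = Hamming distance) hold exactly rather than to rounding error.
The test suite verifies the pathway table against an independent brute-force
enumeration for all 61 × 61 ordered sense-codon pairs, and the assembled
estimator against a whole-pipeline oracle on random alignments.

## From sequences to pairs

The upstream of the estimator mirrors the classical workflow (BLASTP best
hit → protein alignment → back-translation):

- **Pairing.** Real data enters as 12-column BLAST tabular files; the best
  hit per query is the surviving hit (e-value < 10⁻⁵) with the highest bit
  score, ties broken by lower e-value then lexicographic subject id so the
  result is order-independent. The genome-scale alternative of running an
  external search engine is replaced, for offline use, by
  `built_in_pairing()`: an all-vs-all optimal global alignment whose
  "e-value" is a simple length-normalized monotone transform of the score —
  a ranking device, not a database statistic.
- **Alignment.** For a single pair of proteins the optimal global
  (Needleman–Wunsch) alignment under BLOSUM62 with affine gap penalties
  (opening 10, extension 0.5) is the deterministic stand-in for a
  progressive multiple-alignment program; for two sequences the optimum is
  well defined and the aligner's traceback is deterministic, which we
  verify by score-equality against exhaustive enumeration on short
  sequences. Exact reproduction of any particular aligner's gap placement
  is not attempted (it cannot change the optimal score, and only rarely and
  marginally shifts counted columns).
- **Back-translation.** Each amino-acid column maps to its codon
  (protein gap → codon gap `---`), after trimming a terminal stop codon.
  A CDS that does not translate to its aligned protein is a hard error,
  naming the residue. Columns containing a gap, an ambiguous base or a stop
  codon are excluded from counting at codon granularity
  (pairwise-complete deletion, the Pal2Nal-style default).
- **Gene hygiene.** A terminal stop codon on a CDS is silently trimmed; an
  internal stop is an annotation artifact that would corrupt site counting,
  so the gene is dropped with a warning. The genetic code defaults to NCBI
  table 11 (bacterial) and is configurable per organism — e.g. table 4 for
  *Mycoplasma*, where TGA encodes tryptophan.

## Statistics

- **Class comparison.** Per organism, the essential and nonessential means
  of Ka, Ks and Ka/Ks are compared with a two-sided Mann–Whitney U test on
  the per-gene values. Ka and Ks means include zero-variation genes (value
  0); ratio means cover only genes with a defined ratio. Genes are weighted
  equally (not by length). The MWU engine uses midranks; for combined
  samples of at most 10 the p-value is an exhaustive enumeration over all
  group assignments (exact even under ties), otherwise the tie-corrected
  normal approximation with continuity correction. Sidedness is two-sided,
  with the conservation *direction* read separately from the sign of the
  class-mean difference — this is what populates the blue/red cells of the
  COG matrix.
- **Bootstrap.** To guard the class means against a handful of extreme
  ratios, each (organism, metric, class) is resampled 1000 times, each
  replicate drawing ⌊n/2⌋ values (minimum 1) with replacement and recording
  the mean. Half-sampling is interpreted as floor rounding; the replicate
  table is written long-format for box-plot reconstruction.
- **Across organisms.** The essential and nonessential class means are
  compared with a two-sided *paired* Student's t-test, pairing by organism,
  which matches the per-organism structure of the summary. At least three
  organisms are required. The degenerate all-differences-zero case returns
  t = 0, p = 1 (the limit the generic test refuses to compute). No
  multiple-testing correction is applied across organisms or metrics.
- **COG matrix.** Within each (organism, COG letter), the per-gene Ka/Ks
  values of the two classes are MWU-tested at α = 0.01. Letters R and S
  (general prediction / unknown function) are excluded; genes annotated
  with several letters count in each of them (the annotation's granularity,
  not ours); zero-variation genes have no ratio and never enter these
  tests. A letter is a **conserved function subcategory** when the
  essential class is significantly more conserved in *more than half* of
  all organisms in the run — a strict majority against the fixed organism
  count, in which opposite-direction cells do not subtract and organisms
  without COG annotation are excluded from the denominator.
- **PNE genes.** A *persistent nonessential* gene is nonessential, shows no
  nucleotide variation against its ortholog (Ka = Ks = 0) and has homologs
  in at least two other organisms. The reported percentage is out of the
  nonessential genes with an ortholog pair. PNE enrichment is the package's
  diagnostic for organisms where the nonessential class looks *more*
  conserved than the essential one.

## The synthetic panel

The generator exists so that every downstream stage is testable offline; it
emulates the *statistical* structure the analysis assumes, not bacterial
genomes. Each gene is a uniform random sense-codon sequence; its ortholog
is produced by a rejection-sampling substitution process: single-nucleotide
changes proposed uniformly, stop-creating changes rejected, synonymous
changes accepted with probability 1 and nonsynonymous with probability ω,
run until the accepted synonymous substitutions reach `divergence × S`.
Because proposals are uniform, the expected Nei–Gojobori Ka/Ks of the
output equals ω and Ks concentrates near the configured divergence — which
is exactly the calibration the estimator tests need. It is *not* a
continuous-time codon model (no GY94/MG94 rate matrix, no codon-usage
bias, no indels — gap handling is exercised by hand-written alignment
fixtures instead), so passing tests demonstrate correct arithmetic and
inference on idealized data, not realism of bacterial evolution.

Default study conditions: 5 organisms × 200 genes × 300 codons; 20%
essential; ω = 0.05 (essential) vs 0.3 (nonessential); synonymous
divergence 0.2; 5% of nonessential genes PNE (zero divergence, homolog
count ≥ 2, and at least one substitution forced into every non-PNE gene so
the ground-truth PNE set is exact by construction); eight COG letters
cycled within each class so every category is populated in both classes,
of which O and T are overridden to equal class ω (null categories) while
the remaining six carry the class difference. These sizes give each
(organism, letter) cell roughly 5 essential vs 20 nonessential ratio-bearing
genes — enough for a fully separated category to clear α = 0.01 — and are
the problem sizes used throughout the test suite; the deeper recovery
checks run ten such panels over distinct seeds and require the organism-
and category-level conclusions in at least nine.

Homolog-presence counts are drawn per gene (they are inputs to the PNE
rule, not derived from cross-organism alignment — the panel does not
actually align organisms to each other).

## Design decisions that were genuinely open

- *"Highest score"* is taken as bit score; the tie-break chain
  (e-value, then subject id) is ours, chosen for determinism.
- Coverage in the pair QC ("more than 30% identity and ≥ 50% aligned
  residues", with the 30% strict) is measured relative to the query length;
  the denominator was unspecified upstream.
- The stop-codon policy of the estimator (stops nonsynonymous in site
  counts; stop-path orderings excluded with fallback) follows the NG86
  convention but is exposed as `stop_policy` because reference
  implementations differ silently on it.
- Only Ka/Ks (not Ka or Ks separately) is tested per COG category; the
  per-organism summaries test all three metrics.
- The conserved-subcategory majority is evaluated against all organisms in
  the COG analysis, not only those where the letter is testable.

## Limitations

Results depend on the choice of homologous strain: near-identical strains
leave most pairs with zero variation (no ratio), overly distant ones push
proportions past the Jukes–Cantor domain; both kinds of gene are excluded
and logged in the per-stage counts. The built-in pairer is quadratic in the
number of proteins and intended for panels of hundreds of genes, not whole
proteomes — use precomputed hit tables there. The MWU normal approximation
is standard but approximate in the 11–30 sample range; the COG tests at
default panel sizes sit mostly in the exact regime's neighborhood, and the
α = 0.01 calls there should be read with that in mind.
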
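---
title: "Multi-evidence target prioritization: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-evidence target prioritization: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stargazeR)
```

## The scoring model

For a phenotype of interest, the unit of analysis is the set of genes
carrying at least one significant variant association (p ≤ α, inclusive;
α = 0.05 by default). Each gene `g` in that set receives five feature
scores, each normalized to [0, 1] **within the current gene set**, and the
aggregate score is their arithmetic mean:

$$S(g) = \frac{1}{5}\left(f_{\mathrm{OR}} + f_{\mathrm{assoc}} +
f_{\cap} + f_{\mathrm{drug}} + f_{\mathrm{deg}}\right)$$

- $f_{\mathrm{OR}}$: every record contributes an odds-ratio *magnitude* —
  the OR itself for risk alleles (OR ≥ 1, boundary included), and
  $1-\mathrm{OR}$ for protective alleles (OR < 1), for which a lower ratio
  means a stronger association. Magnitudes are averaged over the studies
  of each gene, and gene means are divided by the largest mean in the set.
- $f_{\mathrm{assoc}}$: the gene–disease association score (already in
  [0, 1] at the source), divided by the largest raw score in the set.
  Duplicate (gene, disease) rows are averaged before normalization, by
  analogy with the multi-study averaging of odds ratios.
- $f_{\cap}$: 1 when the gene appears in the post-filter gene sets of
  *both* catalog sources, else 0. (The variant-level intersection — rsIDs
  reported by both sources — is what the intersection *exploration mode*
  tabulates; the per-gene indicator is what enters the score.)
- $f_{\mathrm{drug}}$: the count of distinct target development levels
  excluding Tdark (Tdark means druggability is *unknown*, so it carries no
  credit: {Tbio, Tclin, Tdark} counts 2), divided by the largest count.
- $f_{\mathrm{deg}}$: the gene's degree in the interaction network built
  over the phenotype's gene set, divided by the maximum degree. Edges
  require combined confidence ≥ `min_confidence` (default 400, the
  conventional "medium confidence" cutoff on the 0–1000 scale); duplicate
  and reversed pairs collapse to one edge keeping the maximum confidence,
  and self-loops are discarded.

Because each feature is max-normalized, $S(g)=1$ exactly when a gene leads
the set on all five features, and all scores stay in [0, 1]. Ranking is by
descending score with alphabetical tie-break, which makes output
deterministic and byte-reproducible.

Three tables are produced per phenotype — all alleles, risk alleles only,
protective alleles only — and each is normalized independently over its
own gene set, so a gene's score is only comparable within one table.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | Significance filter on reported p-values, inclusive (p ≤ α). No multiple-testing correction is applied; the filter acts on the p-values as published by the source. |
| `min_confidence` | 400 | Minimum combined interaction confidence (0–1000) for an edge to count toward degree. |
| `context` | ALL | Allele-class restriction: ALL, RISK (OR ≥ 1) or PROTECTIVE (OR < 1). |

## Numerical and design choices

- **Mean, not sum.** Averaging the five features (rather than summing)
  keeps the aggregate in [0, 1] with a meaningful maximum; the bundled
  published example table confirms the mean reproduces its printed
  aggregate column.
- **Protective magnitude $1-\mathrm{OR}$.** The alternative reading
  $\mathrm{OR}-1$ is negative on (0, 1) and cannot be a magnitude; with
  $1-\mathrm{OR}$ a protective OR of 0.9 contributes 0.1 and an OR of 0.2
  contributes 0.8, matching the intent that lower ratios carry more
  weight. In the ALL context risk and protective records mix their
  class-appropriate magnitudes within a gene mean; the scale asymmetry
  (risk magnitudes unbounded above, protective ≤ 1) is inherent to the
  definition and is not rescaled.
- **Degenerate normalizations score 0.** If every raw value of a feature
  is 0 (no associations scored, no druggable gene, an edgeless network),
  all genes get 0 for that feature rather than NaN, so aggregation is
  always defined. Consequently the tightness property — "some gene attains
  1" — holds per feature *unless that feature is identically zero*.
- **Boundary conventions.** OR = 1 is risk; p = α survives the filter.
  Both boundaries are stated inclusively and tested.
- **Harmonization rules.** Gene symbols are uppercased and trimmed and
  then compared exactly; trait labels are matched case-insensitively after
  collapsing internal whitespace. No fuzzy matching of near-duplicate
  trait labels ("Type II diabetes" vs "Type 2 diabetes") and no clinical
  vocabulary mapping (ICD, EFO) is attempted. Multi-gene mapped fields
  ("GENE1 - GENE2") are split into one record per gene. Rows with missing
  or unparseable effect sizes, and GWAS rows whose effect value is
  non-positive (a beta coefficient, not an odds ratio), are dropped and
  counted in the load report: the framework is defined on odds ratios
  only.
- **Provider totality.** Lookups never fail on unknown genes: they return
  the explicit no-evidence values (association score 0, empty TDL set,
  isolated node), so a gene supported only by catalog evidence still
  receives a complete feature vector.

## What the synthetic generator emulates

`generate_fixture()` produces the full five-file input set with
controllable structure: per-gene variant counts, a risk/protective mix
(risk ORs log-normal in (1, 5], protective uniform in [0.2, 1)), a
controllable fraction of variants reported by both sources (these share OR
and p so the significance filter treats them consistently), mixed
p-values so a known subset survives α = 0.05, random TDL assignments, and
an Erdős–Rényi-style edge list. Sizes used in the test suite (3–50 genes,
2–3 phenotypes, 3–4 variants per gene) keep the whole suite fast while
exercising every code path; they are small-world stand-ins, not realistic
catalog scales.

It deliberately does **not** emulate linkage structure, allele
frequencies, study heterogeneity, correlated evidence between sources, or
realistic trait vocabularies. Passing tests therefore demonstrate the
*arithmetic* of the framework — filtering, averaging, normalization,
aggregation, ranking — not the epidemiological validity of any real-data
ranking.

Alongside the input files the generator writes a ground-truth table of
feature vectors and aggregate scores computed by straight-line loops that
share no code with the scoring pipeline. The oracle-equivalence tests
require agreement to 1e-12 across varied generated fixtures, which is the
strongest internal-consistency evidence the package offers.

## Known limitations

- Scores are relative to the phenotype's gene set: adding or removing one
  gene can rescale every other gene's features. This is by construction
  (max normalization) and mirrors the per-table independence noted above.
- The five features are equally weighted; no attempt is made to learn
  weights or model correlation between evidence types.
- Association p-values are taken at face value from the sources; catalogs
  with heterogeneous statistical methodology are mixed without correction.
- The published example table bundled in `inst/extdata/` carries its
  feature columns at 3-decimal print precision, so recomputed aggregates
  can differ from printed aggregates by up to ~0.001 in accumulated
  rounding; one of its 30 rows (HLA-DQB1) differs by 0.0006.
- Live database clients are out of scope; all providers are file-backed,
  which is what makes runs deterministic and reproducible.

## A complete run

```{r example}
dir <- file.path(tempdir(), "fx")
m <- generate_fixture(fixture_spec(n_genes = 8, n_phenotypes = 2, seed = 7),
                      dir)
phewas <- read_catalog(m$files$phewas, "PHEWAS")
gwas <- read_catalog(m$files$gwas, "GWAS")
prov <- load_providers(m$files$associations, m$files$druggability,
                       m$files$edges)
tabs <- prioritize("phenotype 01", phewas, gwas, prov)
head(tabs$ALL)
```

The same run is reproduced byte-for-byte by the `prioritize` subcommand of
the command-line interface (`run_stargazer()`), and agrees with the
generator's independent ground truth:

```{r oracle}
gt <- read.csv(m$files$ground_truth)
gt1 <- subset(gt, phenotype == "phenotype 01" & context == "ALL")
max(abs(sort(gt1$stargazer_score) - sort(tabs$ALL$stargazer_score)))
```
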
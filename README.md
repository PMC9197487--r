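# stargazeR

Multi-evidence drug target prioritization: rank the genes associated with
a phenotype by how attractive they are as drug repositioning candidates.

## The problem and the score

Drug repositioning starts from a disease and asks which of its associated
genes are worth pursuing as targets. Evidence for that decision is
scattered across heterogeneous sources: phenome-wide and genome-wide
association studies report odds ratios per variant; gene–disease
association databases score targets in [0, 1]; druggability resources tag
genes with target development levels (TDL: Tclin > Tchem > Tbio > Tdark);
and protein–protein interaction networks describe each gene's
connectivity.

stargazeR integrates these into five per-gene feature scores, each
normalized to [0, 1] within the phenotype's gene set:

1. **Odds-ratio score** — per record, risk alleles (OR ≥ 1) contribute OR
   and protective alleles (OR < 1) contribute 1 − OR; values are averaged
   over the studies of each gene, then divided by the largest gene mean.
2. **Association score** — the gene–disease association score, divided by
   the largest score in the set.
3. **Intersection indicator** — 1 if the gene has significant records in
   both the PheWAS-style and the GWAS-style catalog, else 0.
4. **Druggability score** — the number of distinct TDL labels excluding
   Tdark (so {Tbio, Tclin, Tdark} counts 2), divided by the largest count.
5. **Network degree score** — the gene's degree in the interaction network
   built over the phenotype's gene set (edges kept at combined confidence
   ≥ 400 by default), divided by the maximum degree.

The **StarGazer score** of a gene is the arithmetic mean of the five
features, so it lives in [0, 1] and equals 1 only when a gene leads the
set on every feature. Genes are ranked by it, in three tables: all
alleles, risk alleles only, and protective alleles only. Associations are
filtered at a significance threshold (p ≤ 0.05 by default) before any
scoring.

## Worked example

Everything is file-backed; the bundled generator writes a complete
synthetic evidence set (PheWAS CSV, GWAS TSV, association scores,
druggability table, interaction edges) plus an independently computed
ground-truth table:

```r
library(stargazeR)
run_stargazer(c("simulate", "--n-genes", "8", "--n-phenotypes", "2",
                "--seed", "7", "--out", "demo"))
run_stargazer(c("prioritize", "--phenotype", "phenotype 01",
                "--phewas", "demo/phewas.csv", "--gwas", "demo/gwas.tsv",
                "--associations", "demo/associations.tsv",
                "--druggability", "demo/druggability.tsv",
                "--edges", "demo/edges.tsv", "--out", "demo_out"))
```

`demo_out/prioritize_all.csv` then begins:

```
Gene Name,StarGazer Score,Odds-Ratio,OpenTargets Associations,Indicator Phe/GWAS,Druggability Score,Network Degree Score
GENE005,0.800,1.000,0.000,1.000,1.000,1.000
GENE004,0.391,0.624,1.000,0.000,0.000,0.333
GENE007,0.364,0.247,0.905,0.000,0.333,0.333
GENE001,0.250,0.250,0.000,0.000,0.667,0.333
```

GENE005 ranks first (score 0.800 = mean of 1, 0, 1, 1, 1): it has the
strongest averaged odds-ratio evidence, appears in both catalogs, leads on
druggability and connectivity, but has no gene–disease association score.
Matching `prioritize_risk.csv` / `prioritize_protective.csv` tables are
written alongside.

The same subcommand surface covers the other exploration modes — `gene`,
`variant`, `phewas`, `gwas`, `union`, `intersection`, `ppi` — each writing
a CSV view; the equivalent R functions (`prioritize()`, `gene_view()`,
`phenotype_view()`, `ppi_view()`, ...) return data frames. A thin wrapper
script lives at `inst/scripts/stargazer`.

As a regression surface, `insomnia_example()` returns a published 30-gene
insomnia prioritization table; the mean of its five feature columns
reproduces the published aggregate scores.

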
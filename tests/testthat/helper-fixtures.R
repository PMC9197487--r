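# Shared fixture builders: small catalogs and provider tables written to
# temp files in the dialects the readers expect.

write_phewas_csv <- function(df, path = tempfile(fileext = ".csv")) {
  names(df) <- c("snp", "gene_name", "phewas phenotype", "odds-ratio",
                 "p")[seq_along(df)]
  utils::write.csv(df, path, row.names = FALSE)
  path
}

write_gwas_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  names(df) <- c("SNPS", "MAPPED_GENE", "DISEASE/TRAIT", "OR or BETA",
                 "P-VALUE")[seq_along(df)]
  utils::write.table(df, path, sep = "\t", row.names = FALSE)
  path
}

mk_phewas <- function(variant, gene, phenotype, or, p) {
  read_catalog(write_phewas_csv(
    data.frame(variant, gene, phenotype, or, p, stringsAsFactors = FALSE)),
    "PHEWAS")
}

mk_gwas <- function(variant, gene, phenotype, or, p) {
  read_catalog(write_gwas_tsv(
    data.frame(variant, gene, phenotype, or, p, stringsAsFactors = FALSE)),
    "GWAS")
}

mk_providers <- function(assoc = NULL, drugg = NULL, edges = NULL) {
  if (is.null(assoc)) {
    assoc <- data.frame(gene = "ZZZNONE", disease = "none", score = 0)
  }
  if (is.null(drugg)) {
    drugg <- data.frame(gene = "ZZZNONE", levels = "")
  }
  if (is.null(edges)) {
    edges <- data.frame(protein1 = character(0), protein2 = character(0),
                        combined_score = numeric(0))
  }
  fa <- tempfile(fileext = ".tsv")
  utils::write.table(assoc, fa, sep = "\t", row.names = FALSE)
  fd <- tempfile(fileext = ".tsv")
  utils::write.table(drugg, fd, sep = "\t", row.names = FALSE)
  fe <- tempfile(fileext = ".tsv")
  names(edges) <- c("protein1", "protein2", "combined_score")
  utils::write.table(edges, fe, sep = "\t", row.names = FALSE)
  load_providers(fa, fd, fe)
}

# Three-gene worked example used across scoring and ranking tests; the
# expected feature values are recomputed by hand in the tests that use it.
hand_fixture <- function() {
  phewas <- mk_phewas(
    variant = c("rs1", "rs2", "rs3", "rs4"),
    gene = c("GENEA", "GENEA", "GENEB", "GENEC"),
    phenotype = "Insomnia",
    or = c(2.0, 3.0, 1.25, 0.5),
    p = c(0.01, 0.04, 0.02, 0.03))
  gwas <- mk_gwas(
    variant = c("rs3", "rs5"),
    gene = c("GENEB", "GENEC"),
    phenotype = "insomnia",
    or = c(1.25, 0.8),
    p = c(0.02, 0.2))
  providers <- mk_providers(
    assoc = data.frame(gene = c("GENEA", "GENEB"),
                       disease = "Insomnia",
                       score = c(0.8, 0.2), stringsAsFactors = FALSE),
    drugg = data.frame(gene = c("GENEA", "GENEB", "GENEC"),
                       levels = c("Tclin;Tbio", "Tbio;Tdark", ""),
                       stringsAsFactors = FALSE),
    edges = data.frame(protein1 = c("GENEA", "GENEB", "GENEA"),
                       protein2 = c("GENEB", "GENEC", "GENEC"),
                       combined_score = c(900, 450, 100),
                       stringsAsFactors = FALSE))
  list(phewas = phewas, gwas = gwas, providers = providers)
}

# Run the full pipeline on a generated fixture and compare every feature
# and score against the generator's independent ground truth; returns the
# largest absolute discrepancy observed.
fixture_max_discrepancy <- function(spec) {
  dir <- tempfile("fx")
  m <- generate_fixture(spec, dir)
  phewas <- read_catalog(m$files$phewas, "PHEWAS")
  gwas <- read_catalog(m$files$gwas, "GWAS")
  prov <- load_providers(m$files$associations, m$files$druggability,
                         m$files$edges)
  gt <- utils::read.csv(m$files$ground_truth, stringsAsFactors = FALSE)
  worst <- 0
  for (phen in unique(gt$phenotype)) {
    tabs <- prioritize(phen, phewas, gwas, prov)
    for (ctx in names(tabs)) {
      g <- gt[gt$phenotype == phen & gt$context == ctx, , drop = FALSE]
      tab <- tabs[[ctx]]
      if (!identical(sort(g$gene), sort(tab$gene))) return(Inf)
      g <- g[order(g$gene), , drop = FALSE]
      tab <- tab[order(tab$gene), , drop = FALSE]
      cols <- c("or_score", "opentargets_score", "intersection_indicator",
                "druggability_score", "network_degree_score",
                "stargazer_score")
      worst <- max(worst, abs(as.matrix(g[cols]) - as.matrix(tab[cols])))
    }
  }
  unlink(dir, recursive = TRUE)
  worst
}
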
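# The five per-gene feature scores for a phenotype's gene set, each
# normalized to [0, 1] within the current allele-class context.

context_subset <- function(records, context = c("ALL", "RISK", "PROTECTIVE")) {
  context <- match.arg(context)
  if (context == "ALL") return(records)
  cls <- classify_allele(records)
  records[cls == context, , drop = FALSE]
}

#' Odds-ratio magnitude of an association
#'
#' Risk alleles (OR >= 1) contribute the odds ratio as is; protective
#' alleles (OR < 1) contribute `1 - OR`, since for them a lower ratio means
#' a stronger association. In the `ALL` context each record contributes its
#' class-appropriate magnitude.
#'
#' @param odds_ratio Positive numeric vector.
#' @param context `"ALL"`, `"RISK"` or `"PROTECTIVE"`. Records incompatible
#'   with a restricted context get `NA` (they are excluded, not an error).
#' @return Numeric vector of non-negative magnitudes (`NA` if excluded).
#' @export
#' @examples
#' or_magnitude(c(2.5, 0.9), "ALL") # 2.5 and 0.1
or_magnitude <- function(odds_ratio, context = c("ALL", "RISK",
                                                 "PROTECTIVE")) {
  context <- match.arg(context)
  cls <- classify_allele(odds_ratio)
  mag <- ifelse(cls == "RISK", odds_ratio, 1 - odds_ratio)
  if (context != "ALL") mag[cls != context] <- NA_real_
  mag
}

# Divide by the maximum; an all-zero (or empty) vector stays all zero
# rather than NaN so scores remain in [0, 1] and aggregate safely.
normalize_max <- function(x) {
  if (!length(x)) return(x)
  m <- max(x)
  if (m <= 0) return(x * 0)
  x / m
}

#' Per-gene normalized odds-ratio score
#'
#' For every gene, the mean odds-ratio magnitude over its compatible
#' records (multiple studies of the same gene are averaged), divided by the
#' maximum mean in the gene set. Genes with no compatible record score 0.
#'
#' @param records Post-filter `sg_records` for one phenotype.
#' @param context Allele-class context.
#' @param genes Gene universe; defaults to the genes present in the
#'   context-compatible records.
#' @return Named numeric vector of scores in \[0, 1\].
#' @export
gene_or_score <- function(records, context = "ALL", genes = NULL) {
  sub <- context_subset(records, context)
  if (is.null(genes)) genes <- sg_sort(unique(sub$gene))
  genes <- norm_gene(genes)
  out <- stats::setNames(numeric(length(genes)), genes)
  if (nrow(sub)) {
    mag <- or_magnitude(sub$odds_ratio, context)
    means <- tapply(mag, sub$gene, mean)
    hit <- intersect(genes, names(means))
    out[hit] <- means[hit]
  }
  normalize_max(out)
}

#' Normalized gene-disease association feature
#'
#' Raw association scores (already in \[0, 1\]) are divided by the maximum
#' raw score across the gene set; an all-zero set stays all zero.
#'
#' @param raw_scores Named numeric vector of raw scores per gene.
#' @return Named numeric vector of normalized scores.
#' @export
opentargets_feature <- function(raw_scores) {
  if (any(raw_scores < 0 | raw_scores > 1)) {
    stop("raw association scores must lie in [0, 1]")
  }
  normalize_max(raw_scores)
}

#' PheWAS-GWAS intersection indicator
#'
#' A gene scores 1 when it appears in the post-filter gene sets of both
#' sources for the phenotype, else 0.
#'
#' @param genes Gene symbols to score.
#' @param phewas_genes,gwas_genes Post-filter gene sets per source.
#' @return Named numeric vector of 0/1 indicators.
#' @export
intersection_feature <- function(genes, phewas_genes, gwas_genes) {
  genes <- norm_gene(genes)
  both <- intersect(norm_gene(phewas_genes), norm_gene(gwas_genes))
  stats::setNames(as.numeric(genes %in% both), genes)
}

#' Count distinct druggability levels, excluding Tdark
#'
#' Tdark means the druggability is unknown, so it never adds to the count:
#' a target labeled Tbio + Tclin + Tdark scores 2 (1 + 1 + 0).
#'
#' @param levels Character vector of TDL labels, or an `sg_druggability`
#'   profile.
#' @return Integer count in 0..3.
#' @export
#' @examples
#' druggability_count(c("Tbio", "Tclin", "Tdark")) # 2
druggability_count <- function(levels) {
  if (inherits(levels, "sg_druggability")) levels <- levels$levels
  bad <- setdiff(unique(levels), .sg_tdl_levels)
  if (length(bad)) {
    stop("unrecognized druggability label(s): ", paste(bad, collapse = ", "))
  }
  length(setdiff(unique(levels), "Tdark"))
}

#' Normalized druggability feature
#'
#' Raw level counts divided by the highest count in the gene set; an
#' all-zero set stays all zero.
#'
#' @param counts Named integer vector of druggability counts per gene.
#' @return Named numeric vector of scores in \[0, 1\].
#' @export
druggability_feature <- function(counts) {
  stats::setNames(normalize_max(as.numeric(counts)), names(counts))
}

#' Normalized network degree feature
#'
#' Each node's degree (number of distinct neighbours) as a ratio of the
#' highest node degree in the network; a network with no edges scores all
#' nodes 0.
#'
#' @param network An [igraph::igraph] built over the phenotype gene set.
#' @return Named numeric vector of degree ratios in \[0, 1\].
#' @export
network_degree_feature <- function(network) {
  deg <- igraph::degree(network)
  normalize_max(deg)
}

#' Compute the five feature scores for a phenotype's gene set
#'
#' Assembles, for the post-significance-filter gene set of the phenotype in
#' the given allele-class context, the five normalized features in output
#' column order: odds-ratio score, gene-disease association score,
#' PheWAS/GWAS intersection indicator, druggability score and network
#' degree score. Normalization denominators are computed within the current
#' context's gene set, so ALL/RISK/PROTECTIVE tables are scored
#' independently.
#'
#' @param phenotype Trait label (matched case-insensitively).
#' @param phewas,gwas `sg_catalog` tables.
#' @param providers An `sg_providers` bundle.
#' @param alpha Significance threshold, default 0.05.
#' @param context `"ALL"`, `"RISK"` or `"PROTECTIVE"`.
#' @param min_confidence Minimum interaction confidence, default 400.
#' @return A data.frame with columns `gene`, `or_score`,
#'   `opentargets_score`, `intersection_indicator`, `druggability_score`,
#'   `network_degree_score`; one row per gene, empty if no record survives.
#' @export
compute_feature_vectors <- function(phenotype, phewas, gwas, providers,
                                    alpha = 0.05, context = "ALL",
                                    min_confidence = 400) {
  stopifnot(inherits(providers, "sg_providers"))
  ph <- filter_significant(records_for_phenotype(phewas, phenotype), alpha)
  gw <- filter_significant(records_for_phenotype(gwas, phenotype), alpha)
  recs <- rbind(as.data.frame(ph), as.data.frame(gw))
  sub <- context_subset(recs, context)
  genes <- sg_sort(unique(sub$gene))
  if (!length(genes)) {
    return(data.frame(gene = character(0), or_score = numeric(0),
                      opentargets_score = numeric(0),
                      intersection_indicator = numeric(0),
                      druggability_score = numeric(0),
                      network_degree_score = numeric(0),
                      stringsAsFactors = FALSE))
  }

  or_score <- gene_or_score(sub, context, genes)
  raw_ot <- stats::setNames(
    association_score(providers$association, genes, phenotype), genes)
  ot <- opentargets_feature(raw_ot)
  inter <- intersection_feature(
    genes,
    unique(sub$gene[sub$source == "PHEWAS"]),
    unique(sub$gene[sub$source == "GWAS"]))
  counts <- vapply(genes, function(g)
    druggability_count(druggability_levels(providers$druggability, g)),
    numeric(1))
  drug <- druggability_feature(counts)
  net <- build_network(providers$edges, genes, min_confidence)
  deg <- network_degree_feature(net)[genes]

  out <- data.frame(gene = genes,
                    or_score = as.numeric(or_score[genes]),
                    opentargets_score = as.numeric(ot[genes]),
                    intersection_indicator = as.numeric(inter[genes]),
                    druggability_score = as.numeric(drug[genes]),
                    network_degree_score = as.numeric(deg),
                    stringsAsFactors = FALSE, row.names = NULL)
  validate_features(out)
  out
}
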
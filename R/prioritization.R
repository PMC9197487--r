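# Aggregation of feature vectors into StarGazer scores, ranked tables per
# allele-class context, and the query logic behind the exploration modes.

# Table 1-style CSV header, in order.
.sg_ranked_header <- c("Gene Name", "StarGazer Score", "Odds-Ratio",
                       "OpenTargets Associations", "Indicator Phe/GWAS",
                       "Druggability Score", "Network Degree Score")

#' Aggregate the five feature scores into a StarGazer score
#'
#' The StarGazer score is the arithmetic mean of the five normalized
#' feature scores, so five features all at their maximum give exactly 1.
#' Tabular output renders it to 3 decimals; full precision is kept
#' internally.
#'
#' @param features A named numeric vector of length 5 (see
#'   [feature_vector()]), or a data.frame containing the five feature
#'   columns (one score per row).
#' @return Numeric score(s) in \[0, 1\].
#' @export
#' @examples
#' stargazer_score(feature_vector(0.725, 0, 0, 1, 0.556)) # 0.4562
stargazer_score <- function(features) {
  validate_features(features)
  if (is.data.frame(features)) {
    rowMeans(features[.sg_feature_cols])
  } else {
    mean(unclass(features)[.sg_feature_cols])
  }
}

#' Rank a phenotype's candidate targets
#'
#' For each allele-class context (ALL, RISK, PROTECTIVE), computes the five
#' feature scores over the post-filter gene set, aggregates them into
#' StarGazer scores and sorts descending (ties broken by gene symbol,
#' ascending). A context with no qualifying records yields an empty table.
#'
#' @inheritParams compute_feature_vectors
#' @return Named list of three `sg_ranked` data.frames (`ALL`, `RISK`,
#'   `PROTECTIVE`), each with columns `gene`, `stargazer_score` and the five
#'   feature columns, plus attributes `phenotype`, `context`, `alpha`.
#' @export
prioritize <- function(phenotype, phewas, gwas, providers, alpha = 0.05,
                       min_confidence = 400) {
  out <- lapply(.sg_contexts, function(ctx) {
    fv <- compute_feature_vectors(phenotype, phewas, gwas, providers,
                                  alpha = alpha, context = ctx,
                                  min_confidence = min_confidence)
    score <- if (nrow(fv)) stargazer_score(fv) else numeric(0)
    tab <- cbind(data.frame(gene = fv$gene, stargazer_score = score,
                            stringsAsFactors = FALSE),
                 fv[.sg_feature_cols])
    ord <- order(-tab$stargazer_score, tab$gene, method = "radix")
    tab <- tab[ord, , drop = FALSE]
    row.names(tab) <- NULL
    structure(tab, class = c("sg_ranked", "data.frame"),
              phenotype = phenotype, context = ctx, alpha = alpha)
  })
  names(out) <- .sg_contexts
  if (!nrow(out$ALL)) {
    sg_log("INFO", sprintf("no associations for '%s' at p <= %s",
                           phenotype, alpha))
  }
  out
}

#' Write a ranked table as CSV
#'
#' Uses the canonical column header (Gene Name, StarGazer Score, Odds-Ratio,
#' OpenTargets Associations, Indicator Phe/GWAS, Druggability Score,
#' Network Degree Score) and renders every score to 3 decimal places.
#'
#' @param ranked An `sg_ranked` table from [prioritize()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ranked_csv <- function(ranked, path) {
  out <- data.frame(ranked$gene,
                    sprintf("%.3f", ranked$stargazer_score),
                    sprintf("%.3f", ranked$or_score),
                    sprintf("%.3f", ranked$opentargets_score),
                    sprintf("%.3f", ranked$intersection_indicator),
                    sprintf("%.3f", ranked$druggability_score),
                    sprintf("%.3f", ranked$network_degree_score),
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(ranked)) out <- out[0, , drop = FALSE]
  names(out) <- .sg_ranked_header
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

view_records <- function(phewas, gwas, alpha, field, value) {
  recs <- rbind(as.data.frame(filter_significant(phewas, alpha)),
                as.data.frame(filter_significant(gwas, alpha)))
  recs <- recs[norm_gene(recs[[field]]) == norm_gene(value), , drop = FALSE]
  if (nrow(recs)) {
    recs$allele_class <- classify_allele(recs)
    recs <- recs[order(-recs$odds_ratio, recs$phenotype, recs$variant_id,
                       method = "radix"), , drop = FALSE]
  } else {
    recs$allele_class <- character(0)
  }
  row.names(recs) <- NULL
  recs[c("phenotype", "variant_id", "gene", "odds_ratio", "p_value",
         "allele_class", "source", "study_id")]
}

#' Gene exploration mode
#'
#' All post-filter associations of a gene across both catalogs, one row per
#' (variant, phenotype, study), ordered by descending odds ratio and
#' annotated with the allele class.
#'
#' @param gene Gene symbol.
#' @param phewas,gwas `sg_catalog` tables.
#' @param alpha Significance threshold.
#' @return Data.frame view; empty for an unknown gene.
#' @export
gene_view <- function(gene, phewas, gwas, alpha = 0.05) {
  view_records(phewas, gwas, alpha, "gene", gene)
}

#' Variant exploration mode
#'
#' As [gene_view()] but keyed by rsID.
#'
#' @param rsid Variant identifier.
#' @inheritParams gene_view
#' @return Data.frame view; empty for an unknown variant.
#' @export
variant_view <- function(rsid, phewas, gwas, alpha = 0.05) {
  view_records(phewas, gwas, alpha, "variant_id", rsid)
}

# Highest druggability level of a gene, for the per-category summary.
.sg_tdl_order <- c("Tclin", "Tchem", "Tbio", "Tdark")
top_tdl <- function(levels) {
  hit <- .sg_tdl_order[.sg_tdl_order %in% levels]
  if (length(hit)) hit[1L] else "None"
}

#' Phenotype exploration modes (PheWAS / GWAS / union / intersection)
#'
#' Post-filter records of a phenotype under one of four source modes:
#' `PHEWAS` or `GWAS` return that source's records, `UNION` their
#' concatenation, and `INTERSECTION` only variants whose rsID appears in
#' post-filter records of both sources. Every row is annotated with the
#' gene's druggability levels; the attached `druggability_summary` reports,
#' over distinct genes, the fraction whose highest level falls in each
#' category (Tclin, Tchem, Tbio, Tdark, None).
#'
#' @param trait Trait label.
#' @param phewas,gwas `sg_catalog` tables.
#' @param providers An `sg_providers` bundle.
#' @param alpha Significance threshold.
#' @param source_mode One of `"PHEWAS"`, `"GWAS"`, `"UNION"`,
#'   `"INTERSECTION"`.
#' @return Data.frame with columns `variant_id`, `gene`, `odds_ratio`,
#'   `p_value`, `allele_class`, `source`, `druggability`; attribute
#'   `druggability_summary` is a data.frame (category, n_genes, percent).
#' @export
phenotype_view <- function(trait, phewas, gwas, providers, alpha = 0.05,
                           source_mode = c("PHEWAS", "GWAS", "UNION",
                                           "INTERSECTION")) {
  source_mode <- match.arg(source_mode)
  ph <- filter_significant(records_for_phenotype(phewas, trait), alpha)
  gw <- filter_significant(records_for_phenotype(gwas, trait), alpha)
  recs <- switch(source_mode,
    PHEWAS = as.data.frame(ph),
    GWAS = as.data.frame(gw),
    UNION = rbind(as.data.frame(ph), as.data.frame(gw)),
    INTERSECTION = {
      both <- intersect(ph$variant_id, gw$variant_id)
      u <- rbind(as.data.frame(ph), as.data.frame(gw))
      u[u$variant_id %in% both, , drop = FALSE]
    })
  recs$allele_class <- if (nrow(recs)) classify_allele(recs) else character(0)
  recs$druggability <- vapply(recs$gene, function(g)
    paste(druggability_levels(providers$druggability, g), collapse = ";"),
    character(1), USE.NAMES = FALSE)
  recs <- recs[order(-recs$odds_ratio, recs$gene, recs$variant_id,
                     method = "radix"), , drop = FALSE]
  row.names(recs) <- NULL
  out <- recs[c("variant_id", "gene", "odds_ratio", "p_value",
                "allele_class", "source", "druggability")]

  genes <- unique(recs$gene)
  cat_per_gene <- vapply(genes, function(g)
    top_tdl(druggability_levels(providers$druggability, g)), character(1))
  cats <- c(.sg_tdl_order, "None")
  n <- vapply(cats, function(cc) sum(cat_per_gene == cc), numeric(1))
  summary <- data.frame(category = cats, n_genes = as.integer(n),
                        percent = if (length(genes))
                          round(100 * n / length(genes), 2) else n * 0,
                        row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "druggability_summary") <- summary
  out
}

#' Protein-protein interaction exploration mode
#'
#' Builds the interaction networks over the phenotype's post-filter gene
#' sets for the ALL, RISK and PROTECTIVE contexts, and tabulates each
#' node's raw degree and degree-ratio score.
#'
#' @inheritParams phenotype_view
#' @param min_confidence Minimum interaction confidence, default 400.
#' @return List with `networks` (list of three [igraph::igraph]s) and
#'   `degrees` (data.frame: context, gene, degree, degree_score).
#' @export
ppi_view <- function(trait, phewas, gwas, providers, alpha = 0.05,
                     min_confidence = 400) {
  ph <- filter_significant(records_for_phenotype(phewas, trait), alpha)
  gw <- filter_significant(records_for_phenotype(gwas, trait), alpha)
  recs <- rbind(as.data.frame(ph), as.data.frame(gw))
  networks <- lapply(.sg_contexts, function(ctx) {
    genes <- unique(context_subset(recs, ctx)$gene)
    build_network(providers$edges, genes, min_confidence)
  })
  names(networks) <- .sg_contexts
  degrees <- do.call(rbind, lapply(.sg_contexts, function(ctx) {
    g <- networks[[ctx]]
    deg <- igraph::degree(g)
    data.frame(context = rep(ctx, length(deg)),
               gene = names(deg), degree = as.integer(deg),
               degree_score = as.numeric(normalize_max(deg)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  list(networks = networks, degrees = degrees)
}
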
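# Core domain types: association records, allele classes, druggability
# profiles and feature vectors. Records are rows of a validated data.frame
# rather than individual objects, matching how the catalogs arrive on disk.

.sg_sources <- c("PHEWAS", "GWAS")
.sg_contexts <- c("ALL", "RISK", "PROTECTIVE")
.sg_tdl_levels <- c("Tclin", "Tchem", "Tbio", "Tdark")
.sg_record_cols <- c("variant_id", "gene", "phenotype", "odds_ratio",
                     "p_value", "source", "study_id")
.sg_feature_cols <- c("or_score", "opentargets_score",
                      "intersection_indicator", "druggability_score",
                      "network_degree_score")

#' Construct a validated table of variant-phenotype association records
#'
#' One row per association between a variant allele and a phenotype, as
#' reported by a PheWAS- or GWAS-style source: odds ratio, p-value, the
#' mapped gene and an optional study identifier. Gene symbols are normalized
#' with [norm_gene()]; phenotype labels keep their original casing (matching
#' is done through [norm_trait()]).
#'
#' @param variant_id Character, rsID-style variant identifiers.
#' @param gene Character, gene symbols (normalized on construction).
#' @param phenotype Character, free-text trait labels.
#' @param odds_ratio Positive numeric effect sizes.
#' @param p_value Numeric in \[0, 1\].
#' @param source `"PHEWAS"` or `"GWAS"` (recycled if length 1).
#' @param study_id Optional character study identifiers.
#' @return A `data.frame` of class `sg_records`.
#' @export
association_records <- function(variant_id, gene, phenotype, odds_ratio,
                                p_value, source, study_id = NA_character_) {
  n <- length(variant_id)
  source <- rep_len(as.character(source), n)
  study_id <- rep_len(as.character(study_id), n)
  rec <- data.frame(
    variant_id = trimws(as.character(variant_id)),
    gene = norm_gene(gene),
    phenotype = gsub("[[:space:]]+", " ", trimws(as.character(phenotype))),
    odds_ratio = as.numeric(odds_ratio),
    p_value = as.numeric(p_value),
    source = source,
    study_id = study_id,
    stringsAsFactors = FALSE
  )
  validate_records(rec)
  class(rec) <- c("sg_records", "data.frame")
  rec
}

validate_records <- function(rec) {
  stopifnot(is.data.frame(rec), all(.sg_record_cols %in% names(rec)))
  bad_src <- !rec$source %in% .sg_sources
  if (any(bad_src)) {
    stop("invalid source tag(s): ", paste(unique(rec$source[bad_src]),
                                          collapse = ", "))
  }
  bad_or <- !is.finite(rec$odds_ratio) | rec$odds_ratio <= 0
  if (any(bad_or)) {
    i <- which(bad_or)[1L]
    stop(sprintf("non-positive odds ratio for record %s (%s / %s): %s",
                 i, rec$variant_id[i], rec$gene[i], rec$odds_ratio[i]))
  }
  bad_p <- !is.finite(rec$p_value) | rec$p_value < 0 | rec$p_value > 1
  if (any(bad_p)) {
    i <- which(bad_p)[1L]
    stop(sprintf("p-value outside [0, 1] for record %s (%s): %s",
                 i, rec$variant_id[i], rec$p_value[i]))
  }
  if (any(!nzchar(rec$gene))) stop("empty gene symbol after normalization")
  if (any(!nzchar(norm_trait(rec$phenotype)))) {
    stop("empty phenotype label after normalization")
  }
  invisible(rec)
}

#' Classify alleles as risk or protective
#'
#' An allele is a risk allele when its odds ratio is >= 1 (more associated
#' with occurrence of the phenotype; the boundary OR = 1 counts as risk) and
#' protective when the odds ratio is < 1.
#'
#' @param x A numeric vector of odds ratios, or an `sg_records` table.
#' @return Character vector, `"RISK"` or `"PROTECTIVE"` per element/row.
#' @export
#' @examples
#' classify_allele(c(2.3, 1, 0.7))
classify_allele <- function(x) {
  or <- if (is.data.frame(x)) x$odds_ratio else as.numeric(x)
  bad <- !is.finite(or) | or <= 0
  if (any(bad)) {
    i <- which(bad)[1L]
    id <- if (is.data.frame(x)) x$variant_id[i] else paste("element", i)
    stop(sprintf("cannot classify %s: non-positive odds ratio %s", id, or[i]))
  }
  ifelse(or >= 1, "RISK", "PROTECTIVE")
}

#' Construct a feature vector of the five normalized target scores
#'
#' The five features, in the order they appear in prioritization output:
#' odds-ratio score, gene-disease association score, PheWAS/GWAS
#' intersection indicator, druggability score and network degree score.
#' Every component must lie in \[0, 1\].
#'
#' @param or_score,opentargets_score,druggability_score,network_degree_score
#'   Numeric in \[0, 1\].
#' @param intersection_indicator 0 or 1.
#' @return Named numeric vector of length 5, class `sg_features`.
#' @export
feature_vector <- function(or_score, opentargets_score,
                           intersection_indicator, druggability_score,
                           network_degree_score) {
  fv <- c(or_score = or_score, opentargets_score = opentargets_score,
          intersection_indicator = intersection_indicator,
          druggability_score = druggability_score,
          network_degree_score = network_degree_score)
  validate_features(fv)
  class(fv) <- "sg_features"
  fv
}

validate_features <- function(fv) {
  if (is.data.frame(fv)) {
    stopifnot(all(.sg_feature_cols %in% names(fv)))
    v <- unlist(fv[.sg_feature_cols], use.names = FALSE)
  } else {
    if (!all(.sg_feature_cols %in% names(fv))) {
      stop("feature vector needs the five named components: ",
           paste(.sg_feature_cols, collapse = ", "))
    }
    v <- unname(unclass(fv)[.sg_feature_cols])
  }
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
    stop("feature scores must all lie in [0, 1]; got: ",
         paste(signif(v[!is.finite(v) | v < 0 | v > 1], 4), collapse = ", "))
  }
  ind <- if (is.data.frame(fv)) fv$intersection_indicator else
    fv[["intersection_indicator"]]
  if (!all(ind %in% c(0, 1))) {
    stop("intersection indicator must be 0 or 1")
  }
  invisible(fv)
}

#' Construct a druggability profile
#'
#' The set of target development level (TDL) labels attached to a gene:
#' Tclin (approved-drug target), Tchem (active compounds known), Tbio (weak
#' evidence), Tdark (unknown). An empty set is allowed and treated as the
#' "None" category.
#'
#' @param gene Gene symbol.
#' @param levels Character vector, subset of
#'   `c("Tclin", "Tchem", "Tbio", "Tdark")`.
#' @return List of class `sg_druggability` with elements `gene`, `levels`.
#' @export
druggability_profile <- function(gene, levels = character()) {
  levels <- unique(as.character(levels))
  bad <- setdiff(levels, .sg_tdl_levels)
  if (length(bad)) {
    stop("unrecognized druggability label(s): ", paste(bad, collapse = ", "))
  }
  structure(list(gene = norm_gene(gene), levels = levels),
            class = "sg_druggability")
}
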
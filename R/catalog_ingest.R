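# Ingest of PheWAS- and GWAS-style association tables, the harmonized
# phenotype list, and the significance filter.

# Default column names follow the public PheWAS-catalog CSV export and a
# minimal GWAS-catalog dialect; both are overridable via column_map.
.sg_default_columns <- list(
  PHEWAS = c(variant = "snp", gene = "gene_name",
             phenotype = "phewas phenotype", odds_ratio = "odds-ratio",
             p_value = "p", study_id = "study"),
  GWAS = c(variant = "SNPS", gene = "MAPPED_GENE",
           phenotype = "DISEASE/TRAIT", odds_ratio = "OR or BETA",
           p_value = "P-VALUE", study_id = "STUDY ACCESSION")
)

sg_read_table <- function(path, delim = NULL, allow_empty = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) {
    delim <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab")) "\t"
             else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character",
                          stringsAsFactors = FALSE, fill = TRUE)
  if (nrow(df) == 0L && !allow_empty) stop("empty table: ", path)
  df
}

#' Read a PheWAS- or GWAS-style association catalog
#'
#' Parses a delimited association table into a validated record table. Rows
#' whose odds ratio or p-value is missing or unparseable are dropped and
#' counted in the attached load report; GWAS rows whose effect value is
#' non-positive are treated as beta coefficients (the scoring framework is
#' defined on odds ratios only) and dropped likewise. Fields mapping a
#' variant to several genes (e.g. `"GENE1 - GENE2"`) are split into one
#' record per gene.
#'
#' @param path Path to a CSV/TSV file with a header row. The delimiter is
#'   inferred from the extension (`.tsv`/`.tab` means tab) unless `delim`
#'   is given.
#' @param source `"PHEWAS"` or `"GWAS"`; sets the default column names.
#' @param column_map Optional named character vector overriding the default
#'   column names; names among `variant`, `gene`, `phenotype`, `odds_ratio`,
#'   `p_value`, `study_id`.
#' @param delim Optional field delimiter override.
#' @return An `sg_catalog`: an `sg_records` data.frame with attributes
#'   `source` and `load_report` (list with `n_read`, `n_dropped`, `reasons`,
#'   `dropped_rows`).
#' @export
read_catalog <- function(path, source = c("PHEWAS", "GWAS"),
                         column_map = NULL, delim = NULL) {
  source <- match.arg(source)
  cols <- .sg_default_columns[[source]]
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(cols))
    if (length(bad)) stop("unknown column_map keys: ",
                          paste(bad, collapse = ", "))
    cols[names(column_map)] <- column_map
  }
  df <- sg_read_table(path, delim)
  required <- cols[c("variant", "gene", "phenotype", "odds_ratio", "p_value")]
  missing <- required[!required %in% names(df)]
  if (length(missing)) {
    stop(sprintf("missing required column(s) %s; available headers: %s",
                 paste(missing, collapse = ", "),
                 paste(names(df), collapse = ", ")))
  }

  or <- sg_as_num(df[[cols[["odds_ratio"]]]])
  p <- sg_as_num(df[[cols[["p_value"]]]])
  reasons <- character(0)
  drop <- rep(FALSE, nrow(df))

  bad_or <- !is.finite(or)
  bad_p <- !is.finite(p) | p < 0 | p > 1
  nonpos <- is.finite(or) & or <= 0
  drop <- bad_or | bad_p | nonpos
  if (any(bad_or)) reasons["missing or unparseable odds ratio"] <- sum(bad_or)
  if (any(bad_p)) reasons["missing or invalid p-value"] <- sum(bad_p)
  if (any(nonpos))

    reasons["non-positive effect value (beta, not an odds ratio)"] <-
      sum(nonpos)

  dropped_rows <- which(drop)
  for (r in names(reasons)) {
    sg_log("WARN", sprintf("dropped %s rows: %s", reasons[[r]], r))
  }

  keep <- !drop
  genes <- as.character(df[[cols[["gene"]]]])[keep]
  gene_list <- strsplit(genes, "[;,]| - ")
  reps <- lengths(gene_list)
  idx <- rep(which(keep), reps)
  study <- if (cols[["study_id"]] %in% names(df)) {
    as.character(df[[cols[["study_id"]]]])
  } else {
    rep(NA_character_, nrow(df))
  }
  study[!is.na(study) & !nzchar(trimws(study))] <- NA_character_
  rec <- association_records(
    variant_id = as.character(df[[cols[["variant"]]]])[idx],
    gene = unlist(gene_list, use.names = FALSE),
    phenotype = as.character(df[[cols[["phenotype"]]]])[idx],
    odds_ratio = or[idx],
    p_value = p[idx],
    source = source,
    study_id = study[idx]
  )
  structure(rec,
            class = c("sg_catalog", class(rec)),
            source = source,
            load_report = list(n_read = nrow(df),
                               n_dropped = length(dropped_rows),
                               reasons = as.list(reasons),
                               dropped_rows = dropped_rows))
}

#' Write a catalog back to disk in its source's default dialect
#'
#' @param catalog An `sg_catalog`.
#' @param path Output file; extension selects the delimiter.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  src <- attr(catalog, "source")
  cols <- .sg_default_columns[[src]]
  out <- data.frame(catalog$variant_id, catalog$gene, catalog$phenotype,
                    catalog$odds_ratio, catalog$p_value, catalog$study_id,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- cols[c("variant", "gene", "phenotype", "odds_ratio",
                       "p_value", "study_id")]
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "tab")) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE,
                     na = "")
  invisible(path)
}

#' Build the harmonized phenotype list from both catalogs
#'
#' The union of normalized trait labels from the PheWAS- and GWAS-style
#' catalogs, deduplicated under the case-insensitive matching rule and
#' sorted lexicographically.
#'
#' @param phewas,gwas `sg_catalog` tables (either may be empty).
#' @return Character vector of distinct normalized trait labels, sorted.
#' @export
build_phenotype_list <- function(phewas, gwas) {
  traits <- c(if (!is.null(phewas)) norm_trait(phewas$phenotype),
              if (!is.null(gwas)) norm_trait(gwas$phenotype))
  sg_sort(unique(traits))
}

#' Filter association records by significance
#'
#' Keeps records with `p_value <= alpha` (inclusive boundary), preserving
#' the original row order.
#'
#' @param records An `sg_records`/`sg_catalog` table.
#' @param alpha Significance threshold in (0, 1\]; default 0.05.
#' @return The surviving subset, same class and attributes.
#' @export
filter_significant <- function(records, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop("alpha must be a single number in (0, 1]")
  }
  records[records$p_value <= alpha, , drop = FALSE]
}

#' Records of a catalog matching a phenotype
#'
#' Returns every record whose normalized trait label equals the normalized
#' query; an unknown trait yields an empty table.
#'
#' @param catalog An `sg_records`/`sg_catalog` table.
#' @param trait Trait label (matched case-insensitively).
#' @return Subset of `catalog`.
#' @export
records_for_phenotype <- function(catalog, trait) {
  stopifnot(nzchar(trimws(trait)))
  catalog[norm_trait(catalog$phenotype) == norm_trait(trait), , drop = FALSE]
}
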
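#' @keywords internal
"_PACKAGE"

# Log levels in increasing severity; threshold set via option or CLI flag.
.sg_levels <- c(DEBUG = 10L, INFO = 20L, WARN = 30L, ERROR = 40L)

sg_log <- function(level, ...) {
  threshold <- getOption("stargazeR.log_level", "INFO")
  if (.sg_levels[[level]] >= .sg_levels[[threshold]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

#' Normalize a gene symbol
#'
#' Gene symbols are the join key across all evidence sources, so they are
#' whitespace-trimmed and uppercased on ingest; all downstream comparisons
#' are exact matches on the normalized form.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of normalized symbols.
#' @export
#' @examples
#' norm_gene(c(" meis1 ", "Esr1"))
norm_gene <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Normalize a phenotype/trait label
#'
#' Trait labels differ in casing and spacing between PheWAS- and GWAS-style
#' sources. Matching is case-insensitive after trimming and collapsing
#' internal whitespace.
#'
#' @param x Character vector of trait labels.
#' @return Character vector of normalized labels (lower case, single-spaced).
#' @export
#' @examples
#' norm_trait("  Type 2   Diabetes ")
norm_trait <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(as.character(x))))
}

# Locale-independent lexicographic sort (C collation via radix method).
sg_sort <- function(x) sort(x, method = "radix")

# Parse numerics without coercion warnings; returns NA for unparseable input.
sg_as_num <- function(x) {
  suppressWarnings(as.numeric(x))
}
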
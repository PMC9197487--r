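# File-backed evidence providers: gene-disease association scores
# (OpenTargets-style), druggability levels (Pharos/TCRD-style TDL labels)
# and protein-protein interaction edges (STRING-style combined scores).
# Lookups are total: an unknown gene yields the documented no-evidence
# value (score 0, empty level set, isolated node), never an error.

#' Load a gene-disease association score table
#'
#' Accepts a TSV/CSV with columns `gene`, `disease`, `score` or a JSON array
#' of objects with those keys. Scores must lie in \[0, 1\]. Duplicate
#' (gene, disease) rows are averaged, mirroring how odds ratios from
#' multiple studies of the same gene are averaged.
#'
#' @param path Path to the table (`.tsv`/`.csv`/`.json`).
#' @return An `sg_association_provider`; query it with [association_score()].
#' @export
load_association_table <- function(path) {
  if (tolower(tools::file_ext(path)) == "json") {
    df <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    df <- sg_read_table(path)
  }
  need <- c("gene", "disease", "score")
  if (!all(need %in% names(df))) {
    stop("association table needs columns gene, disease, score; got: ",
         paste(names(df), collapse = ", "))
  }
  score <- sg_as_num(df$score)
  bad <- !is.finite(score) | score < 0 | score > 1
  if (any(bad)) {
    stop(sprintf("association score outside [0, 1] at row %d: %s",
                 which(bad)[1L], df$score[which(bad)[1L]]))
  }
  key <- paste(norm_gene(df$gene), norm_trait(df$disease), sep = "\r")
  means <- tapply(score, key, mean)
  structure(list(scores = as.list(means)), class = "sg_association_provider")
}

#' Look up a gene-disease association score
#'
#' @param provider An `sg_association_provider`.
#' @param gene Gene symbol(s).
#' @param disease Trait label (recycled).
#' @return Numeric vector of scores in \[0, 1\]; 0 for unknown pairs.
#' @export
association_score <- function(provider, gene, disease) {
  stopifnot(inherits(provider, "sg_association_provider"))
  key <- paste(norm_gene(gene), norm_trait(disease), sep = "\r")
  vapply(key, function(k) {
    s <- provider$scores[[k]]
    if (is.null(s)) 0 else s
  }, numeric(1), USE.NAMES = FALSE)
}

#' Load a druggability (TDL) table
#'
#' Expects a TSV with columns `gene` and `levels`, the latter a
#' semicolon-separated subset of `Tclin;Tchem;Tbio;Tdark` (empty allowed).
#'
#' @param path Path to the TSV.
#' @return An `sg_druggability_provider`; query with [druggability_levels()].
#' @export
load_druggability_table <- function(path) {
  df <- sg_read_table(path)
  if (!all(c("gene", "levels") %in% names(df))) {
    stop("druggability table needs columns gene, levels; got: ",
         paste(names(df), collapse = ", "))
  }
  lv <- strsplit(as.character(df$levels), ";", fixed = TRUE)
  lv <- lapply(lv, function(x) unique(trimws(x[nzchar(trimws(x))])))
  bad <- setdiff(unique(unlist(lv)), .sg_tdl_levels)
  if (length(bad)) {
    stop("unrecognized druggability label(s): ", paste(bad, collapse = ", "))
  }
  names(lv) <- norm_gene(df$gene)
  structure(list(levels = lv), class = "sg_druggability_provider")
}

#' Look up the druggability levels of a gene
#'
#' @param provider An `sg_druggability_provider`.
#' @param gene A single gene symbol.
#' @return Character vector of TDL labels; empty for unknown genes.
#' @export
druggability_levels <- function(provider, gene) {
  stopifnot(inherits(provider, "sg_druggability_provider"))
  lv <- provider$levels[[norm_gene(gene)]]
  if (is.null(lv)) character(0) else lv
}

#' Read a protein-protein interaction edge list
#'
#' STRING-export dialect: columns `protein1`, `protein2`, `combined_score`
#' with scores on the 0-1000 combined-confidence scale. Malformed rows are
#' skipped with a counted warning; negative confidences are an error.
#'
#' @param path Path to the TSV.
#' @return A data.frame with columns `protein1`, `protein2`,
#'   `combined_score`.
#' @export
read_edge_table <- function(path) {
  df <- sg_read_table(path, allow_empty = TRUE)
  if (!all(c("protein1", "protein2", "combined_score") %in% names(df))) {
    stop("edge list needs columns protein1, protein2, combined_score; got: ",
         paste(names(df), collapse = ", "))
  }
  score <- sg_as_num(df$combined_score)
  if (any(is.finite(score) & score < 0)) {
    stop("negative combined_score at row ",
         which(is.finite(score) & score < 0)[1L])
  }
  malformed <- !is.finite(score) | !nzchar(trimws(df$protein1)) |
    !nzchar(trimws(df$protein2))
  if (any(malformed)) {
    sg_log("WARN", sprintf("dropped %d rows: malformed edge", sum(malformed)))
  }
  data.frame(protein1 = norm_gene(df$protein1)[!malformed],
             protein2 = norm_gene(df$protein2)[!malformed],
             combined_score = score[!malformed],
             stringsAsFactors = FALSE)
}

#' Build an interaction network over a gene set
#'
#' Constructs the undirected protein-protein interaction network whose node
#' set is exactly `gene_set`: genes with no qualifying edge remain isolated
#' nodes. Edges are kept iff both endpoints belong to the gene set, the
#' endpoints differ (no self-loops) and the combined score is at least
#' `min_confidence`; duplicate and reversed pairs collapse to a single edge
#' carrying the maximum confidence.
#'
#' @param edges Path to a STRING-style edge list or a data.frame as
#'   returned by [read_edge_table()].
#' @param gene_set Character vector of gene symbols.
#' @param min_confidence Minimum combined score, default 400 (the STRING
#'   "medium confidence" convention).
#' @return An [igraph::igraph] with vertex names equal to the normalized
#'   gene set and an edge attribute `confidence`.
#' @export
build_network <- function(edges, gene_set, min_confidence = 400) {
  if (is.character(edges) && length(edges) == 1L) {
    edges <- read_edge_table(edges)
  }
  gene_set <- sg_sort(unique(norm_gene(gene_set)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(gene_set), name = gene_set)
  if (nrow(edges)) {
    a <- norm_gene(edges$protein1)
    b <- norm_gene(edges$protein2)
    keep <- a %in% gene_set & b %in% gene_set & a != b &
      edges$combined_score >= min_confidence
    if (any(keep)) {
      lo <- pmin(a[keep], b[keep])
      hi <- pmax(a[keep], b[keep])
      conf <- tapply(edges$combined_score[keep], paste(lo, hi, sep = "\r"),
                     max)
      pairs <- do.call(rbind, strsplit(names(conf), "\r", fixed = TRUE))
      g <- igraph::add_edges(g, as.vector(t(pairs)),
                             confidence = as.numeric(conf))
    }
  }
  g
}

#' Bundle the three evidence providers
#'
#' Convenience container carrying the association-score provider, the
#' druggability provider and the interaction edge table so scoring
#' functions take a single argument.
#'
#' @param association An `sg_association_provider`.
#' @param druggability An `sg_druggability_provider`.
#' @param edges Edge data.frame (see [read_edge_table()]) or path.
#' @return List of class `sg_providers`.
#' @export
provider_bundle <- function(association, druggability, edges) {
  if (is.character(edges) && length(edges) == 1L) {
    edges <- read_edge_table(edges)
  }
  structure(list(association = association, druggability = druggability,
                 edges = edges), class = "sg_providers")
}

#' Load all three providers from a directory or explicit paths
#'
#' @param associations,druggability,edges Paths to the three tables.
#' @return An `sg_providers` bundle.
#' @export
load_providers <- function(associations, druggability, edges) {
  provider_bundle(load_association_table(associations),
                  load_druggability_table(druggability),
                  read_edge_table(edges))
}
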
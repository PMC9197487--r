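# Deterministic synthetic-data generator. Produces all five input files a
# run needs (PheWAS CSV, GWAS TSV, association scores, druggability table,
# interaction edge list) plus a ground-truth table of feature vectors and
# StarGazer scores computed by straight-line arithmetic that shares no code
# with the scoring pipeline, so tests can compare the two as true oracle
# against implementation.

#' Specify a synthetic fixture
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_phenotypes Number of phenotypes (>= 1).
#' @param variants_per_gene Variants simulated per gene (>= 1).
#' @param risk_fraction Fraction of variants drawn as risk alleles
#'   (OR in (1, 5\]); the rest are protective (OR in \[0.2, 1)).
#' @param overlap_fraction Fraction of variants reported by both the
#'   PheWAS- and GWAS-style sources (with identical OR and p, so the
#'   significance filter keeps or drops them together).
#' @param edge_density Probability that any unordered gene pair gets an
#'   interaction edge.
#' @param seed RNG seed; identical specs produce byte-identical files.
#' @return List of class `sg_fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 20, n_phenotypes = 3,
                         variants_per_gene = 4, risk_fraction = 0.6,
                         overlap_fraction = 0.3, edge_density = 0.2,
                         seed = 1) {
  spec <- list(n_genes = as.integer(n_genes),
               n_phenotypes = as.integer(n_phenotypes),
               variants_per_gene = as.integer(variants_per_gene),
               risk_fraction = risk_fraction,
               overlap_fraction = overlap_fraction,
               edge_density = edge_density,
               seed = as.integer(seed))
  with(spec, {
    if (n_genes < 1L || n_phenotypes < 1L || variants_per_gene < 1L) {
      stop("n_genes, n_phenotypes and variants_per_gene must be >= 1")
    }
    for (f in c(risk_fraction, overlap_fraction, edge_density)) {
      if (!is.finite(f) || f < 0 || f > 1) {
        stop("fractions must lie in [0, 1]")
      }
    }
  })
  structure(spec, class = "sg_fixture_spec")
}

#' Generate a synthetic evidence fixture with ground truth
#'
#' Writes `phewas.csv`, `gwas.tsv`, `associations.tsv`, `druggability.tsv`
#' and `edges.tsv` under `out_dir`, together with `ground_truth.csv`
#' (feature vectors and StarGazer scores per phenotype and allele-class
#' context, at alpha = 0.05 and interaction confidence >= 400) and a JSON
#' `manifest.json`. Odds ratios are drawn log-normally within (1, 5\] for
#' risk alleles and uniformly within \[0.2, 1) for protective alleles;
#' p-values are mixed so a known subset survives alpha = 0.05 and every
#' phenotype keeps at least one significant record.
#'
#' @param spec An `sg_fixture_spec`.
#' @param out_dir Output directory (created if absent).
#' @return The manifest list, invisibly (element `files` holds the paths).
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "sg_fixture_spec"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)

  genes <- sprintf("GENE%03d", seq_len(spec$n_genes))
  phen_label <- sprintf("Phenotype %02d", seq_len(spec$n_phenotypes))
  phen_norm <- norm_trait(phen_label)

  nv <- spec$n_genes * spec$variants_per_gene
  v_gene <- rep(genes, each = spec$variants_per_gene)
  v_id <- sprintf("rs%d", 100000L + seq_len(nv))
  v_phen <- ((seq_len(nv) - 1L) %% spec$n_phenotypes) + 1L
  is_risk <- stats::runif(nv) < spec$risk_fraction
  v_or <- ifelse(is_risk,
                 round(1 + pmin(stats::rlnorm(nv, 0, 0.5), 4), 4),
                 round(stats::runif(nv, 0.2, 0.999), 4))
  first_seen <- !duplicated(v_phen)
  v_p <- ifelse(first_seen | stats::runif(nv) < 0.7,
                round(stats::runif(nv, 0.001, 0.049), 5),
                round(stats::runif(nv, 0.051, 0.9), 5))
  primary_phewas <- seq_len(nv) %% 2L == 1L
  in_both <- stats::runif(nv) < spec$overlap_fraction
  in_phewas <- primary_phewas | in_both
  in_gwas <- !primary_phewas | in_both

  f_phewas <- file.path(out_dir, "phewas.csv")
  phw <- data.frame(snp = v_id[in_phewas], gene_name = v_gene[in_phewas],
                    `phewas phenotype` = phen_label[v_phen[in_phewas]],
                    `odds-ratio` = v_or[in_phewas], p = v_p[in_phewas],
                    study = "phewas-2013",
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(phw, f_phewas, row.names = FALSE, quote = TRUE)

  f_gwas <- file.path(out_dir, "gwas.tsv")
  gws <- data.frame(SNPS = v_id[in_gwas], MAPPED_GENE = v_gene[in_gwas],
                    `DISEASE/TRAIT` = toupper(phen_label[v_phen[in_gwas]]),
                    `OR or BETA` = v_or[in_gwas], `P-VALUE` = v_p[in_gwas],
                    `STUDY ACCESSION` = sprintf("GCST%06d",
                                                which(in_gwas)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(gws, f_gwas, sep = "\t", row.names = FALSE,
                     quote = TRUE)

  f_assoc <- file.path(out_dir, "associations.tsv")
  ag <- expand.grid(gene = genes, disease = phen_label,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ag$score <- ifelse(stats::runif(nrow(ag)) < 0.3, 0,
                     round(stats::runif(nrow(ag)), 4))
  utils::write.table(ag, f_assoc, sep = "\t", row.names = FALSE,
                     quote = TRUE)

  f_drug <- file.path(out_dir, "druggability.tsv")
  lv_prob <- c(Tclin = 0.2, Tchem = 0.3, Tbio = 0.6, Tdark = 0.15)
  drug_levels <- lapply(genes, function(g) {
    names(lv_prob)[stats::runif(4) < lv_prob]
  })
  utils::write.table(
    data.frame(gene = genes,
               levels = vapply(drug_levels, paste, character(1),
                               collapse = ";"),
               stringsAsFactors = FALSE),
    f_drug, sep = "\t", row.names = FALSE, quote = TRUE)

  f_edges <- file.path(out_dir, "edges.tsv")
  pairs <- if (spec$n_genes > 1) t(utils::combn(genes, 2)) else
    matrix(character(0), ncol = 2)
  keep <- stats::runif(nrow(pairs)) < spec$edge_density
  edges <- data.frame(protein1 = pairs[keep, 1],
                      protein2 = pairs[keep, 2],
                      combined_score = if (any(keep))
                        sample(150:999, sum(keep), replace = TRUE)
                      else integer(0),
                      stringsAsFactors = FALSE)
  utils::write.table(edges, f_edges, sep = "\t", row.names = FALSE,
                     quote = TRUE)

  truth <- .fixture_ground_truth(
    v_id = v_id, v_gene = v_gene, v_phen = phen_norm[v_phen], v_or = v_or,
    v_p = v_p, in_phewas = in_phewas, in_gwas = in_gwas,
    assoc = data.frame(gene = ag$gene, disease = norm_trait(ag$disease),
                       score = ag$score, stringsAsFactors = FALSE),
    drug_levels = stats::setNames(drug_levels, genes), edges = edges,
    phenotypes = phen_norm)
  f_truth <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(truth, f_truth, row.names = FALSE, quote = FALSE)

  manifest <- list(
    spec = unclass(spec),
    alpha = 0.05,
    min_confidence = 400,
    n_significant = sum(v_p <= 0.05),
    files = list(phewas = f_phewas, gwas = f_gwas, associations = f_assoc,
                 druggability = f_drug, edges = f_edges,
                 ground_truth = f_truth)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Straight-line recomputation of every feature and score from the raw
# simulated vectors. Deliberately plain loops and base arithmetic only:
# this must stay independent of the scoring pipeline it is used to check.
.fixture_ground_truth <- function(v_id, v_gene, v_phen, v_or, v_p,
                                  in_phewas, in_gwas, assoc, drug_levels,
                                  edges, phenotypes) {
  # expand to one row per (variant, source)
  src <- c(rep("PHEWAS", sum(in_phewas)), rep("GWAS", sum(in_gwas)))
  rid <- c(v_id[in_phewas], v_id[in_gwas])
  rgene <- c(v_gene[in_phewas], v_gene[in_gwas])
  rphen <- c(v_phen[in_phewas], v_phen[in_gwas])
  ror <- c(v_or[in_phewas], v_or[in_gwas])
  rp <- c(v_p[in_phewas], v_p[in_gwas])

  # deduplicated qualifying edges (confidence >= 400)
  elo <- pmin(edges$protein1, edges$protein2)
  ehi <- pmax(edges$protein1, edges$protein2)
  eok <- edges$combined_score >= 400 & elo != ehi
  ekey <- unique(paste(elo[eok], ehi[eok]))

  rows <- list()
  for (phen in phenotypes) {
    for (ctx in c("ALL", "RISK", "PROTECTIVE")) {
      sel <- rphen == phen & rp <= 0.05
      if (ctx == "RISK") sel <- sel & ror >= 1
      if (ctx == "PROTECTIVE") sel <- sel & ror < 1
      if (!any(sel)) next
      gs <- sort(unique(rgene[sel]), method = "radix")

      or_mean <- numeric(length(gs))
      ot_raw <- numeric(length(gs))
      inter <- numeric(length(gs))
      dcount <- numeric(length(gs))
      degree <- numeric(length(gs))
      phw_genes <- unique(rgene[sel & src == "PHEWAS"])
      gws_genes <- unique(rgene[sel & src == "GWAS"])
      for (i in seq_along(gs)) {
        g <- gs[i]
        ors <- ror[sel & rgene == g]
        mags <- numeric(length(ors))
        for (j in seq_along(ors)) {
          mags[j] <- if (ors[j] >= 1) ors[j] else 1 - ors[j]
        }
        or_mean[i] <- sum(mags) / length(mags)
        hit <- assoc$score[assoc$gene == g & assoc$disease == phen]
        ot_raw[i] <- if (length(hit)) sum(hit) / length(hit) else 0
        inter[i] <- as.numeric(g %in% phw_genes && g %in% gws_genes)
        lv <- drug_levels[[g]]
        dcount[i] <- length(unique(lv[lv != "Tdark"]))
        nb <- character(0)
        for (k in seq_along(ekey)) {
          ends <- strsplit(ekey[k], " ", fixed = TRUE)[[1]]
          if (ends[1] == g && ends[2] %in% gs) nb <- c(nb, ends[2])
          if (ends[2] == g && ends[1] %in% gs) nb <- c(nb, ends[1])
        }
        degree[i] <- length(unique(nb))
      }
      nz <- function(x) if (max(x) > 0) x / max(x) else x * 0
      f1 <- nz(or_mean); f2 <- nz(ot_raw); f4 <- nz(dcount); f5 <- nz(degree)
      rows[[length(rows) + 1L]] <- data.frame(
        phenotype = phen, context = ctx, gene = gs,
        or_score = f1, opentargets_score = f2,
        intersection_indicator = inter, druggability_score = f4,
        network_degree_score = f5,
        stargazer_score = (f1 + f2 + inter + f4 + f5) / 5,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
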
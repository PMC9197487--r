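# Expected values in this file are hand arithmetic: per-gene means of
# odds-ratio magnitudes, division by the set maximum, neighbour counts.

test_that("odds-ratio magnitude is OR for risk and 1 - OR for protective", {
  expect_equal(or_magnitude(2.5, "RISK"), 2.5)
  expect_equal(or_magnitude(1.0, "RISK"), 1.0)
  expect_equal(or_magnitude(0.9, "PROTECTIVE"), 0.1)
  # records incompatible with a restricted context are excluded, not errors
  expect_true(is.na(or_magnitude(0.9, "RISK")))
  expect_true(is.na(or_magnitude(1.5, "PROTECTIVE")))
  expect_equal(or_magnitude(c(2.5, 0.9), "ALL"), c(2.5, 0.1))
})

test_that("gene OR scores average studies then normalize by the set max", {
  rec <- association_records(
    paste0("rs", 1:3), c("A", "A", "B"), "t",
    odds_ratio = c(2.0, 3.0, 1.25), p_value = 0.01, source = "PHEWAS")
  sc <- gene_or_score(rec, "RISK")
  expect_equal(sc[["A"]], 1.0)     # mean(2, 3) = 2.5 is the max
  expect_equal(sc[["B"]], 0.5)     # 1.25 / 2.5
  one <- association_records("rs1", "A", "t", 1.7, 0.01, "PHEWAS")
  expect_equal(gene_or_score(one, "RISK")[["A"]], 1.0)
  prot <- association_records("rs1", "A", "t", 0.5, 0.01, "PHEWAS")
  expect_equal(gene_or_score(prot, "RISK", genes = "A")[["A"]], 0)
})

test_that("adding a study at the current mean leaves the score unchanged", {
  set.seed(21)
  for (i in 1:10) {
    ors <- stats::runif(3, 1, 4)
    rec <- association_records(paste0("rs", 1:4), c("A", "A", "A", "B"), "t",
                               odds_ratio = c(ors, 1.1), p_value = 0.01,
                               source = "PHEWAS")
    aug <- association_records(paste0("rs", 1:5),
                               c("A", "A", "A", "B", "A"), "t",
                               odds_ratio = c(ors, 1.1, mean(ors)),
                               p_value = 0.01, source = "PHEWAS")
    expect_equal(gene_or_score(aug, "RISK"), gene_or_score(rec, "RISK"))
  }
})

test_that("association feature divides by the max and is scale invariant", {
  raw <- c(MEIS1 = 0.62, DRD2 = 0.093, ESR1 = 0.0056)
  sc <- opentargets_feature(raw)
  expect_equal(round(sc, 3),
               c(MEIS1 = 1.000, DRD2 = 0.150, ESR1 = 0.009))
  expect_equal(opentargets_feature(raw * 0.5), sc)
  expect_equal(opentargets_feature(c(A = 0, B = 0)), c(A = 0, B = 0))
  expect_equal(opentargets_feature(c(A = 0.3))[["A"]], 1.0)
  expect_error(opentargets_feature(c(A = 1.4)), "\\[0, 1\\]")
})

test_that("the intersection indicator requires membership in both sources", {
  sc <- intersection_feature(c("A", "B", "C"),
                             phewas_genes = c("A", "B"),
                             gwas_genes = c("a", "C"))
  expect_equal(unname(sc), c(1, 0, 0))
  expect_equal(unname(intersection_feature("A", character(0),
                                           character(0))), 0)
})

test_that("druggability counts distinct levels and never counts Tdark", {
  expect_equal(druggability_count(c("Tbio", "Tclin", "Tdark")), 2)
  expect_equal(druggability_count("Tdark"), 0)
  expect_equal(druggability_count(c("Tclin", "Tchem", "Tbio")), 3)
  expect_equal(druggability_count(character(0)), 0)
  expect_error(druggability_count("Tnew"), "Tnew")
  # removing Tdark from any profile leaves the count unchanged
  lvls <- c("Tclin", "Tchem", "Tbio", "Tdark")
  for (i in 0:15) {
    set <- lvls[bitwAnd(i, c(1L, 2L, 4L, 8L)) > 0]
    expect_equal(druggability_count(set),
                 druggability_count(setdiff(set, "Tdark")))
  }
})

test_that("druggability feature normalizes counts by the set maximum", {
  expect_equal(druggability_feature(c(A = 1, B = 2)), c(A = 0.5, B = 1.0))
  expect_equal(druggability_feature(c(A = 0, B = 0)), c(A = 0, B = 0))
  expect_equal(druggability_feature(c(A = 3))[["A"]], 1.0)
})

test_that("degree feature is the ratio to the highest node degree", {
  path <- build_network(data.frame(protein1 = c("A", "B"),
                                   protein2 = c("B", "C"),
                                   combined_score = c(900, 900)),
                        c("A", "B", "C"))
  expect_equal(network_degree_feature(path),
               c(A = 0.5, B = 1.0, C = 0.5))
  tri <- build_network(data.frame(protein1 = c("A", "B", "C"),
                                  protein2 = c("B", "C", "A"),
                                  combined_score = 900),
                       c("A", "B", "C"))
  expect_equal(unname(network_degree_feature(tri)), c(1, 1, 1))
  lone <- build_network(data.frame(protein1 = character(0),
                                   protein2 = character(0),
                                   combined_score = numeric(0)), "A")
  expect_equal(network_degree_feature(lone), c(A = 0))
})

test_that("degree scores are integer multiples of 1/maxdegree", {
  set.seed(5)
  for (i in 1:8) {
    n <- sample(4:12, 1)
    genes <- paste0("G", seq_len(n))
    pairs <- t(utils::combn(genes, 2))
    keep <- stats::runif(nrow(pairs)) < 0.4
    g <- build_network(data.frame(protein1 = pairs[keep, 1],
                                  protein2 = pairs[keep, 2],
                                  combined_score = 900), genes)
    sc <- network_degree_feature(g)
    maxdeg <- max(igraph::degree(g))
    if (maxdeg > 0) {
      expect_equal(sc * maxdeg, round(sc * maxdeg))
    } else {
      expect_true(all(sc == 0))
    }
  }
})

test_that("the assembled feature vectors match hand computation end to end", {
  fx <- hand_fixture()
  fv <- compute_feature_vectors("insomnia", fx$phewas, fx$gwas,
                                fx$providers, context = "ALL")
  expect_identical(fv$gene, c("GENEA", "GENEB", "GENEC"))
  # means 2.5 / 1.25 / 0.5 -> /2.5; OT 0.8/0.2/0 -> /0.8; B in both sources;
  # level counts 2/1/0; degrees 1/2/1 at min confidence 400
  expect_equal(fv$or_score, c(1, 0.5, 0.2))
  expect_equal(fv$opentargets_score, c(1, 0.25, 0))
  expect_equal(fv$intersection_indicator, c(0, 1, 0))
  expect_equal(fv$druggability_score, c(1, 0.5, 0))
  expect_equal(fv$network_degree_score, c(0.5, 1, 0.5))

  risk <- compute_feature_vectors("Insomnia", fx$phewas, fx$gwas,
                                  fx$providers, context = "RISK")
  expect_identical(risk$gene, c("GENEA", "GENEB"))
  expect_equal(risk$network_degree_score, c(1, 1))
  prot <- compute_feature_vectors("insomnia", fx$phewas, fx$gwas,
                                  fx$providers, context = "PROTECTIVE")
  expect_identical(prot$gene, "GENEC")
  expect_equal(unlist(prot[1, -1], use.names = FALSE), c(1, 0, 0, 0, 0))
})

test_that("a context with no compatible records yields an empty map", {
  phewas <- mk_phewas("rs1", "A", "t", 0.5, 0.01)
  gwas <- mk_gwas("rs2", "B", "t", 0.7, 0.01)
  fv <- compute_feature_vectors("t", phewas, gwas, mk_providers(),
                                context = "RISK")
  expect_equal(nrow(fv), 0)
})

test_that("genes absent from every provider get no-evidence defaults", {
  phewas <- mk_phewas(c("rs1", "rs2"), c("A", "B"), "t", c(2, 1.5),
                      c(0.01, 0.01))
  gwas <- mk_gwas("rs3", "C", "other", 1.2, 0.01)
  fv <- compute_feature_vectors("t", phewas, gwas, mk_providers())
  b <- fv[fv$gene == "B", ]
  expect_equal(unlist(b[-1], use.names = FALSE), c(0.75, 0, 0, 0, 0))
})

test_that("every non-zero feature attains 1 somewhere (tightness) and all
           outputs stay inside [0,1] on generated fixtures", {
  for (seed in c(101, 202)) {
    dir <- tempfile("fx")
    m <- generate_fixture(fixture_spec(n_genes = 10, n_phenotypes = 2,
                                       seed = seed), dir)
    phewas <- read_catalog(m$files$phewas, "PHEWAS")
    gwas <- read_catalog(m$files$gwas, "GWAS")
    prov <- load_providers(m$files$associations, m$files$druggability,
                           m$files$edges)
    for (ctx in c("ALL", "RISK", "PROTECTIVE")) {
      fv <- compute_feature_vectors("phenotype 01", phewas, gwas, prov,
                                    context = ctx)
      if (!nrow(fv)) next
      vals <- as.matrix(fv[, -1])
      expect_true(all(vals >= 0 & vals <= 1))
      for (col in c("or_score", "opentargets_score", "druggability_score",
                    "network_degree_score")) {
        expect_true(max(fv[[col]]) %in% c(0, 1),
                    label = sprintf("feature %s (seed %d, %s) attains 1",
                                    col, seed, ctx))
      }
    }
    unlink(dir, recursive = TRUE)
  }
})
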
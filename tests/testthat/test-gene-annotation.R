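# independent trigram-Dice oracle used to check fuzzyScore
diceOracle <- function(a, b) {
  norm <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  tri <- function(x) {
    if (nchar(x) < 3) return(character(0))
    unique(vapply(1:(nchar(x) - 2), function(i) substr(x, i, i + 2), ""))
  }
  na <- norm(a); nb <- norm(b)
  if (!nzchar(na) || !nzchar(nb)) return(0)
  if (na == nb) return(1)
  ta <- tri(na); tb <- tri(nb)
  if (!length(ta) || !length(tb)) return(0)
  2 * sum(ta %in% tb) / (length(ta) + length(tb))
}

test_that("fuzzy score has the expected identities and matches the oracle", {
  expect_equal(fuzzyScore("Phenylalanine", "phenyl-alanine"), 1)
  expect_equal(fuzzyScore("abc", "xyz"), 0)
  s <- fuzzyScore("phenylalanine", "phenylalanine hydroxylase")
  expect_equal(s, diceOracle("phenylalanine", "phenylalanine hydroxylase"))
  expect_gt(s, 0.5)
  # symmetry and range over random string pairs
  set.seed(50)
  for (i in 1:20) {
    a <- paste(sample(letters, sample(3:12, 1), TRUE), collapse = "")
    b <- paste(sample(letters, sample(3:12, 1), TRUE), collapse = "")
    s1 <- fuzzyScore(a, b)
    expect_equal(s1, fuzzyScore(b, a))
    expect_gte(s1, 0); expect_lte(s1, 1)
    expect_equal(s1, diceOracle(a, b))
  }
  expect_equal(fuzzyScore("", "abc"), 0)
  expect_equal(fuzzyScore("!!", "abc"), 0)
})

test_that("nearest-gene ranking handles containment, caps at 20 and matches a sort oracle", {
  genes <- data.frame(
    gene_id = c("A", "B", "C"), chrom = "1",
    start = c(900, 5000, 20000), end = c(1500, 6000, 21000),
    protein_coding = TRUE)
  r <- rankNearestGenes("1", 1000, genes)
  expect_identical(r$gene_id[1], "A")
  expect_equal(r$distance[1], 0)

  set.seed(51)
  big <- data.frame(gene_id = sprintf("g%02d", 1:25), chrom = "1",
                    start = sort(sample.int(1e6, 25)),
                    protein_coding = TRUE)
  big$end <- big$start + 500
  r2 <- rankNearestGenes("1", 5e5, big)
  expect_equal(nrow(r2), 20L)
  # oracle: exhaustive distance sort
  d <- ifelse(5e5 >= big$start & 5e5 <= big$end, 0,
              pmin(abs(5e5 - big$start), abs(5e5 - big$end)))
  oracle <- big$gene_id[order(d, big$gene_id)][1:20]
  expect_identical(r2$gene_id, oracle)
  # non-protein-coding genes are never returned
  big$protein_coding[1:10] <- FALSE
  expect_equal(nrow(rankNearestGenes("1", 5e5, big)), 15L)
})

test_that("disease-name matching strips stop words before fuzzy comparison", {
  res <- list(
    metabolite_synonyms = data.frame(metabolite_id = "met_M",
                                     synonym = "methionine"),
    gene_diseases = data.frame(gene_id = "MAT1A",
                               disease_name = "hypermethioninemia"))
  cg <- data.frame(gene_id = "MAT1A", distance_rank = 1L)
  ev <- suppressWarnings(annotateGim("met_M", cg, res))
  hit <- ev[ev$source == "disease_name", ]
  expect_equal(nrow(hit), 1L)
  expect_gt(hit$score, 0.5)
  # without stop-word removal the raw strings would not clear the cutoff
  expect_lt(fuzzyScore("methionine", "hypermethioninemia"),
            hit$score)
})

test_that("GO terms with 500 or more member genes are excluded", {
  res <- list(
    metabolite_synonyms = data.frame(metabolite_id = "m", synonym = "proline"),
    go_bp = data.frame(gene_id = "G",
                       term = c("proline metabolic process",
                                "proline catabolic process"),
                       n_genes = c(600, 40)))
  cg <- data.frame(gene_id = "G", distance_rank = 1L)
  ev <- suppressWarnings(annotateGim("m", cg, res))
  go <- ev[ev$source == "go_bp", ]
  expect_equal(nrow(go), 1L)
  expect_identical(go$matched_b, "proline catabolic process")
})

test_that("pathway co-occurrence and interacting-metabolite channels hit without fuzziness", {
  res <- list(
    gene_pathways = data.frame(gene_id = "G", map_id = "map00330"),
    metabolite_pathways = data.frame(metabolite_id = "m", map_id = "map00330"),
    interacting_metabolites = data.frame(gene_id = "G", metabolite_id = "m"))
  cg <- data.frame(gene_id = "G", distance_rank = 3L)
  ev <- suppressWarnings(annotateGim("m", cg, res))
  expect_setequal(ev$source, c("pathway_map", "interacting_protein"))
  # a gene with no hits on any channel yields an empty table
  ev2 <- suppressWarnings(annotateGim(
    "other", data.frame(gene_id = "H", distance_rank = 1L), res))
  expect_equal(nrow(ev2), 0L)
  expect_identical(attr(ev2, "flagged_causal"), "none")
})

test_that("a missing resource table skips its channel with a warning", {
  res <- list(metabolite_synonyms = data.frame(metabolite_id = "m",
                                               synonym = "urate"))
  expect_warning(
    annotateGim("m", data.frame(gene_id = "G", distance_rank = 1L), res),
    "missing")
})

test_that("IEM enrichment reproduces the background rate and a pmf-sum oracle", {
  # background: 785 / 19817 rounds to 4%
  e0 <- iemEnrichment("g1", "g1")
  expect_equal(round(100 * e0$p0), 4)
  expect_equal(e0$p0, 785 / 19817)

  # fold = 1 when the tested proportion equals the background
  tested <- paste0("t", 1:19817)
  iem <- paste0("t", 1:785)
  e1 <- iemEnrichment(tested, iem)
  expect_equal(e1$fold, 1)

  # 10 of 20 tested IEM genes at p0 = 785/19817: fold and two-tailed P
  tested2 <- paste0("g", 1:20)
  iem2 <- c(paste0("g", 1:10), "other")
  e2 <- iemEnrichment(tested2, iem2)
  expect_equal(e2$fold, (10 / 20) / (785 / 19817))
  # minimum-likelihood two-tailed oracle by exhaustive pmf summation
  pm <- dbinom(0:20, 20, 785 / 19817)
  oracleP <- sum(pm[pm <= pm[11] * (1 + 1e-7)])
  expect_equal(e2$pval, oracleP, tolerance = 1e-9)
  expect_error(iemEnrichment(character(0), iem2), "non-empty")
})
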
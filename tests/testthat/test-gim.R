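fakeGimMatrix <- function(om, order = seq_len(nrow(om)), threshold = 5e-8) {
  structure(list(out_matrix = om,
                 marker_order = setNames(order, rownames(om)),
                 threshold = threshold), class = "GimMatrix")
}

test_that("a single strong variant-metabolite pair yields one single-pair GIM", {
  vs <- variantSpec("1", 1e6, maf = 0.3)
  g <- simulateGenotypes(vs, 4000, seed = 30)
  beta <- sqrt(0.05 / (2 * 0.3 * 0.7))
  tt <- TruthTable(causalEntries = data.frame(
    variant_id = vs$id, metabolite_id = "m1", beta = beta,
    var_explained = 0.05))
  met <- simulateMetabolites(g, tt, seed = 31)
  Y <- matrix(as.vector(scale(log(met[, 1]))), ncol = 1,
              dimnames = list(NULL, "m1"))
  gm <- gimSelect(Y, g, cohort = rep(c("a", "b"), 2000))
  expect_identical(names(gm$marker_order), vs$id)
  expect_equal(unname(gm$marker_order), 1L)
  gims <- clusterGims(gm)
  expect_length(gims, 1L)
  expect_identical(gims[[1]]$metabolites, "m1")
})

test_that("selection stops at the -log10(5e-8) threshold", {
  # association at conditional P ~ 1e-5: never selected at the default stop
  vs <- variantSpec("1", 1e6, maf = 0.3)
  g <- simulateGenotypes(vs, 2000, seed = 32)
  set.seed(33)
  y <- 0.06 * g[, 1] + rnorm(2000)
  p <- summary(lm(y ~ g[, 1]))$coefficients[2, 4]
  expect_gt(p, 5e-8)  # fixture sanity: marginal P is sub-threshold
  expect_lt(p, 0.05)  # ... but clearly non-null
  Y <- matrix(as.vector(scale(y)), ncol = 1, dimnames = list(NULL, "m1"))
  gm <- gimSelect(Y, g)
  expect_equal(length(gm$marker_order), 0L)
  expect_length(clusterGims(gm), 0L)
})

test_that("bipartite clustering reproduces the four-GIM example structure", {
  # {v1,v2} -> {m1,m2}; {v3..v6} -> {m3,m4,m5}; {v7} -> {m6}; {v8} -> {m7}
  om <- matrix(0, 8, 7, dimnames = list(paste0("v", 1:8), paste0("m", 1:7)))
  om[1:2, 1:2] <- 20
  om[3:6, 3:5] <- -15
  om[7, 6] <- 30
  om[8, 7] <- 12
  gims <- clusterGims(fakeGimMatrix(om), regionId = "region512")
  expect_length(gims, 4L)
  sizes <- t(vapply(gims, function(g)
    c(nrow(g$variants), length(g$metabolites)), numeric(2)))
  expect_setequal(paste(sizes[, 1], sizes[, 2]),
                  c("2 2", "4 3", "1 1", "1 1"))
  # partition property: no variant or metabolite in two GIMs
  vsets <- lapply(gims, function(g) g$variants$variant_id)
  msets <- lapply(gims, function(g) g$metabolites)
  expect_equal(length(unlist(vsets)), length(unique(unlist(vsets))))
  expect_equal(length(unlist(msets)), length(unique(unlist(msets))))
})

test_that("an entry at exactly the threshold does not form an edge", {
  om <- matrix(-log10(5e-8), 1, 1, dimnames = list("v1", "m1"))
  expect_length(clusterGims(fakeGimMatrix(om)), 0L)  # strict inequality
  om[1, 1] <- -log10(6e-8)
  expect_length(clusterGims(fakeGimMatrix(om)), 0L)  # 6e-8 is weaker still
  om[1, 1] <- -log10(4e-8)
  expect_length(clusterGims(fakeGimMatrix(om)), 1L)
})

test_that("connected components match a union-find oracle on random bipartite graphs", {
  set.seed(34)
  for (rep in 1:25) {
    nv <- sample(2:6, 1); nm <- sample(2:6, 1)
    om <- matrix(0, nv, nm, dimnames = list(paste0("v", 1:nv),
                                            paste0("m", 1:nm)))
    edges <- which(matrix(runif(nv * nm) < 0.3, nv, nm), arr.ind = TRUE)
    if (!nrow(edges)) next
    om[edges] <- sample(c(-1, 1), nrow(edges), TRUE) * runif(nrow(edges), 8, 40)
    gims <- clusterGims(fakeGimMatrix(om))
    # union-find oracle over nodes v1..vnv, m1..mnm
    nodes <- c(rownames(om), paste0("M", colnames(om)))
    parent <- setNames(nodes, nodes)
    findr <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    for (e in seq_len(nrow(edges)))
      parent[[findr(rownames(om)[edges[e, 1]])]] <-
        findr(paste0("M", colnames(om)[edges[e, 2]]))
    roots <- vapply(nodes, findr, character(1))
    touched <- unique(c(rownames(om)[edges[, 1]],
                        paste0("M", colnames(om)[edges[, 2]])))
    nComp <- length(unique(roots[touched]))
    expect_length(gims, nComp)
    # same variant grouping
    oracleGroups <- split(intersect(touched, rownames(om)),
                          roots[intersect(touched, rownames(om))])
    gimGroups <- lapply(gims, function(g) g$variants$variant_id)
    expect_setequal(lapply(oracleGroups, function(x) paste(sort(x), collapse = ",")),
                    lapply(gimGroups, function(x) paste(sort(x), collapse = ",")))
  }
})

test_that("two independent planted signals with disjoint metabolites separate cleanly", {
  vs <- variantSpec("1", c(1e6, 6e6), maf = 0.3)
  g <- simulateGenotypes(vs, 6000, seed = 35)
  beta <- sqrt(0.04 / (2 * 0.3 * 0.7))
  tt <- TruthTable(causalEntries = data.frame(
    variant_id = rep(vs$id, each = 1), metabolite_id = c("m1", "m2"),
    beta = beta, var_explained = 0.04))
  met <- simulateMetabolites(g, tt, seed = 36)
  Y <- apply(log(met), 2, scale)
  gm <- gimSelect(Y, g, cohort = rep(c("a", "b"), 3000))
  expect_equal(length(gm$marker_order), 2L)
  # cross entries (variant of one GIM vs the other's metabolite) stay weak
  for (i in 1:2) {
    other <- setdiff(1:2, i)
    expect_lt(abs(gm$out_matrix[vs$id[i], colnames(Y)[other]]), -log10(5e-8))
  }
  gims <- clusterGims(gm)
  expect_length(gims, 2L)
})

test_that("adjacent regions sharing a metabolite are merged and recomputed", {
  library(GenomicRanges)
  reg <- GRanges("1", IRanges(c(1e6, 2.2e6), c(2e6, 3e6)))
  mcols(reg)$region_id <- c("rA", "rB")
  mcols(reg)$sentinels <- c("s1", "s2")
  gims <- list(
    rA = list(list(id = "rA_GIM1", metabolites = c("m1", "m2"))),
    rB = list(list(id = "rB_GIM1", metabolites = c("m2", "m3"))))
  calls <- 0L
  recompute <- function(chrom, lo, hi, rid) {
    calls <<- calls + 1L
    list(list(id = paste0(rid, "_GIM1"), metabolites = c("m1", "m2", "m3")))
  }
  out <- mergeAdjacentRegions(reg, gims, recompute)
  expect_equal(length(out$regions), 1L)
  expect_equal(calls, 1L)
  expect_identical(mcols(out$regions)$region_id, "rA+rB")

  # disjoint metabolite sets: a no-op
  gims2 <- list(rA = list(list(id = "a", metabolites = "m1")),
                rB = list(list(id = "b", metabolites = "m9")))
  out2 <- mergeAdjacentRegions(reg, gims2, recompute)
  expect_equal(length(out2$regions), 2L)
  expect_identical(out2$gims, gims2)
})

test_that("a planted locus split across a region boundary reunites after merging", {
  st <- smallStudy(seed = 40, nRegions = 1)
  res <- runDiscoveryPipeline(st$cohorts[1:2], minN = 100,
                              condThreshold = 1e-5, gimThreshold = 1e-5,
                              pMeta = 1e-5, mergeAdjacent = TRUE)
  # the single planted locus ends up in one region with its GIMs intact
  expect_equal(length(res$regions), 1L)
  rec <- recoveredPartition(res$gims)
  expect_gte(ari(rec, plantedPartition(st$truth)), 0.99)
})

test_that("display matrix caps magnitudes at 50 and transposes layout", {
  om <- matrix(c(120, -80, 3, -3), 2, 2,
               dimnames = list(c("v1", "v2"), c("m1", "m2")))
  d <- gimDisplayMatrix(fakeGimMatrix(om))
  expect_equal(dim(d), c(2L, 2L))
  expect_equal(d["m1", "v1"], 50)
  expect_equal(d["m1", "v2"], -50)
  expect_equal(d["m2", "v1"], 3)
})
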
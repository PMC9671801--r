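test_that("the conditional threshold reproduces the Bonferroni arithmetic", {
  expect_equal(conditionalThreshold(), 1.25e-8)
  expect_equal(conditionalThreshold(0.05, 39297, 102),
               signif(0.05 / (39297 * 102), 3))
})

test_that("stepwise selection matches an exhaustive forward-search oracle", {
  set.seed(10)
  for (rep in 1:6) {
    n <- 900
    p <- sample(3:6, 1)
    g <- matrix(rbinom(n * p, 2, runif(p, 0.1, 0.4)), n, p, byrow = TRUE,
                dimnames = list(NULL, paste0("v", 1:p)))
    causal <- sample(p, 2)
    y <- 0.35 * g[, causal[1]] - 0.3 * g[, causal[2]] + rnorm(n)
    y <- as.vector(scale(y))
    cohort <- rep(c("a", "b"), length.out = n)
    thr <- 1e-4
    model <- stepwiseConditional(y, g, cohort = cohort, threshold = thr)
    oracle <- stepwiseOracle(y, g, cohort = cohort, threshold = thr)
    expect_identical(model$selected$variant_id, oracle)
  }
})

test_that("a planted causal variant among LD proxies is recovered alone", {
  hits <- 0L
  for (rep in 1:5) {
    vs <- variantSpec("1", sort(1e6 + sample.int(3000, 20)), maf = 0.3)
    g <- simulateGenotypes(vs, 8000, ldDecay = 2e-4, seed = 100 + rep)
    causal <- vs$id[10]
    beta <- sqrt(0.02 / (2 * 0.3 * 0.7))
    tt <- TruthTable(causalEntries = data.frame(
      variant_id = causal, metabolite_id = "m1", beta = beta,
      var_explained = 0.02))
    met <- simulateMetabolites(g, tt, seed = 200 + rep)
    y <- as.vector(scale(log(met[, 1])))
    cohort <- rep(c("a", "b"), length.out = 8000)
    model <- stepwiseConditional(y, g, cohort = cohort)
    model <- finalJoint(model, y, g, cohort = cohort)
    sel <- model$joint$variant_id
    if (length(sel) == 1 &&
        (sel == causal || ldR2(g)[sel, causal] > 0.9)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("two independent planted variants are both selected, stronger first", {
  vs <- variantSpec("1", c(1e6, 6e6), maf = c(0.3, 0.3))
  g <- simulateGenotypes(vs, 8000, seed = 42)
  b1 <- sqrt(0.04 / (2 * 0.3 * 0.7)); b2 <- sqrt(0.02 / (2 * 0.3 * 0.7))
  tt <- TruthTable(causalEntries = data.frame(
    variant_id = vs$id, metabolite_id = "m1", beta = c(b1, b2),
    var_explained = c(0.04, 0.02)))
  met <- simulateMetabolites(g, tt, seed = 43)
  y <- as.vector(scale(log(met[, 1])))
  model <- stepwiseConditional(y, g, cohort = rep(c("a", "b"), 4000))
  expect_identical(model$selected$variant_id, vs$id)  # stronger (v1) first
})

test_that("final joint model drops sub-threshold variants and flags fallback", {
  set.seed(20)
  n <- 4000
  g <- matrix(rbinom(n * 2, 2, 0.3), n, 2, dimnames = list(NULL, c("v1", "v2")))
  y <- as.vector(scale(0.3 * g[, 1] + 0.05 * g[, 2] + rnorm(n)))
  model <- stepwiseConditional(y, g, threshold = 0.05, checkCohorts = FALSE)
  pruned <- finalJoint(model, y, g, threshold = 1e-8)
  # only the strong variant survives the much stricter joint threshold
  expect_identical(pruned$joint$variant_id, "v1")
  expect_false(pruned$fallback)

  # nothing passes an impossible threshold: the lead alone is retained
  fb <- finalJoint(model, y, g, threshold = 1e-300)
  expect_identical(fb$joint$variant_id, model$selected$variant_id[1])
  expect_true(fb$fallback)
})

test_that("collinear selected variants resolve to the earlier-selected one", {
  set.seed(21)
  n <- 2000
  g1 <- rbinom(n, 2, 0.3)
  g <- cbind(v1 = g1, v2 = g1)  # perfect copies
  y <- as.vector(scale(0.3 * g1 + rnorm(n)))
  model <- list(selected = data.frame(variant_id = c("v1", "v2"),
                                      step = 1:2, beta_cond = NA,
                                      se_cond = NA, pval_cond = NA),
                fallback = FALSE, threshold = 1e-4)
  class(model) <- "ConditionalModel"
  expect_warning(pruned <- finalJoint(model, y, g, threshold = 1e-4),
                 "collinear")
  expect_identical(pruned$joint$variant_id, "v1")
})

test_that("monotone R2 during selection and variance partition bookkeeping", {
  set.seed(22)
  n <- 10000
  g <- cbind(v1 = rbinom(n, 2, 0.3), v2 = rbinom(n, 2, 0.05),
             v3 = rbinom(n, 2, 0.008))
  y <- as.vector(scale(0.25 * g[, 1] - 0.35 * g[, 2] + 0.9 * g[, 3] + rnorm(n)))
  maf <- c(v1 = 0.3, v2 = 0.05, v3 = 0.008)
  vp <- variancePartition(y, g, maf)
  # bin totals sum exactly to the grand total
  expect_equal(sum(vp$bin_totals), vp$grand_total, tolerance = 1e-10)
  expect_true(vp$grand_total >= 0 && vp$grand_total <= 1)
  # MAF bin assignment: 0.008 rare, 0.05 low-frequency (boundary inclusive),
  # 0.3 common
  expect_identical(vp$per_variant$bin[match(c("v3", "v2", "v1"),
                                            vp$per_variant$variant_id)],
                   c("rare", "low_frequency", "common"))
  # a variant at exactly MAF 0.01 counts as rare
  vp2 <- variancePartition(y, g[, 1, drop = FALSE], c(v1 = 0.01))
  expect_identical(vp2$per_variant$bin, "rare")
  # single retained variant: grand total equals the squared correlation
  expect_equal(vp2$grand_total, cor(y, g[, 1])^2, tolerance = 1e-10)
})

test_that("orthogonal variants give exactly additive contributions", {
  set.seed(23)
  n <- 5000
  g1 <- rbinom(n, 2, 0.3)
  g2r <- resid(lm(rbinom(n, 2, 0.3) ~ g1))  # exactly orthogonal predictor
  g <- cbind(v1 = g1, v2 = g2r)
  y <- as.vector(scale(0.2 * g[, 1] + 0.2 * g[, 2] + rnorm(n)))
  vp <- variancePartition(y, g, c(v1 = 0.3, v2 = 0.3))
  expect_equal(sum(vp$per_variant$r2), vp$grand_total, tolerance = 1e-10)
})

test_that("variance explained recovers the planted target at n = 10000", {
  vs <- variantSpec("1", c(1e6, 6e6), maf = c(0.25, 0.35))
  g <- simulateGenotypes(vs, 10000, seed = 77)
  beta <- sqrt(c(0.05, 0.03) / (2 * vs$maf * (1 - vs$maf)))
  tt <- TruthTable(causalEntries = data.frame(
    variant_id = vs$id, metabolite_id = "m1", beta = beta,
    var_explained = c(0.05, 0.03)))
  met <- simulateMetabolites(g, tt, seed = 78)
  y <- as.vector(scale(log(met[, 1])))
  vp <- variancePartition(y, g, setNames(vs$maf, vs$id))
  expect_lt(abs(vp$grand_total - 0.08) / 0.08, 0.20)
})

test_that("no variants are selected under a global null", {
  set.seed(24)
  selections <- 0L
  for (rep in 1:25) {
    n <- 500
    g <- matrix(rbinom(n * 4, 2, 0.3), n, 4,
                dimnames = list(NULL, paste0("v", 1:4)))
    y <- rnorm(n)
    model <- stepwiseConditional(y, g, checkCohorts = FALSE)
    selections <- selections + nrow(model$selected)
  }
  expect_equal(selections, 0L)
})
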
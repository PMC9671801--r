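library(GenomicRanges)

fakeLd <- function(ids, fill = 0) {
  m <- matrix(fill, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 1
  m
}

test_that("isolated sentinels get a +/- 500 kb interval", {
  cand <- data.frame(variant_id = "v1", chrom = "1", pos = 1e7,
                     ref = "A", alt = "G", pval = 1e-12,
                     metabolite_id = "m1")
  iv <- metaboliteRegions(cand, fakeLd("v1"))
  expect_equal(iv$start, 9.5e6)
  expect_equal(iv$end, 10.5e6)
  expect_identical(iv$sentinel_id, "v1")
})

test_that("candidates in LD with the sentinel span a single interval", {
  ids <- paste0("v", 1:4)
  ld <- fakeLd(ids, fill = 0.5)
  cand <- data.frame(variant_id = ids, chrom = "1",
                     pos = c(1e6, 1.2e6, 1.5e6, 2e6), ref = "A", alt = "G",
                     pval = c(1e-9, 1e-20, 1e-10, 1e-9),
                     metabolite_id = "m1")
  iv <- metaboliteRegions(cand, ld)
  expect_equal(nrow(iv), 1L)
  expect_identical(iv$sentinel_id, "v2")  # smallest P
  expect_equal(iv$start, 1e6)
  expect_equal(iv$end, 2e6)
})

test_that("candidates without mutual LD yield separate sentinels", {
  ld <- fakeLd(c("v1", "v2"), fill = 0.05)
  cand <- data.frame(variant_id = c("v1", "v2"), chrom = "1",
                     pos = c(1e6, 9e6), ref = "A", alt = "G",
                     pval = c(1e-12, 1e-10), metabolite_id = "m1")
  iv <- metaboliteRegions(cand, ld)
  expect_equal(nrow(iv), 2L)
  expect_setequal(iv$sentinel_id, c("v1", "v2"))
})

test_that("a candidate absent from the LD matrix is rejected", {
  cand <- data.frame(variant_id = "vX", chrom = "1", pos = 1e6,
                     ref = "A", alt = "G", pval = 1e-9, metabolite_id = "m1")
  expect_error(metaboliteRegions(cand, fakeLd("v1")), "absent")
})

test_that("regions with sentinels in LD merge and gain 250 kb padding", {
  iv <- data.frame(chrom = "1", start = c(1e6, 3e6), end = c(2e6, 4e6),
                   sentinel_id = c("s1", "s2"), sentinel_pval = 1e-10,
                   metabolite_id = c("m1", "m2"))
  ld <- fakeLd(c("s1", "s2"), fill = 0.7)
  reg <- mergeRegions(iv, ld)
  expect_equal(length(reg), 1L)
  expect_equal(start(reg), 1e6 - 250000)
  expect_equal(end(reg), 4e6 + 250000)

  # r2 = 0.5 below the 0.6 merge threshold and a gap wider than the padding
  iv2 <- data.frame(chrom = "1", start = c(1e6, 3e6), end = c(1.2e6, 4e6),
                    sentinel_id = c("s1", "s2"), sentinel_pval = 1e-10,
                    metabolite_id = c("m1", "m2"))
  reg2 <- mergeRegions(iv2, fakeLd(c("s1", "s2"), fill = 0.5))
  expect_equal(length(reg2), 2L)
})

test_that("padded regions that abut but do not overlap stay separate", {
  # after +/- 250 kb padding: [750001, 1500000] and [1500001, 2250000]
  iv <- data.frame(chrom = "1", start = c(1000001, 1750001),
                   end = c(1250000, 2000000),
                   sentinel_id = c("s1", "s2"), sentinel_pval = 1e-10,
                   metabolite_id = c("m1", "m2"))
  reg <- mergeRegions(iv, fakeLd(c("s1", "s2"), fill = 0))
  expect_equal(length(reg), 2L)
  expect_equal(end(reg)[1] + 1L, start(reg)[2])
})

test_that("overlap merging equals a brute-force interval-union oracle", {
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    st <- sample.int(5e6, k)
    iv <- data.frame(chrom = "1", start = st,
                     end = st + sample.int(1e6, k),
                     sentinel_id = paste0("s", 1:k), sentinel_pval = 1e-10,
                     metabolite_id = "m1")
    reg <- mergeRegions(iv, fakeLd(iv$sentinel_id), pad = 0)
    # oracle: sweep over sorted padded intervals, closed-interval overlap
    o <- iv[order(iv$start), ]
    merged <- list(c(o$start[1], o$end[1]))
    for (i in seq_len(k)[-1]) {
      last <- merged[[length(merged)]]
      if (o$start[i] <= last[2])
        merged[[length(merged)]] <- c(last[1], max(last[2], o$end[i]))
      else merged[[length(merged) + 1L]] <- c(o$start[i], o$end[i])
    }
    expect_equal(start(reg), vapply(merged, `[`, numeric(1), 1))
    expect_equal(end(reg), vapply(merged, `[`, numeric(1), 2))
    # idempotence: re-merging the output changes nothing
    iv2 <- data.frame(chrom = "1", start = start(reg), end = end(reg),
                      sentinel_id = paste0("t", seq_along(reg)),
                      sentinel_pval = 1e-10, metabolite_id = "m1")
    reg2 <- mergeRegions(iv2, fakeLd(iv2$sentinel_id), pad = 0)
    expect_equal(start(reg2), start(reg))
    expect_equal(end(reg2), end(reg))
  }
})

test_that("final regions are disjoint and cover every candidate", {
  st <- smallStudy(seed = 5)
  res <- runDiscoveryPipeline(st$cohorts[1:2], minN = 100,
                              condThreshold = 1e-5, gimThreshold = 1e-5,
                              pMeta = 1e-5, mergeAdjacent = FALSE)
  reg <- res$regions
  if (length(reg) > 1) {
    df <- as.data.frame(reg)
    for (i in seq_len(nrow(df) - 1))
      expect_lt(df$end[i], df$start[i + 1])
  }
  expect_true(all(!is.na(res$candidates$region_id)))
})

test_that("well-separated planted loci are recovered as one region each", {
  st <- smallStudy(seed = 8, nRegions = 3)
  res <- runDiscoveryPipeline(st$cohorts[1:2], minN = 100,
                              condThreshold = 1e-5, gimThreshold = 1e-5,
                              pMeta = 1e-5)
  expect_equal(length(res$regions), 3L)
})

test_that("BED export converts 1-based closed to 0-based half-open exactly", {
  iv <- data.frame(chrom = "1", start = 1000, end = 2000,
                   sentinel_id = "s1", sentinel_pval = 1e-10,
                   metabolite_id = "m1")
  reg <- mergeRegions(iv, fakeLd("s1"), pad = 0)
  f <- tempfile(fileext = ".bed")
  bed <- exportRegionsBED(reg, f)
  expect_equal(bed$start, 999)
  expect_equal(bed$end, 2000)
  expect_true(file.exists(f))
})
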
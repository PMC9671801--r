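# shared fixture builders; everything is generated in code at test time

# small planted two-discovery-cohort study; sizes kept modest for unit tests
smallStudy <- function(seed = 1, sizes = c(1500, 1200, 800), nRegions = 2,
                       varExplained = 0.03, ...) {
  arch <- plantedArchitecture(nRegions = nRegions, gimsPerRegion = 2,
                              metabolitesPerGim = 2, variantsPerGim = 1,
                              proxiesPerRegion = 4,
                              varExplained = varExplained, seed = seed, ...)
  st <- simulateStudy(sizes = sizes, architecture = arch, seed = seed,
                      missingRate = 0.02)
  st
}

# adjusted Rand index between two partitions given as named label vectors
# (closed-form, used as the oracle-side metric)
ari <- function(a, b) {
  common <- intersect(names(a), names(b))
  a <- a[common]; b <- b[common]
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(common), 2)
  exp_ <- ai * bj / n2
  mx <- (ai + bj) / 2
  if (mx == exp_) return(1)
  (nij - exp_) / (mx - exp_)
}

# metabolite -> gim label vector from a pipeline result
recoveredPartition <- function(gims) {
  lab <- character(0)
  for (rid in names(gims)) for (g in gims[[rid]])
    lab[g$metabolites] <- g$id
  lab
}

plantedPartition <- function(truth) {
  pg <- plantedGims(truth)
  lab <- setNames(pg$gim_id, pg$metabolite_id)
  lab[!duplicated(names(lab))]
}

# exhaustive forward-search oracle for stepwise conditional selection,
# implemented independently with stats::lm
stepwiseOracle <- function(y, G, cohort = NULL, threshold, cohortP = 0.01,
                           checkCohorts = !is.null(cohort)) {
  keep <- !is.na(y)
  y <- y[keep]; G <- G[keep, , drop = FALSE]
  if (!is.null(cohort)) cohort <- factor(cohort[keep])
  selected <- character(0)
  remaining <- colnames(G)
  repeat {
    stats <- lapply(remaining, function(v) {
      df <- data.frame(y = y, G[, c(selected, v), drop = FALSE], check.names = FALSE)
      fm <- if (!is.null(cohort) && nlevels(cohort) > 1) {
        df$cohort <- cohort
        lm(y ~ ., data = df)
      } else lm(y ~ ., data = df)
      sm <- summary(fm)$coefficients
      row <- sm[rownames(sm) == paste0("`", v, "`") | rownames(sm) == v, , drop = FALSE]
      c(beta = row[1, 1], p = row[1, 4])
    })
    p <- vapply(stats, `[[`, numeric(1), "p")
    ord <- order(p)
    pick <- NULL
    for (i in ord) {
      if (p[i] >= threshold) break
      v <- remaining[i]
      if (checkCohorts) {
        okAll <- TRUE; signs <- numeric(0)
        for (ch in levels(cohort)) {
          idx <- cohort == ch
          df <- data.frame(y = y[idx], G[idx, c(selected, v), drop = FALSE],
                           check.names = FALSE)
          sm <- summary(lm(y ~ ., data = df))$coefficients
          row <- sm[rownames(sm) == paste0("`", v, "`") | rownames(sm) == v, ,
                    drop = FALSE]
          if (row[1, 4] >= cohortP) { okAll <- FALSE; break }
          signs <- c(signs, sign(row[1, 1]))
        }
        if (!okAll || length(unique(signs)) > 1) next
      }
      pick <- v
      break
    }
    if (is.null(pick)) break
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (!length(remaining)) break
  }
  selected
}
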
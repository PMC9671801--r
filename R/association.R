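#' @importFrom data.table as.data.table data.table rbindlist setDF setDT :=
NULL

#' Per-variant marginal association within one cohort
#'
#' Simple linear regression of each prepared (standardized) metabolite on
#' each allele dosage, complete-case per metabolite. Slope, standard error
#' and two-sided P from the t distribution with n-2 degrees of freedom are
#' returned together with the minor allele count (MAC) over the analyzed
#' samples. Variants with zero dosage variance, or fewer than `minObs`
#' complete observations, are excluded and flagged.
#'
#' @param cohort a [CohortData-class].
#' @param prepared a [PreparedMetabolites-class] for the same samples (or a
#'   plain standardized matrix).
#' @param minObs minimum complete observations per test (default 30).
#' @return data.frame with columns `variant_id`, `metabolite_id`, `cohort`,
#'   `beta`, `se`, `pval`, `mac`, `n`.
#' @export
marginalAssoc <- function(cohort, prepared, minObs = 30) {
  G <- dosages(cohort)
  Y <- if (is(prepared, "PreparedMetabolites")) residualMatrix(prepared) else as.matrix(prepared)
  stopifnot(nrow(G) == nrow(Y))
  out <- vector("list", ncol(Y))
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    obs <- which(!is.na(y))
    n <- length(obs)
    if (n < minObs) next
    yv <- y[obs]
    Gs <- G[obs, , drop = FALSE]
    csum <- colSums(Gs)
    gm <- csum / n
    Sgg <- colSums(Gs^2) - n * gm^2
    ym <- mean(yv)
    Syy <- sum(yv^2) - n * ym^2
    Sgy <- as.vector(crossprod(Gs, yv)) - n * gm * ym
    ok <- Sgg > 0
    beta <- Sgy / Sgg
    rss <- Syy - beta * Sgy
    sigma2 <- pmax(rss, 0) / (n - 2)
    se <- sqrt(sigma2 / Sgg)
    tstat <- beta / se
    pval <- 2 * pt(-abs(tstat), df = n - 2)
    mac <- pmin(csum, 2 * n - csum)
    out[[j]] <- data.table(
      variant_id = colnames(G)[ok], metabolite_id = colnames(Y)[j],
      cohort = cohortId(cohort), beta = beta[ok], se = se[ok],
      pval = pval[ok], mac = round(mac[ok]), n = n)
  }
  setDF(rbindlist(out))
}

#' Inverse-variance weighted fixed-effect meta-analysis
#'
#' Pools per-cohort association records per (variant, metabolite):
#' `beta_meta = sum(w_i beta_i) / sum(w_i)` with `w_i = 1/se_i^2`,
#' `se_meta = sum(w_i)^(-1/2)`, two-sided P from the normal distribution.
#' Cohorts failing the minor-allele-count filter (`mac <= macMin`) are
#' dropped before pooling; pairs with no surviving cohort are dropped
#' entirely.
#'
#' @param records long data.frame of per-cohort statistics as produced by
#'   [marginalAssoc()].
#' @param macMin minor allele count threshold; cohorts must have
#'   `mac > macMin` to contribute (default 10).
#' @return data.frame with `variant_id`, `metabolite_id`, `beta_meta`,
#'   `se_meta`, `pval_meta`, `n_cohorts`, `direction_consistent` (all
#'   contributing betas share a sign), `max_cohort_p`, `min_cohort_mac`,
#'   `n_total`.
#' @export
ivwMeta <- function(records, macMin = 10) {
  dt <- as.data.table(records)[mac > macMin]
  if (!nrow(dt))
    return(data.frame(variant_id = character(0), metabolite_id = character(0),
                      beta_meta = numeric(0), se_meta = numeric(0),
                      pval_meta = numeric(0), n_cohorts = integer(0),
                      direction_consistent = logical(0),
                      max_cohort_p = numeric(0), min_cohort_mac = numeric(0),
                      n_total = integer(0)))
  meta <- dt[, {
    w <- 1 / se^2
    b <- sum(w * beta) / sum(w)
    s <- 1 / sqrt(sum(w))
    list(beta_meta = b, se_meta = s,
         pval_meta = 2 * pnorm(-abs(b / s)),
         n_cohorts = .N,
         direction_consistent = all(beta > 0) || all(beta < 0),
         max_cohort_p = max(pval), min_cohort_mac = min(mac),
         n_total = sum(n))
  }, by = .(variant_id, metabolite_id)]
  setDF(meta)
}

#' Filter meta-analyzed associations to region-definition candidates
#'
#' Retains associations with meta-analysis `P < pMeta`, and `P < pCohort`,
#' `MAC > macMin` and a consistent direction of effect in every contributing
#' discovery cohort (all of which must contribute).
#'
#' @param meta output of [ivwMeta()] on the discovery cohorts.
#' @param records the per-cohort records that fed the meta-analysis.
#' @param pMeta meta-analysis significance threshold (default 5e-8).
#' @param pCohort per-cohort threshold (default 0.01).
#' @param macMin per-cohort MAC threshold (default 10).
#' @param nCohorts number of discovery cohorts that must each pass
#'   (default: number of distinct cohorts in `records`).
#' @return subset of `meta` rows meeting all conditions.
#' @export
candidateFilter <- function(meta, records, pMeta = 5e-8, pCohort = 0.01,
                            macMin = 10, nCohorts = NULL) {
  if (is.null(nCohorts)) nCohorts <- length(unique(records$cohort))
  dt <- as.data.table(records)
  percoh <- dt[, list(
    all_pass = .N == nCohorts && all(pval < pCohort) && all(mac > macMin) &&
      (all(beta > 0) || all(beta < 0))
  ), by = .(variant_id, metabolite_id)]
  m <- as.data.table(meta)
  m <- merge(m, percoh, by = c("variant_id", "metabolite_id"))
  setDF(m[all_pass == TRUE & pval_meta < pMeta][, all_pass := NULL])
}

#' Bonferroni threshold for validation-stage significance
#'
#' Genome-wide threshold divided by the number of metabolites tested,
#' rounded to 3 significant figures (e.g. 5e-8 over 913 metabolites gives
#' 5.48e-11).
#'
#' @param alpha genome-wide threshold (default 5e-8).
#' @param nMetabolites number of metabolites (default 913).
#' @return the corrected threshold.
#' @export
validationThreshold <- function(alpha = 5e-8, nMetabolites = 913) {
  signif(alpha / nMetabolites, 3)
}

#' Bonferroni threshold for conditional analysis
#'
#' `alpha / (nVariants * nMetabolites)` rounded to 3 significant figures;
#' with the defaults (the maximum numbers of variants and metabolites tested
#' at any region) this is 1.25e-8.
#'
#' @param alpha family-wise level (default 0.05).
#' @param nVariants maximum regional variant count (default 39297).
#' @param nMetabolites maximum regional metabolite count (default 102).
#' @return the corrected threshold.
#' @export
conditionalThreshold <- function(alpha = 0.05, nVariants = 39297,
                                 nMetabolites = 102) {
  signif(alpha / (nVariants * nMetabolites), 3)
}

#' Validate discovery associations in an independent cohort
#'
#' Re-meta-analyzes the discovery cohorts together with the validation
#' cohort for each requested (variant, metabolite) pair. A pair is
#' `"validated"` iff the combined P is below `threshold` and all three
#' per-cohort effect estimates share a sign; `"untestable"` if the variant
#' or metabolite is absent from the validation records.
#'
#' @param pairs data.frame with `variant_id`, `metabolite_id` (typically the
#'   regional sentinel-metabolite pairs).
#' @param discoveryRecords per-cohort records from the discovery cohorts.
#' @param validationRecords per-cohort records from the validation cohort.
#' @param threshold combined significance threshold, default
#'   [validationThreshold()].
#' @param macMin MAC filter applied before pooling.
#' @return `pairs` with added `beta_combined`, `se_combined`,
#'   `pval_combined`, `n_cohorts`, `verdict`.
#' @export
validateAssociation <- function(pairs, discoveryRecords, validationRecords,
                                threshold = validationThreshold(),
                                macMin = 10) {
  all3 <- rbind(as.data.frame(discoveryRecords), as.data.frame(validationRecords))
  nExpect <- length(unique(all3$cohort))
  dt <- as.data.table(all3)[mac > macMin]
  out <- as.data.table(pairs)[, c("beta_combined", "se_combined",
                                  "pval_combined", "n_cohorts") :=
                                list(NA_real_, NA_real_, NA_real_, 0L)]
  out$verdict <- "untestable"
  for (i in seq_len(nrow(out))) {
    rec <- dt[variant_id == out$variant_id[i] &
                metabolite_id == out$metabolite_id[i]]
    if (!nrow(rec)) next
    w <- 1 / rec$se^2
    b <- sum(w * rec$beta) / sum(w)
    s <- 1 / sqrt(sum(w))
    out$beta_combined[i] <- b
    out$se_combined[i] <- s
    out$pval_combined[i] <- 2 * pnorm(-abs(b / s))
    out$n_cohorts[i] <- nrow(rec)
    if (nrow(rec) < nExpect) { out$verdict[i] <- "untestable"; next }
    consistent <- all(rec$beta > 0) || all(rec$beta < 0)
    out$verdict[i] <- if (out$pval_combined[i] < threshold && consistent)
      "validated" else "not_validated"
  }
  setDF(out)
}

#' Pairwise LD (squared Pearson correlation) between dosage columns
#'
#' @param dosageMat samples x variants dosage matrix from the LD reference
#'   cohort (conventionally the largest cohort).
#' @param variantIds optional subset of columns.
#' @return symmetric matrix of r-squared values with unit diagonal;
#'   zero-variance columns give NA rows/columns (flagged via attribute
#'   `"undefined"`).
#' @export
ldR2 <- function(dosageMat, variantIds = NULL) {
  if (!is.null(variantIds)) dosageMat <- dosageMat[, variantIds, drop = FALSE]
  v <- apply(dosageMat, 2, var)
  bad <- names(v)[v == 0]
  r <- suppressWarnings(cor(dosageMat, use = "pairwise.complete.obs"))^2
  if (length(bad)) r[bad, ] <- r[, bad] <- NA_real_
  diag(r) <- 1
  attr(r, "undefined") <- bad
  r
}
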
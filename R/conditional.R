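# Partial-regression scan (Frisch-Waugh-Lovell): conditional slope, SE and
# two-sided t-test P of y on each column of Gcand, adjusting for X.
.condScan <- function(y, X, Gcand) {
  qrX <- qr(X)
  ry <- qr.resid(qrX, y)
  RG <- qr.resid(qrX, Gcand)
  n <- length(y)
  df <- n - ncol(X) - 1L
  Sgg <- colSums(RG^2)
  Sgy <- as.vector(crossprod(RG, ry))
  ok <- Sgg > 1e-12
  beta <- ifelse(ok, Sgy / Sgg, NA_real_)
  rss <- sum(ry^2) - ifelse(ok, beta * Sgy, 0)
  se <- ifelse(ok, sqrt(pmax(rss, 0) / df / Sgg), NA_real_)
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df = df)
  data.frame(variant_id = colnames(Gcand), beta = beta, se = se, pval = pval,
             row.names = NULL, stringsAsFactors = FALSE)
}

# covariate design matrix: intercept + cohort indicator + extra covariates
.condDesign <- function(n, cohort = NULL, covariates = NULL) {
  X <- matrix(1, n, 1)
  if (!is.null(cohort) && length(unique(cohort)) > 1)
    X <- cbind(X, stats::model.matrix(~ factor(cohort))[, -1, drop = FALSE])
  if (!is.null(covariates) && NCOL(covariates) > 0)
    X <- cbind(X, stats::model.matrix(~ ., as.data.frame(covariates))[, -1, drop = FALSE])
  X
}

#' Forward stepwise conditional analysis for one region and metabolite
#'
#' Exact conditional analysis on pooled individual-level data: at each step,
#' every remaining regional variant is tested conditional on the already
#' selected variants (and the cohort indicator plus any extra covariates);
#' the candidate with the smallest conditional P is added, provided the same
#' conditional association has a consistent direction of effect with
#' `P < cohortP` in each discovery cohort separately (ineligible top
#' candidates are skipped in favor of the next best). Selection stops when
#' no eligible candidate reaches `threshold`.
#'
#' @param y pooled standardized metabolite vector (NA rows dropped together
#'   with the corresponding dosage rows).
#' @param G pooled samples x regional-variants dosage matrix.
#' @param cohort factor/vector of cohort labels, same length as `y` (used
#'   both as a fixed-effect covariate and for the per-cohort consistency
#'   check).
#' @param covariates optional extra covariates (e.g. genetic principal
#'   components).
#' @param threshold conditional significance threshold, default
#'   [conditionalThreshold()] = 1.25e-8.
#' @param cohortP per-cohort conditional eligibility threshold (default
#'   0.01); set `checkCohorts = FALSE` to disable the check.
#' @param checkCohorts logical, re-check per-cohort direction consistency at
#'   every step (default TRUE when `cohort` has > 1 level).
#' @return list of class `ConditionalModel`: `selected` data.frame
#'   (`variant_id`, `step`, `beta_cond`, `se_cond`, `pval_cond`), plus
#'   `region` bookkeeping fields filled by callers.
#' @export
stepwiseConditional <- function(y, G, cohort = NULL, covariates = NULL,
                                threshold = conditionalThreshold(),
                                cohortP = 0.01, checkCohorts = NULL) {
  keep <- !is.na(y)
  y <- y[keep]
  G <- G[keep, , drop = FALSE]
  if (!is.null(cohort)) cohort <- cohort[keep]
  if (!is.null(covariates))
    covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
  if (is.null(checkCohorts))
    checkCohorts <- !is.null(cohort) && length(unique(cohort)) > 1
  X0 <- .condDesign(length(y), cohort, covariates)
  selected <- character(0)
  rows <- list()
  remaining <- colnames(G)
  repeat {
    if (!length(remaining)) break
    X <- cbind(X0, G[, selected, drop = FALSE])
    scan <- .condScan(y, X, G[, remaining, drop = FALSE])
    scan <- scan[order(scan$pval), , drop = FALSE]
    pick <- NULL
    for (i in seq_len(nrow(scan))) {
      if (is.na(scan$pval[i]) || scan$pval[i] >= threshold) break
      v <- scan$variant_id[i]
      if (checkCohorts && !.cohortConsistent(y, X0c = NULL, G, selected, v,
                                             cohort, covariates, cohortP))
        next
      pick <- scan[i, , drop = FALSE]
      break
    }
    if (is.null(pick)) break
    selected <- c(selected, pick$variant_id)
    rows[[length(rows) + 1L]] <- data.frame(
      variant_id = pick$variant_id, step = length(selected),
      beta_cond = pick$beta, se_cond = pick$se, pval_cond = pick$pval,
      stringsAsFactors = FALSE)
    remaining <- setdiff(remaining, pick$variant_id)
  }
  structure(list(
    selected = if (length(rows)) do.call(rbind, rows) else
      data.frame(variant_id = character(0), step = integer(0),
                 beta_cond = numeric(0), se_cond = numeric(0),
                 pval_cond = numeric(0)),
    fallback = FALSE, threshold = threshold),
    class = "ConditionalModel")
}

# per-cohort conditional direction + P check for one candidate
.cohortConsistent <- function(y, X0c, G, selected, v, cohort, covariates,
                              cohortP) {
  betas <- numeric(0)
  for (ch in unique(cohort)) {
    idx <- which(cohort == ch & !is.na(y))
    Xc <- .condDesign(length(idx), NULL,
                      if (is.null(covariates)) NULL else
                        covariates[idx, , drop = FALSE])
    Xc <- cbind(Xc, G[idx, selected, drop = FALSE])
    sc <- .condScan(y[idx], Xc, G[idx, v, drop = FALSE])
    if (is.na(sc$pval) || sc$pval >= cohortP) return(FALSE)
    betas <- c(betas, sc$beta)
  }
  all(betas > 0) || all(betas < 0)
}

#' Final joint model pruning of a stepwise selection
#'
#' Refits all selected variants jointly (with the same covariate design) and
#' drops any variant whose joint P is at or above `threshold`. If no variant
#' survives (including the lead), the lead variant alone is retained and the
#' fallback flag is set. Perfectly collinear selected variants are resolved
#' by dropping the later-selected member with a warning.
#'
#' @inheritParams stepwiseConditional
#' @param model a `ConditionalModel` from [stepwiseConditional()].
#' @return the pruned `ConditionalModel` with a `joint` data.frame
#'   (`variant_id`, `beta_joint`, `se_joint`, `pval_joint`) and `fallback`
#'   flag.
#' @export
finalJoint <- function(model, y, G, cohort = NULL, covariates = NULL,
                       threshold = model$threshold) {
  keep <- !is.na(y)
  y <- y[keep]
  G <- G[keep, , drop = FALSE]
  if (!is.null(cohort)) cohort <- cohort[keep]
  if (!is.null(covariates))
    covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
  sel <- model$selected$variant_id
  if (!length(sel)) {
    model$joint <- data.frame(variant_id = character(0), beta_joint = numeric(0),
                              se_joint = numeric(0), pval_joint = numeric(0))
    return(model)
  }
  X0 <- .condDesign(length(y), cohort, covariates)
  # drop later-selected members of collinear groups
  repeat {
    Xf <- cbind(X0, G[, sel, drop = FALSE])
    if (qr(Xf)$rank == ncol(Xf) || length(sel) == 1) break
    warning("collinear selected variants; dropping later-selected member")
    sel <- sel[-length(sel)]
  }
  joint <- .jointFit(y, X0, G[, sel, drop = FALSE])
  pass <- joint$pval_joint < threshold
  if (!any(pass)) {
    lead <- model$selected$variant_id[1]
    model$joint <- joint[joint$variant_id == lead, , drop = FALSE]
    model$fallback <- TRUE
  } else {
    kept <- joint$variant_id[pass]
    model$joint <- .jointFit(y, X0, G[, kept, drop = FALSE])
    model$fallback <- FALSE
  }
  model$selected <- model$selected[model$selected$variant_id %in%
                                     model$joint$variant_id, , drop = FALSE]
  model
}

.jointFit <- function(y, X0, Gsel) {
  X <- cbind(X0, Gsel)
  fit <- stats::lm.fit(X, y)
  df <- length(y) - fit$rank
  rss <- sum(fit$residuals^2)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * rss / df)
  idx <- ncol(X0) + seq_len(ncol(Gsel))
  beta <- fit$coefficients[idx]
  sev <- se[idx]
  data.frame(variant_id = colnames(Gsel), beta_joint = unname(beta),
             se_joint = sev, pval_joint = 2 * pt(-abs(beta / sev), df),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Variance explained by conditionally independent variants, by MAF bin
#'
#' The grand total is the R-squared of the joint regression of the
#' standardized metabolite on all retained variants (pooled over the
#' metabolite's regions). Each variant's contribution is the decrease in
#' joint R-squared when it is removed (leave-one-out); any shared
#' R-squared (grand total minus the sum of contributions) is allocated
#' proportionally to the contributions. Bin totals sum contributions by MAF
#' bin: rare (MAF <= 1%), low-frequency (1% < MAF <= 5%), common (> 5%).
#'
#' @param y standardized metabolite vector.
#' @param G samples x retained-variants dosage matrix (all regions pooled).
#' @param maf named numeric vector of meta-analysis minor allele
#'   frequencies for the retained variants.
#' @return list of class `VarianceReport`: `per_variant` data.frame
#'   (`variant_id`, `maf`, `bin`, `r2`), `bin_totals` named numeric
#'   (rare/low_frequency/common), `grand_total`.
#' @export
variancePartition <- function(y, G, maf) {
  keep <- !is.na(y)
  y <- y[keep]; G <- as.matrix(G)[keep, , drop = FALSE]
  vids <- colnames(G)
  if (!length(vids)) {
    return(structure(list(
      per_variant = data.frame(variant_id = character(0), maf = numeric(0),
                               bin = character(0), r2 = numeric(0)),
      bin_totals = c(rare = 0, low_frequency = 0, common = 0),
      grand_total = 0), class = "VarianceReport"))
  }
  r2of <- function(cols) {
    if (!length(cols)) return(0)
    fit <- stats::lm.fit(cbind(1, G[, cols, drop = FALSE]), y)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  grand <- r2of(vids)
  contrib <- vapply(vids, function(v) grand - r2of(setdiff(vids, v)), numeric(1))
  contrib <- pmax(contrib, 0)
  shared <- grand - sum(contrib)
  if (sum(contrib) > 0) {
    contrib <- contrib + shared * contrib / sum(contrib)
  } else if (length(contrib)) {
    contrib <- contrib + shared / length(contrib)
  }
  bin <- ifelse(maf[vids] <= 0.01, "rare",
                ifelse(maf[vids] <= 0.05, "low_frequency", "common"))
  bt <- c(rare = sum(contrib[bin == "rare"]),
          low_frequency = sum(contrib[bin == "low_frequency"]),
          common = sum(contrib[bin == "common"]))
  structure(list(
    per_variant = data.frame(variant_id = vids, maf = unname(maf[vids]),
                             bin = bin, r2 = unname(contrib),
                             row.names = NULL),
    bin_totals = bt, grand_total = grand), class = "VarianceReport")
}

#' @export
print.ConditionalModel <- function(x, ...) {
  cat("ConditionalModel:", nrow(x$selected), "selected variant(s)",
      if (isTRUE(x$fallback)) "(fallback: lead retained)" else "", "\n")
  if (nrow(x$selected)) print(x$selected)
  invisible(x)
}

#' @export
print.VarianceReport <- function(x, ...) {
  cat("VarianceReport: grand total R2 =", signif(x$grand_total, 4), "\n")
  print(x$bin_totals)
  invisible(x)
}
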
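#' Build a weighted metabolite genetic score
#'
#' Variants are filtered to those with marginal meta-analysis `P < pThresh`
#' and association with fewer than `maxMetabolites` metabolites (pleiotropy
#' filter); the per-sample score is the dosage-weighted sum with weights
#' equal to the marginal effect sizes. Metabolites left with fewer than two
#' surviving variants yield no score (`NULL`).
#'
#' @param metaboliteId the metabolite to score.
#' @param variantIds its conditionally independent variants.
#' @param marginalStats data.frame of marginal meta-analysis statistics
#'   (`variant_id`, `metabolite_id`, `beta_meta`, `pval_meta`) covering at
#'   least the candidate variants; also used to count, per variant, the
#'   number of metabolites it is associated with at `P < pThresh`.
#' @param dosageMat samples x variants dosage matrix of the target cohort.
#' @param pThresh marginal significance filter (default 5e-8).
#' @param maxMetabolites a variant associated with this many or more
#'   metabolites is excluded from all scores (default 5).
#' @return list of class `MetaboliteScore`: `metabolite_id`, `weights`
#'   (named by variant), `score` (per-sample), `n_variants`; or `NULL` if
#'   fewer than two variants survive.
#' @export
buildScore <- function(metaboliteId, variantIds, marginalStats, dosageMat,
                       pThresh = 5e-8, maxMetabolites = 5) {
  ms <- as.data.frame(marginalStats)
  sig <- ms[ms$pval_meta < pThresh, , drop = FALSE]
  pleio <- table(sig$variant_id[!duplicated(paste(sig$variant_id,
                                                  sig$metabolite_id))])
  own <- sig[sig$metabolite_id == metaboliteId &
               sig$variant_id %in% variantIds, , drop = FALSE]
  keep <- own$variant_id[own$variant_id %in% colnames(dosageMat) &
                           pleio[own$variant_id] < maxMetabolites]
  if (length(keep) < 2) return(NULL)
  w <- setNames(own$beta_meta[match(keep, own$variant_id)], keep)
  score <- as.vector(dosageMat[, keep, drop = FALSE] %*% w)
  structure(list(metabolite_id = metaboliteId, weights = w, score = score,
                 n_variants = length(keep)),
            class = "MetaboliteScore")
}

#' Phenome-wide association of a metabolite score with binary phecodes
#'
#' Logistic regression of each phecode on the standardized score plus
#' covariates; the reported odds ratio is per 1 s.d. of the score. Phecodes
#' with fewer than `minCases` cases (or controls) are skipped. Fits showing
#' separation are flagged with a missing P value.
#'
#' @param score a `MetaboliteScore` from [buildScore()] (or a numeric
#'   vector).
#' @param phecodes samples x phecodes 0/1 matrix.
#' @param covariates optional covariate data.frame.
#' @param minCases minimum case (and control) count (default 50).
#' @return data.frame with `metabolite_id`, `phecode_id`, `or`, `beta`,
#'   `se`, `pval`, `n_cases`, `n_controls`, `flag`.
#' @export
phewas <- function(score, phecodes, covariates = NULL, minCases = 50) {
  s <- if (inherits(score, "MetaboliteScore")) score$score else score
  mid <- if (inherits(score, "MetaboliteScore")) score$metabolite_id else NA_character_
  z <- as.vector(scale(s))
  X <- cbind(1, z)
  if (!is.null(covariates) && NCOL(covariates) > 0)
    X <- cbind(X, stats::model.matrix(~ ., as.data.frame(covariates))[, -1, drop = FALSE])
  out <- vector("list", ncol(phecodes))
  for (j in seq_len(ncol(phecodes))) {
    yy <- phecodes[, j]
    ok <- !is.na(yy)
    nc <- sum(yy[ok] == 1); nn <- sum(yy[ok] == 0)
    if (nc < minCases || nn < minCases) next
    fit <- suppressWarnings(
      glm.fit(X[ok, , drop = FALSE], yy[ok], family = stats::binomial()))
    cf <- fit$coefficients[2]
    XW <- X[ok, , drop = FALSE] * sqrt(fit$weights)
    se <- sqrt(diag(chol2inv(chol(crossprod(XW)))))[2]
    sep <- !fit$converged || abs(cf) > 15 || se > 100
    out[[j]] <- data.frame(
      metabolite_id = mid, phecode_id = colnames(phecodes)[j],
      or = exp(cf), beta = unname(cf), se = unname(se),
      pval = if (sep) NA_real_ else 2 * pnorm(-abs(cf / se)),
      n_cases = nc, n_controls = nn,
      flag = if (sep) "separation" else "", row.names = NULL)
  }
  do.call(rbind, out)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Standard step-up adjusted q values ([stats::p.adjust()], method "BH")
#' plus the significant set at level `q`.
#'
#' @param p vector of P values in (0, 1\].
#' @param q FDR level (default 0.05).
#' @return list: `qvalues` (same order as `p`), `significant` logical.
#' @export
bhFdr <- function(p, q = 0.05) {
  if (any(!is.na(p) & (p <= 0 | p > 1))) stop("p values must be in (0, 1]")
  qa <- p.adjust(p, method = "BH")
  list(qvalues = qa, significant = !is.na(qa) & qa < q)
}

#' Dose-response assessment via a two-sample-style MR toolkit
#'
#' Per-variant Wald ratios (`beta_outcome / beta_exposure`, first-order
#' standard errors `se_outcome / |beta_exposure|`) are pooled by
#' inverse-variance weighting; Cochran's Q on the ratio estimates tests
#' between-variant heterogeneity, and MR-Egger regression (weighted, with
#' intercept) tests directional pleiotropy. The `strong_evidence` flag is
#' set iff at least three variants contribute and the heterogeneity P
#' exceeds 0.05.
#'
#' @param betaExposure,seExposure per-variant effects on the metabolite.
#' @param betaOutcome,seOutcome per-variant effects on the outcome
#'   (log-odds scale).
#' @return list of class `MRResult`: `ivw_estimate`, `ivw_se`, `ivw_pval`,
#'   `q`, `q_df`, `het_pval`, `egger_intercept`, `egger_intercept_se`,
#'   `egger_pval`, `n_variants`, `strong_evidence`. Egger fields are `NA`
#'   with fewer than three variants.
#' @export
mrDoseResponse <- function(betaExposure, betaOutcome, seExposure, seOutcome) {
  k <- length(betaExposure)
  if (k < 1) stop("at least one variant required")
  ratio <- betaOutcome / betaExposure
  seRatio <- seOutcome / abs(betaExposure)
  w <- 1 / seRatio^2
  ivw <- sum(w * ratio) / sum(w)
  ivwSe <- 1 / sqrt(sum(w))
  ivwP <- 2 * pnorm(-abs(ivw / ivwSe))
  if (k >= 2) {
    qstat <- sum(w * (ratio - ivw)^2)
    qdf <- k - 1L
    hetP <- pchisq(qstat, qdf, lower.tail = FALSE)
  } else {
    qstat <- NA_real_; qdf <- NA_integer_; hetP <- NA_real_
  }
  if (k >= 3) {
    # MR-Egger: orient exposure effects positive, weight by 1/seOutcome^2
    sgn <- sign(betaExposure)
    bx <- abs(betaExposure); by <- betaOutcome * sgn
    we <- 1 / seOutcome^2
    fit <- stats::lm(by ~ bx, weights = we)
    sm <- summary(fit)
    eggerInt <- sm$coefficients[1, 1]
    eggerIntSe <- sm$coefficients[1, 2]
    eggerP <- sm$coefficients[1, 4]
  } else {
    eggerInt <- eggerIntSe <- eggerP <- NA_real_
  }
  structure(list(
    ivw_estimate = ivw, ivw_se = ivwSe, ivw_pval = ivwP,
    q = qstat, q_df = qdf, het_pval = hetP,
    egger_intercept = eggerInt, egger_intercept_se = eggerIntSe,
    egger_pval = eggerP, n_variants = k,
    strong_evidence = isTRUE(k >= 3 && !is.na(hetP) && hetP > 0.05)),
    class = "MRResult")
}

#' @export
print.MRResult <- function(x, ...) {
  cat(sprintf("MR (IVW): %.4f (SE %.4f, P %.3g); Q = %.3f (het P %.3g); %s\n",
              x$ivw_estimate, x$ivw_se, x$ivw_pval,
              if (is.na(x$q)) NA else x$q, x$het_pval,
              if (x$strong_evidence) "strong evidence" else "no strong-evidence flag"))
  invisible(x)
}
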
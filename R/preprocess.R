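#' Prepare raw metabolite abundances for genetic analysis
#'
#' Applies, per metabolite, the standard untargeted-metabolomics pipeline:
#' natural-log transform, winsorization at `winsorK` standard deviations from
#' the mean (mean and s.d. computed once, on the pre-winsorization log
#' values), linear-regression residualization on the covariates
#' (complete-case per metabolite), and standardization of the residuals to
#' mean 0 and s.d. 1 (sample s.d., n-1 denominator). Metabolites observed in
#' fewer than `minN` samples are dropped, as are metabolites constant after
#' the log transform (with a warning). Samples missing any covariate are
#' excluded from all metabolites.
#'
#' @param raw samples x metabolites matrix of strictly positive abundances
#'   (NA allowed for missing).
#' @param covariates per-sample covariate data.frame; character/factor
#'   columns are expanded to dummies via [stats::model.matrix()].
#' @param winsorK winsorization bound in standard deviations (default 5).
#' @param minN minimum number of non-missing samples for a metabolite to be
#'   retained (default 200).
#' @return A [PreparedMetabolites-class] object.
#' @export
preprocessMetabolites <- function(raw, covariates = NULL, winsorK = 5,
                                  minN = 200) {
  raw <- as.matrix(raw)
  if (is.null(colnames(raw)))
    colnames(raw) <- paste0("met", seq_len(ncol(raw)))
  bad <- which(raw <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive abundance in metabolite(s): ",
         paste(unique(colnames(raw)[bad[, 2]]), collapse = ", "))

  n <- nrow(raw)
  covOk <- rep(TRUE, n)
  X <- NULL
  if (!is.null(covariates) && ncol(as.data.frame(covariates))) {
    covariates <- as.data.frame(covariates)
    covOk <- complete.cases(covariates)
    # constant columns (e.g. a single-cohort batch label) carry no information
    keepCov <- vapply(covariates, function(v) length(unique(v[covOk])) > 1,
                      logical(1))
    if (any(keepCov))
      X <- stats::model.matrix(~ ., data = covariates[covOk, keepCov, drop = FALSE])
  }

  logm <- log(raw)
  logm[!covOk, ] <- NA  # samples missing a covariate are excluded throughout

  nObs <- colSums(!is.na(logm))
  keep <- nObs >= minN
  const <- rep(FALSE, ncol(logm))
  res <- matrix(NA_real_, n, ncol(logm), dimnames = dimnames(logm))
  nWins <- integer(ncol(logm))

  for (j in which(keep)) {
    v <- logm[, j]
    obs <- which(!is.na(v))
    mu <- mean(v[obs]); s <- sd(v[obs])
    if (!is.finite(s) || s == 0) { const[j] <- TRUE; next }
    lo <- mu - winsorK * s; hi <- mu + winsorK * s
    w <- pmin(pmax(v, lo), hi)
    nWins[j] <- sum(v[obs] < lo | v[obs] > hi)
    if (!is.null(X)) {
      # rows of X correspond to covOk samples in order
      xi <- match(obs, which(covOk))
      fit <- stats::lm.fit(X[xi, , drop = FALSE], w[obs])
      r <- fit$residuals
    } else {
      r <- w[obs] - mean(w[obs])
    }
    sr <- sd(r)
    if (!is.finite(sr) || sr == 0) { const[j] <- TRUE; next }
    res[obs, j] <- (r - mean(r)) / sr
  }
  if (any(const))
    warning("dropped constant metabolite(s): ",
            paste(colnames(logm)[const], collapse = ", "))
  keep <- keep & !const
  new("PreparedMetabolites",
      residuals = res[, keep, drop = FALSE],
      inclusionMask = setNames(keep, colnames(logm)),
      provenance = data.frame(metabolite_id = colnames(logm),
                              n_obs = nObs, n_winsorized = nWins,
                              row.names = NULL))
}

#' Winsorize a numeric vector at k standard deviations
#'
#' Bounds are `mean +/- k * sd` computed once on the input (NA ignored);
#' values outside are replaced by the bound.
#'
#' @param x numeric vector.
#' @param k bound in standard deviations.
#' @return winsorized vector (same NA pattern).
#' @export
winsorize <- function(x, k = 5) {
  mu <- mean(x, na.rm = TRUE); s <- sd(x, na.rm = TRUE)
  pmin(pmax(x, mu - k * s), mu + k * s)
}
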
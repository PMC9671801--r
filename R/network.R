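#' Multiple imputation by chained equations (normal linear models)
#'
#' Metabolites with more than `maxMissing` missing observations are excluded
#' before imputation. For each of `m` imputations an independent chain is
#' run for `nIter` iterations: each metabolite with missing entries is
#' regressed on all other eligible metabolites over its observed rows, the
#' regression parameters are drawn from their posterior (Bayesian linear
#' regression, the "norm" method), and missing entries are imputed as
#' posterior-predictive draws. This assumes missing values are explainable
#' by the observed metabolite values (missing at random given the
#' observed data).
#'
#' @param mat samples x metabolites matrix (residual scale) with NAs.
#' @param maxMissing maximum missing fraction per metabolite (default 0.30,
#'   strict: fraction must be below this to be retained).
#' @param m number of imputations (default 30).
#' @param nIter chained-equation iterations per imputation (default 50).
#' @param seed integer seed; deterministic given the seed.
#' @return list of `m` completed matrices (columns = retained metabolites);
#'   attribute `"excluded"` lists dropped metabolites. Samples missing all
#'   retained metabolites are excluded with a warning.
#' @export
imputeChained <- function(mat, maxMissing = 0.30, m = 30, nIter = 50,
                          seed = 1) {
  mat <- as.matrix(mat)
  frac <- colMeans(is.na(mat))
  excluded <- colnames(mat)[frac >= maxMissing]
  mat <- mat[, frac < maxMissing, drop = FALSE]
  allMiss <- rowSums(!is.na(mat)) == 0
  if (any(allMiss)) {
    warning(sum(allMiss), " sample(s) missing all metabolites excluded")
    mat <- mat[!allMiss, , drop = FALSE]
  }
  miss <- is.na(mat)
  if (!any(miss)) {
    out <- rep(list(mat), m)
    attr(out, "excluded") <- excluded
    return(out)
  }
  set.seed(seed)
  p <- ncol(mat)
  out <- vector("list", m)
  for (imp in seq_len(m)) {
    x <- mat
    # initialize missing entries by random draws from the observed margin
    for (j in seq_len(p)) {
      mj <- miss[, j]
      if (any(mj))
        x[mj, j] <- sample(mat[!mj, j], sum(mj), replace = TRUE)
    }
    for (it in seq_len(nIter)) {
      for (j in which(colSums(miss) > 0)) {
        obs <- !miss[, j]
        X <- cbind(1, x[, -j, drop = FALSE])
        yobs <- x[obs, j]
        Xo <- X[obs, , drop = FALSE]
        qrX <- qr(Xo)
        bhat <- qr.coef(qrX, yobs)
        bhat[is.na(bhat)] <- 0
        res <- yobs - Xo %*% bhat
        df <- max(length(yobs) - ncol(Xo), 1)
        sigma2 <- sum(res^2) / rchisq(1, df)
        R <- qr.R(qrX)
        # guard rank deficiency with a small ridge
        V <- tryCatch(chol2inv(R), error = function(e)
          chol2inv(chol(crossprod(Xo) + diag(1e-8, ncol(Xo)))))
        bdraw <- bhat + t(chol(sigma2 * (V + diag(1e-12, ncol(V))))) %*%
          rnorm(ncol(Xo))
        pred <- X[miss[, j], , drop = FALSE] %*% bdraw
        x[miss[, j], j] <- pred + rnorm(sum(miss[, j]), 0, sqrt(sigma2))
      }
    }
    out[[imp]] <- x
  }
  attr(out, "excluded") <- excluded
  out
}

#' Shrinkage-regularized partial correlations
#'
#' Columns are standardized; the sample correlation matrix is shrunk toward
#' the identity with an analytically estimated intensity
#' (Schaefer-Strimmer: `lambda = sum Var(r_ij) / sum r_ij^2` over
#' off-diagonal entries, clipped to \[0, 1\]), inverted, and rescaled to
#' partial correlations `-omega_ij / sqrt(omega_ii omega_jj)`.
#'
#' @param mat completed samples x metabolites matrix (n >= 3).
#' @return symmetric partial-correlation matrix with unit diagonal;
#'   attribute `"lambda"` records the shrinkage intensity.
#' @export
partialCorrelations <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 3) stop("at least 3 samples required")
  x <- scale(mat)
  r <- crossprod(x) / (n - 1)
  p <- ncol(r)
  # Schaefer-Strimmer estimate of Var(r_ij): with w_kij = x_ki x_kj over
  # standardized columns, Var(r_ij) = n/(n-1)^3 * sum_k (w_kij - wbar_ij)^2
  W2 <- crossprod(x^2)
  varR <- (n / (n - 1)^3) * (W2 - ((n - 1)^2 / n) * r^2)
  off <- upper.tri(r)
  lambda <- sum(varR[off]) / sum(r[off]^2)
  lambda <- min(1, max(0, lambda))
  rs <- (1 - lambda) * r
  diag(rs) <- 1
  omega <- solve(rs)
  d <- 1 / sqrt(diag(omega))
  pc <- -omega * outer(d, d)
  diag(pc) <- 1
  pc <- (pc + t(pc)) / 2
  dimnames(pc) <- dimnames(r)
  attr(pc, "lambda") <- lambda
  pc
}

.fisherZ <- function(r) atanh(r)

#' Pool per-imputation partial correlations and meta-analyze across cohorts
#'
#' Per edge and cohort: each imputation's partial correlation is Fisher
#' z-transformed; Rubin's rules pool the `m` estimates (mean z; total
#' variance `T = W + (1 + 1/m) B`, with within-imputation variance
#' `W = 1/(n - k - 3)` for partial correlations of order `k` and `B` the
#' between-imputation variance). Cohort-level pooled z estimates are then
#' combined by fixed-effect inverse-variance weighting and back-transformed
#' with `tanh`.
#'
#' @param pcorsByCohort named list (one element per cohort) of lists of
#'   partial-correlation matrices (one per imputation, identical metabolite
#'   universe).
#' @param nByCohort named numeric vector of complete-sample sizes per
#'   cohort.
#' @return data.frame edge list: `met_a`, `met_b`, per-cohort pooled z and
#'   total variance columns, `z_meta`, `se_meta`, `r_meta`, `n_cohorts`,
#'   `flagged` (TRUE when an edge was available in fewer cohorts than
#'   supplied).
#' @export
poolRubinMeta <- function(pcorsByCohort, nByCohort) {
  cohorts <- names(pcorsByCohort)
  stopifnot(length(cohorts) >= 1, all(cohorts %in% names(nByCohort)))
  ref <- pcorsByCohort[[1]][[1]]
  mets <- colnames(ref)
  k <- length(mets) - 2  # order of the partial correlations
  idx <- which(upper.tri(ref), arr.ind = TRUE)
  edges <- data.frame(met_a = mets[idx[, 1]], met_b = mets[idx[, 2]],
                      stringsAsFactors = FALSE)
  zs <- vs <- matrix(NA_real_, nrow(edges), length(cohorts),
                     dimnames = list(NULL, cohorts))
  for (ch in cohorts) {
    mats <- pcorsByCohort[[ch]]
    m <- length(mats)
    zmat <- vapply(mats, function(pm) .fisherZ(pm[idx]), numeric(nrow(edges)))
    zmat <- matrix(zmat, nrow(edges), m)
    qbar <- rowMeans(zmat)
    W <- 1 / (nByCohort[[ch]] - k - 3)
    B <- if (m > 1) apply(zmat, 1, var) else 0
    Tt <- W + (1 + 1 / m) * B
    zs[, ch] <- qbar
    vs[, ch] <- Tt
    edges[[paste0("z_", ch)]] <- qbar
    edges[[paste0("T_", ch)]] <- Tt
  }
  w <- 1 / vs
  navail <- rowSums(!is.na(zs))
  zmeta <- rowSums(zs * w, na.rm = TRUE) / rowSums(w, na.rm = TRUE)
  semeta <- 1 / sqrt(rowSums(w, na.rm = TRUE))
  edges$z_meta <- zmeta
  edges$se_meta <- semeta
  edges$r_meta <- tanh(zmeta)
  edges$n_cohorts <- navail
  edges$flagged <- navail < length(cohorts)
  edges
}

#' Threshold the meta-analyzed edge list into a metabolic network
#'
#' Keeps edges with `|r| > cutoff` (strict inequality), retaining the sign
#' of the partial correlation; optional gene links (e.g. GIM causal genes)
#' are attached as a second edge type.
#'
#' @param edges edge list from [poolRubinMeta()].
#' @param cutoff absolute partial-correlation cutoff; conventional choices
#'   are 0.10, 0.12 and 0.15.
#' @param geneLinks optional data.frame `gene_id`, `metabolite_id`.
#' @return [igraph::graph] with vertex attribute `type`
#'   (`"metabolite"`/`"gene"`) and edge attributes `weight` (r), `sign`,
#'   `edge_type` (`"pcor"`/`"gene"`).
#' @export
thresholdNetwork <- function(edges, cutoff = 0.10, geneLinks = NULL) {
  keep <- edges[abs(edges$r_meta) > cutoff, , drop = FALSE]
  el <- data.frame(from = keep$met_a, to = keep$met_b,
                   weight = keep$r_meta, sign = sign(keep$r_meta),
                   edge_type = "pcor", stringsAsFactors = FALSE)
  verts <- data.frame(name = unique(c(edges$met_a, edges$met_b)),
                      type = "metabolite", stringsAsFactors = FALSE)
  if (!is.null(geneLinks) && nrow(geneLinks)) {
    gl <- data.frame(from = geneLinks$gene_id, to = geneLinks$metabolite_id,
                     weight = NA_real_, sign = NA_real_,
                     edge_type = "gene", stringsAsFactors = FALSE)
    el <- rbind(el, gl)
    verts <- rbind(verts,
                   data.frame(name = setdiff(unique(geneLinks$gene_id),
                                             verts$name),
                              type = "gene", stringsAsFactors = FALSE))
  }
  igraph::graph_from_data_frame(el, directed = FALSE, vertices = verts)
}

#' Write a network to GraphML
#'
#' @param graph an [igraph::graph] from [thresholdNetwork()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
exportGraphML <- function(graph, file) {
  igraph::write_graph(graph, file, format = "graphml")
  invisible(file)
}

#' Write an edge list to TSV
#'
#' @param edges edge list from [poolRubinMeta()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
exportEdgeList <- function(edges, file) {
  data.table::fwrite(edges, file, sep = "\t")
  invisible(file)
}
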
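#' Build a variant specification table
#'
#' @param chrom chromosome labels.
#' @param pos 1-based positions, strictly increasing within a chromosome.
#' @param maf minor allele frequency targets in (0, 0.5].
#' @param ref,alt allele labels (defaults "A"/"G").
#' @param id variant ids; default `chrom:pos:ref:alt`.
#' @return data.frame usable as the `variants` argument of
#'   [simulateGenotypes()].
#' @export
variantSpec <- function(chrom, pos, maf, ref = "A", alt = "G", id = NULL) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = ref, alt = alt, maf = maf,
                   stringsAsFactors = FALSE)
  if (is.null(id)) id <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  df$id <- id
  df[c("id", "chrom", "pos", "ref", "alt", "maf")]
}

.checkVariantSpec <- function(variants) {
  if (any(variants$maf <= 0))
    stop("maf_target must be > 0 (monomorphic variants unsupported)")
  if (any(variants$maf > 0.5))
    stop("maf_target must be <= 0.5")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0))
      stop("variant positions must be strictly increasing within a chromosome")
  }
  invisible(TRUE)
}

#' Simulate LD-structured hard-call genotype dosages
#'
#' Genotypes are generated from a latent Gaussian model: per haplotype, a
#' multivariate normal vector with correlation `exp(-ldDecay * distance)`
#' between variants on the same chromosome is thresholded at the standard
#' normal quantile of the target minor allele frequency; the two haplotype
#' calls are summed to a dosage in {0, 1, 2}. This yields Hardy-Weinberg
#' genotypes with a tunable allele-frequency spectrum and exponentially
#' distance-decaying LD, the two genotype properties the downstream pipeline
#' consumes.
#'
#' @param variants variant table from [variantSpec()] (sorted by position
#'   within chromosome).
#' @param nSamples number of samples (>= 2).
#' @param ldDecay per-base-pair decay rate of the latent correlation;
#'   `exp(-ldDecay * d)` at distance `d` bp. Default 1e-5 gives r2 ~ 0.6 at
#'   25 kb and near-zero beyond ~500 kb, a plausible European-ancestry decay.
#' @param seed integer seed; the function is a pure function of
#'   `(variants, nSamples, ldDecay, seed)`.
#' @return numeric matrix samples x variants with values in {0, 1, 2};
#'   column names are variant ids.
#' @export
simulateGenotypes <- function(variants, nSamples, ldDecay = 1e-5, seed = 1) {
  .checkVariantSpec(variants)
  if (nSamples < 2) stop("nSamples must be >= 2")
  set.seed(seed)
  p <- nrow(variants)
  out <- matrix(0L, nSamples, p, dimnames = list(NULL, variants$id))
  thr <- qnorm(1 - variants$maf)   # P(latent > thr) = maf
  for (ch in unique(variants$chrom)) {
    idx <- which(variants$chrom == ch)
    d <- abs(outer(variants$pos[idx], variants$pos[idx], "-"))
    R <- exp(-ldDecay * d)
    # ridge for numerical PD at near-duplicate positions
    L <- chol(R + diag(1e-10, length(idx)))
    for (hap in 1:2) {
      Z <- matrix(rnorm(nSamples * length(idx)), nSamples) %*% L
      out[, idx] <- out[, idx] +
        (Z > matrix(thr[idx], nSamples, length(idx), byrow = TRUE))
    }
  }
  storage.mode(out) <- "double"
  out
}

#' Simulate metabolite abundances with planted genetic effects
#'
#' On a standardized latent scale, each causal variant in `truth` contributes
#' `beta` per allele copy; Gaussian noise brings the latent variance to ~1,
#' covariate main effects are added on the log scale, and the latent is
#' exponentiated to a positive abundance scale. Entries are then set missing
#' completely at random at `missingRate` (a missing-at-random hook is exposed
#' via `missingProb`).
#'
#' @param dosageMat samples x variants dosage matrix (columns named by
#'   variant id).
#' @param truth a [TruthTable-class]; `causalEntries$beta` is on the
#'   standardized (s.d. per allele) scale.
#' @param covariates per-sample covariate data.frame; numeric columns get
#'   independent N(0, 0.1^2) coefficients on the log scale.
#' @param metaboliteIds metabolite ids to generate; default the union of ids
#'   in `truth` (at least one id required).
#' @param noiseSd if `NULL` (default), residual s.d. is
#'   `sqrt(1 - sum(var_explained))` per metabolite so the latent has unit
#'   variance; otherwise a fixed value.
#' @param missingRate MCAR missingness fraction in \[0, 1).
#' @param missingProb optional samples x metabolites matrix of per-entry
#'   missingness probabilities overriding `missingRate` (MAR hook).
#' @param seed integer seed.
#' @return samples x metabolites positive abundance matrix with NAs.
#' @export
simulateMetabolites <- function(dosageMat, truth, covariates = NULL,
                                metaboliteIds = NULL, noiseSd = NULL,
                                missingRate = 0, missingProb = NULL, seed = 1) {
  if (missingRate < 0 || missingRate >= 1) stop("missingRate must be in [0, 1)")
  ce <- causalEntries(truth)
  if (is.null(metaboliteIds)) metaboliteIds <- unique(ce$metabolite_id)
  if (!length(metaboliteIds)) stop("no metabolite ids to simulate")
  if (nrow(ce)) {
    tot <- tapply(ce$var_explained, ce$metabolite_id, sum)
    if (any(tot >= 1))
      stop("variance_explained targets sum to >= 1 for metabolite(s): ",
           paste(names(tot)[tot >= 1], collapse = ", "))
    if (!all(ce$variant_id %in% colnames(dosageMat)))
      stop("truth references variants absent from the dosage matrix")
  }
  # operation-specific stream offset: passing one master seed to the
  # genotype and metabolite generators must not reuse the same draws
  set.seed((seed + 104729L) %% .Machine$integer.max)
  n <- nrow(dosageMat)
  m <- length(metaboliteIds)
  lat <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, metaboliteIds))
  for (j in seq_len(m)) {
    rows <- ce[ce$metabolite_id == metaboliteIds[j], , drop = FALSE]
    ve <- if (nrow(rows)) sum(rows$var_explained) else 0
    s <- if (is.null(noiseSd)) sqrt(max(1 - ve, 0)) else noiseSd
    lat[, j] <- lat[, j] * s
    for (k in seq_len(nrow(rows)))
      lat[, j] <- lat[, j] + rows$beta[k] * dosageMat[, rows$variant_id[k]]
  }
  if (!is.null(covariates) && ncol(covariates)) {
    num <- vapply(covariates, is.numeric, logical(1))
    if (any(num)) {
      X <- scale(as.matrix(covariates[num]))
      X[is.na(X)] <- 0
      B <- matrix(rnorm(ncol(X) * m, sd = 0.1), ncol(X), m)
      lat <- lat + X %*% B
    }
  }
  ab <- exp(lat)
  if (!is.null(missingProb)) {
    ab[matrix(runif(n * m), n, m) < missingProb] <- NA
  } else if (missingRate > 0) {
    ab[matrix(runif(n * m), n, m) < missingRate] <- NA
  }
  ab
}

#' Simulate binary phecodes from metabolite liabilities
#'
#' Case status is drawn from a logistic model whose linear predictor is the
#' planted log-odds per s.d. of metabolite liability summed over the
#' metabolites affecting each phecode; the intercept is solved numerically so
#' the marginal prevalence matches `baselinePrevalence`.
#'
#' @param liabilities samples x metabolites matrix of standardized metabolite
#'   liabilities (columns named by metabolite id).
#' @param truth a [TruthTable-class] with `phecodeEffects`.
#' @param phecodeIds phecodes to generate; default those in `truth`.
#' @param baselinePrevalence marginal case prevalence in (0, 1).
#' @param seed integer seed.
#' @return integer 0/1 matrix samples x phecodes.
#' @export
simulatePhecodes <- function(liabilities, truth, phecodeIds = NULL,
                             baselinePrevalence = 0.1, seed = 1) {
  if (baselinePrevalence <= 0 || baselinePrevalence >= 1)
    stop("baselinePrevalence must be in (0, 1)")
  pe <- phecodeEffects(truth)
  if (is.null(phecodeIds))
    phecodeIds <- unique(pe$phecode_id)
  if (!length(phecodeIds)) stop("no phecode ids to simulate")
  set.seed((seed + 224737L) %% .Machine$integer.max)  # own stream (see simulateMetabolites)
  n <- nrow(liabilities)
  out <- matrix(0L, n, length(phecodeIds), dimnames = list(NULL, phecodeIds))
  for (j in seq_along(phecodeIds)) {
    rows <- pe[pe$phecode_id == phecodeIds[j], , drop = FALSE]
    eta <- rep(0, n)
    for (k in seq_len(nrow(rows)))
      eta <- eta + rows$log_odds[k] * liabilities[, rows$metabolite_id[k]]
    a <- uniroot(function(a) mean(plogis(a + eta)) - baselinePrevalence,
                 c(-30, 30))$root
    out[, j] <- rbinom(n, 1, plogis(a + eta))
  }
  out
}

#' Split a simulated population into discovery and validation cohorts
#'
#' Samples are partitioned into disjoint sets; each cohort gains a `batch`
#' covariate set to its cohort label.
#'
#' @param population a [CohortData-class] holding the full simulated
#'   population.
#' @param sizes integer vector of cohort sizes (sum <= population size).
#' @param cohortIds labels, default `discovery1`, `discovery2`, `validation`.
#' @param seed integer seed.
#' @return list of [CohortData-class] objects, one per size.
#' @export
splitCohorts <- function(population, sizes,
                         cohortIds = c("discovery1", "discovery2", "validation"),
                         seed = 1) {
  n <- nrow(dosages(population))
  if (sum(sizes) > n)
    stop("requested cohort sizes sum to ", sum(sizes),
         " but population has only ", n, " samples")
  if (length(cohortIds) < length(sizes))
    cohortIds <- paste0("cohort", seq_along(sizes))
  set.seed((seed + 48611L) %% .Machine$integer.max)  # own stream (see simulateMetabolites)
  perm <- sample.int(n)
  out <- vector("list", length(sizes))
  off <- 0L
  for (i in seq_along(sizes)) {
    idx <- sort(perm[(off + 1L):(off + sizes[i])])
    off <- off + sizes[i]
    cov <- covariates(population)[idx, , drop = FALSE]
    cov$batch <- cohortIds[i]
    rownames(cov) <- NULL
    out[[i]] <- CohortData(
      dosages = dosages(population)[idx, , drop = FALSE],
      variants = variantInfo(population),
      metabolites = metabolites(population)[idx, , drop = FALSE],
      covariates = cov,
      cohortId = cohortIds[i]
    )
  }
  names(out) <- cohortIds[seq_along(sizes)]
  out
}

#' Build a planted regional architecture for a simulated study
#'
#' Lays out `nRegions` well-separated loci on one chromosome; each locus
#' carries a block of variants in LD and 2-3 planted GIMs, each GIM being a
#' small set of causal variants affecting an exclusive set of metabolites at
#' controlled variance explained. Effect signs alternate; effect sizes are
#' derived from the variance-explained target as
#' `beta = sqrt(ve / (2 maf (1 - maf)))`.
#'
#' @param nRegions number of planted loci.
#' @param gimsPerRegion integer vector recycled over regions (default 2:3).
#' @param metabolitesPerGim metabolites affected by each planted GIM.
#' @param variantsPerGim causal variants per GIM.
#' @param proxiesPerRegion extra non-causal LD proxy variants per region.
#' @param varExplained per causal variant-metabolite variance explained.
#' @param mafRange range of minor allele frequencies for causal variants.
#' @param regionSpacing distance between locus anchors in bp (default 5 Mb,
#'   far beyond the LD decay length so loci are independent).
#' @param seed integer seed.
#' @return list with elements `variants` (variant spec table) and
#'   `truth` (a [TruthTable-class]).
#' @export
plantedArchitecture <- function(nRegions = 3, gimsPerRegion = c(2, 3),
                                metabolitesPerGim = 2, variantsPerGim = 1,
                                proxiesPerRegion = 6, varExplained = 0.02,
                                mafRange = c(0.05, 0.4),
                                regionSpacing = 5e6, seed = 1) {
  set.seed(seed)
  gimsPerRegion <- rep_len(gimsPerRegion, nRegions)
  rows <- list(); ce <- list(); pg <- list()
  metCounter <- 0L
  for (r in seq_len(nRegions)) {
    anchor <- r * regionSpacing
    nGims <- gimsPerRegion[r]
    proxiesPerGim <- ceiling(proxiesPerRegion / nGims)
    vsList <- list()
    gimVar <- vector("list", nGims)
    for (g in seq_len(nGims)) {
      # one 5 kb sub-block per GIM, blocks 40 kb apart: intra-block LD is
      # high while inter-block dosage r2 is negligible at the default decay
      blockAnchor <- anchor + (g - 1L) * 40000L
      nVar <- variantsPerGim + proxiesPerGim
      pos <- sort(blockAnchor + sample.int(5000L, nVar))
      maf <- runif(nVar, mafRange[1], mafRange[2])
      vb <- variantSpec(chrom = "1", pos = pos, maf = maf)
      vb$region_planted <- paste0("locus", r)
      gimVar[[g]] <- vb$id[sample.int(nVar, variantsPerGim)]
      vsList[[g]] <- vb
    }
    vs <- do.call(rbind, vsList)
    vs <- vs[order(vs$pos), , drop = FALSE]
    for (g in seq_len(nGims)) {
      gid <- sprintf("gim_r%d_%d", r, g)
      mids <- sprintf("met%03d", metCounter + seq_len(metabolitesPerGim))
      metCounter <- metCounter + metabolitesPerGim
      for (v in gimVar[[g]]) {
        mafv <- vs$maf[vs$id == v]
        beta <- sqrt(varExplained / (2 * mafv * (1 - mafv)))
        for (i in seq_along(mids)) {
          sign <- if (i %% 2 == 0) -1 else 1
          ce[[length(ce) + 1L]] <- data.frame(
            variant_id = v, metabolite_id = mids[i],
            beta = sign * beta, var_explained = varExplained)
        }
        pg[[length(pg) + 1L]] <- data.frame(
          region_id = paste0("locus", r), gim_id = gid,
          variant_id = v, metabolite_id = mids)
      }
    }
    rows[[r]] <- vs
  }
  variants <- do.call(rbind, rows)
  list(variants = variants,
       truth = TruthTable(causalEntries = do.call(rbind, ce),
                          plantedGims = do.call(rbind, pg)))
}

#' Simulate a complete two-cohort discovery study plus validation cohort
#'
#' Convenience wrapper tying together [plantedArchitecture()],
#' [simulateGenotypes()], [simulateMetabolites()] and [splitCohorts()]. The
#' default cohort sizes (8455 / 5841 discovery, 5698 validation) reproduce a
#' two-cohort discovery design with an additional validation cohort; scale
#' them down for quick experiments.
#'
#' @param sizes cohort sizes `(discovery1, discovery2, validation)`.
#' @param architecture result of [plantedArchitecture()]; built with defaults
#'   when `NULL`.
#' @param ldDecay,missingRate passed to the generators.
#' @param seed integer master seed (sub-seeds are derived deterministically).
#' @param ... passed to [plantedArchitecture()] when `architecture` is NULL.
#' @return list with `cohorts` (list of three [CohortData-class]),
#'   `truth`, `variants`.
#' @export
simulateStudy <- function(sizes = c(8455, 5841, 5698), architecture = NULL,
                          ldDecay = 1e-4, missingRate = 0.05, seed = 1, ...) {
  if (is.null(architecture))
    architecture <- plantedArchitecture(seed = seed, ...)
  variants <- architecture$variants
  truth <- architecture$truth
  n <- sum(sizes)
  g <- simulateGenotypes(variants, n, ldDecay = ldDecay, seed = seed)
  covs <- local({
    set.seed(seed + 11L)
    data.frame(age = round(rnorm(n, 55, 8)), sex = rbinom(n, 1, 0.5))
  })
  met <- simulateMetabolites(g, truth, covariates = covs,
                             missingRate = missingRate, seed = seed + 23L)
  pop <- CohortData(g, variants, met, covs, "population")
  cohorts <- splitCohorts(pop, sizes, seed = seed + 31L)
  list(cohorts = cohorts, truth = truth, variants = variants)
}
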
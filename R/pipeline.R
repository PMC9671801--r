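#' Run the discovery pipeline: preprocessing to GIMs
#'
#' Ties the modules together for a two-cohort discovery design: per-cohort
#' metabolite preprocessing, per-cohort marginal association, fixed-effect
#' meta-analysis, candidate filtering, LD-based region definition, exact
#' stepwise conditional analysis per (region, metabolite) on the pooled
#' individual-level data (with a cohort fixed effect), GIM selection and
#' clustering per region, an optional adjacent-region merge pass, and
#' variance-explained partitioning per metabolite.
#'
#' @param cohorts list of two discovery [CohortData-class] objects.
#' @param minN preprocessing inclusion threshold (passed to
#'   [preprocessMetabolites()]); choose relative to cohort size.
#' @param pMeta,pCohort,macMin candidate filter settings (defaults 5e-8,
#'   0.01, 10).
#' @param condThreshold conditional threshold (default
#'   [conditionalThreshold()]).
#' @param gimThreshold GIM selection/stop threshold (default 5e-8).
#' @param ldReference index of the LD reference cohort (default the larger
#'   cohort).
#' @param mergeAdjacent logical: run the adjacent-region merge pass
#'   (default TRUE).
#' @param gapMax adjacency rule for the merge pass (default 1e6 bp).
#' @return list with elements `prepared` (per cohort), `records`
#'   (per-cohort associations), `meta`, `candidates`, `regions` (GRanges),
#'   `conditional` (data.frame of retained variants per region x
#'   metabolite), `gims` (named list by region), `gimMatrices`,
#'   `variance` (named list of `VarianceReport` by metabolite), `pooled`
#'   (the pooled matrices used for conditioning).
#' @export
runDiscoveryPipeline <- function(cohorts, minN = 200, pMeta = 5e-8,
                                 pCohort = 0.01, macMin = 10,
                                 condThreshold = conditionalThreshold(),
                                 gimThreshold = 5e-8, ldReference = NULL,
                                 mergeAdjacent = TRUE, gapMax = 1e6) {
  stopifnot(length(cohorts) >= 2)
  prepared <- lapply(cohorts, function(ch)
    preprocessMetabolites(metabolites(ch), covariates(ch), minN = minN))
  records <- do.call(rbind, lapply(seq_along(cohorts), function(i)
    marginalAssoc(cohorts[[i]], prepared[[i]])))
  meta <- ivwMeta(records, macMin = macMin)
  candidates <- candidateFilter(meta, records, pMeta = pMeta,
                                pCohort = pCohort, macMin = macMin)
  vinfo <- variantInfo(cohorts[[1]])
  empty <- list(prepared = prepared, records = records, meta = meta,
                candidates = candidates, regions = GRanges(),
                conditional = NULL, gims = list(), gimMatrices = list(),
                variance = list(), pooled = NULL)
  if (!nrow(candidates)) return(empty)
  candidates <- merge(candidates, vinfo[c("id", "chrom", "pos", "ref", "alt")],
                      by.x = "variant_id", by.y = "id")
  if (is.null(ldReference))
    ldReference <- which.max(vapply(cohorts, function(ch)
      nrow(dosages(ch)), numeric(1)))
  ld <- ldR2(dosages(cohorts[[ldReference]]), unique(candidates$variant_id))

  # per-metabolite intervals, then global merge
  intervals <- do.call(rbind, lapply(split(candidates,
                                           candidates$metabolite_id),
                                     function(cc) {
    cc$pval <- cc$pval_meta
    metaboliteRegions(cc, ld)
  }))
  regions <- mergeRegions(intervals, ld)
  candidates <- assignToRegions(candidates, regions)

  # pooled individual-level data (common metabolites)
  commonMets <- Reduce(intersect, lapply(prepared, function(p)
    colnames(residualMatrix(p))))
  Ypool <- do.call(rbind, lapply(prepared, function(p)
    residualMatrix(p)[, commonMets, drop = FALSE]))
  Gpool <- do.call(rbind, lapply(cohorts, dosages))
  cohortVec <- rep(vapply(cohorts, cohortId, character(1)),
                   vapply(cohorts, function(ch) nrow(dosages(ch)), numeric(1)))
  mafMeta <- colMeans(Gpool) / 2
  mafMeta <- pmin(mafMeta, 1 - mafMeta)

  runRegion <- function(chrom, lo, hi, regionId) {
    cc <- candidates[candidates$chrom == chrom & candidates$pos >= lo &
                       candidates$pos <= hi, , drop = FALSE]
    mets <- intersect(unique(cc$metabolite_id), commonMets)
    condRows <- list()
    retainedByMet <- list()
    for (met in mets) {
      vids <- unique(cc$variant_id[cc$metabolite_id == met])
      model <- stepwiseConditional(Ypool[, met], Gpool[, vids, drop = FALSE],
                                   cohort = cohortVec,
                                   threshold = condThreshold,
                                   cohortP = pCohort)
      if (!nrow(model$selected)) {
        # fallback path: nothing reaches the conditional threshold, retain
        # the lead variant (smallest marginal conditional P) alone
        scan <- .condScan(Ypool[!is.na(Ypool[, met]), met],
                          .condDesign(sum(!is.na(Ypool[, met])),
                                      cohortVec[!is.na(Ypool[, met])], NULL),
                          Gpool[!is.na(Ypool[, met]), vids, drop = FALSE])
        lead <- scan$variant_id[which.min(scan$pval)]
        model$selected <- data.frame(variant_id = lead, step = 1L,
                                     beta_cond = scan$beta[which.min(scan$pval)],
                                     se_cond = scan$se[which.min(scan$pval)],
                                     pval_cond = min(scan$pval, na.rm = TRUE))
        model <- finalJoint(model, Ypool[, met], Gpool[, vids, drop = FALSE],
                            cohort = cohortVec, threshold = condThreshold)
        model$fallback <- TRUE
      } else {
        model <- finalJoint(model, Ypool[, met], Gpool[, vids, drop = FALSE],
                            cohort = cohortVec, threshold = condThreshold)
      }
      if (nrow(model$joint)) {
        retainedByMet[[met]] <- model$joint$variant_id
        condRows[[met]] <- cbind(region_id = regionId, metabolite_id = met,
                                 merge(model$selected, model$joint,
                                       by = "variant_id"),
                                 fallback = model$fallback)
      }
    }
    uni <- unique(unlist(retainedByMet))
    gm <- NULL; gims <- list()
    if (length(uni) && length(mets)) {
      gm <- gimSelect(Ypool[, mets, drop = FALSE],
                      Gpool[, uni, drop = FALSE], cohort = cohortVec,
                      stopThreshold = gimThreshold, cohortP = pCohort)
      gims <- clusterGims(gm, regionId = regionId)
    }
    list(conditional = if (length(condRows)) do.call(rbind, condRows) else NULL,
         gimMatrix = gm, gims = gims)
  }

  condAll <- list(); gimsByRegion <- list(); gmByRegion <- list()
  for (k in seq_along(regions)) {
    rid <- mcols(regions)$region_id[k]
    res <- runRegion(as.character(seqnames(regions))[k],
                     start(regions)[k], end(regions)[k], rid)
    condAll[[rid]] <- res$conditional
    gimsByRegion[[rid]] <- res$gims
    gmByRegion[[rid]] <- res$gimMatrix
  }

  if (mergeAdjacent && length(regions) > 1) {
    recompute <- function(chrom, lo, hi, rid) {
      res <- runRegion(chrom, lo, hi, rid)
      condAll[[rid]] <<- res$conditional
      gmByRegion[[rid]] <<- res$gimMatrix
      res$gims
    }
    ma <- mergeAdjacentRegions(regions, gimsByRegion, recompute,
                               gapMax = gapMax)
    oldIds <- mcols(regions)$region_id
    regions <- ma$regions
    gimsByRegion <- ma$gims
    gone <- setdiff(oldIds, mcols(regions)$region_id)
    condAll[gone] <- NULL
    gmByRegion[gone] <- NULL
  }

  conditional <- if (length(condAll)) do.call(rbind, c(condAll,
                                                       make.row.names = FALSE))
  else NULL

  variance <- list()
  if (!is.null(conditional) && nrow(conditional)) {
    for (met in unique(conditional$metabolite_id)) {
      vids <- unique(conditional$variant_id[conditional$metabolite_id == met])
      variance[[met]] <- variancePartition(Ypool[, met],
                                           Gpool[, vids, drop = FALSE],
                                           mafMeta[vids])
    }
  }

  list(prepared = prepared, records = records, meta = meta,
       candidates = candidates, regions = regions, conditional = conditional,
       gims = gimsByRegion, gimMatrices = gmByRegion, variance = variance,
       pooled = list(Y = Ypool, G = Gpool, cohort = cohortVec,
                     maf = mafMeta))
}
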
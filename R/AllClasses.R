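#' @import methods
#' @importFrom stats coef complete.cases cor lm glm pchisq pf pnorm pt qlogis
#'   qnorm quantile rbinom rnorm runif sd setNames var p.adjust dbinom
#'   binom.test plogis uniroot anova as.formula rchisq
#' @importFrom utils head tail
NULL

#' CohortData: aligned genotypes, metabolites and covariates for one cohort
#'
#' Container holding, for a single cohort, the sample x variant dosage matrix
#' (values in \[0, 2\]), the sample x metabolite raw abundance matrix (positive
#' scale, possibly with missing entries), a covariate table and per-variant
#' metadata. All three sample-indexed tables must agree on row count and
#' sample ordering.
#'
#' @slot dosages numeric matrix, samples x variants, allele dosages in \[0, 2\].
#' @slot variants data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`,
#'   `maf` (one row per dosage column, same order).
#' @slot metabolites numeric matrix, samples x metabolites, raw abundances.
#' @slot covariates data.frame of per-sample covariates (e.g. age, sex, batch).
#' @slot cohortId single character label.
#'
#' @exportClass CohortData
setClass("CohortData",
  representation(
    dosages     = "matrix",
    variants    = "data.frame",
    metabolites = "matrix",
    covariates  = "data.frame",
    cohortId    = "character"
  )
)

setValidity("CohortData", function(object) {
  msg <- character(0)
  n <- nrow(object@dosages)
  if (nrow(object@metabolites) != n)
    msg <- c(msg, "metabolites and dosages disagree on sample count")
  if (nrow(object@covariates) != n)
    msg <- c(msg, "covariates and dosages disagree on sample count")
  if (nrow(object@variants) != ncol(object@dosages))
    msg <- c(msg, "variant table must have one row per dosage column")
  need <- c("id", "chrom", "pos", "ref", "alt", "maf")
  if (!all(need %in% names(object@variants)))
    msg <- c(msg, paste("variant table missing columns:",
                        paste(setdiff(need, names(object@variants)), collapse = ", ")))
  if (length(object@cohortId) != 1L)
    msg <- c(msg, "cohortId must be a single string")
  d <- object@dosages
  if (length(d) && (min(d, na.rm = TRUE) < 0 || max(d, na.rm = TRUE) > 2))
    msg <- c(msg, "dosages must lie in [0, 2]")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortData object
#'
#' @param dosages samples x variants dosage matrix.
#' @param variants variant metadata data.frame (`id`, `chrom`, `pos`, `ref`,
#'   `alt`, `maf`).
#' @param metabolites samples x metabolites raw abundance matrix.
#' @param covariates per-sample covariate data.frame.
#' @param cohortId cohort label.
#' @return A [CohortData-class] object.
#' @export
CohortData <- function(dosages, variants, metabolites, covariates, cohortId) {
  dosages <- as.matrix(dosages)
  metabolites <- as.matrix(metabolites)
  if (is.null(colnames(dosages))) colnames(dosages) <- variants$id
  new("CohortData", dosages = dosages, variants = as.data.frame(variants),
      metabolites = metabolites, covariates = as.data.frame(covariates),
      cohortId = as.character(cohortId))
}

#' @describeIn CohortData-class number of samples
#' @param x,object a `CohortData` object
#' @export
setMethod("nrow", "CohortData", function(x) nrow(x@dosages))

#' Accessors for CohortData
#'
#' `dosages()`, `variantInfo()`, `metabolites()`, `covariates()` and
#' `cohortId()` extract the corresponding slots.
#'
#' @param x a [CohortData-class] object.
#' @return the slot contents.
#' @name CohortData-accessors
NULL

#' @rdname CohortData-accessors
#' @export
dosages <- function(x) x@dosages

#' @rdname CohortData-accessors
#' @export
variantInfo <- function(x) x@variants

#' @rdname CohortData-accessors
#' @export
metabolites <- function(x) x@metabolites

#' @rdname CohortData-accessors
#' @export
covariates <- function(x) x@covariates

#' @rdname CohortData-accessors
#' @export
cohortId <- function(x) x@cohortId

setMethod("show", "CohortData", function(object) {
  cat("CohortData '", object@cohortId, "': ",
      nrow(object@dosages), " samples, ",
      ncol(object@dosages), " variants, ",
      ncol(object@metabolites), " metabolites, ",
      ncol(object@covariates), " covariates\n", sep = "")
})

#' TruthTable: planted simulation architecture
#'
#' Records the generative truth of a simulated study: which variants causally
#' affect which metabolites (effect size on the standardized scale and target
#' variance explained), the planted region/GIM structure, and planted
#' metabolite -> phecode effects. Used downstream as the recovery oracle.
#'
#' @slot causalEntries data.frame: `variant_id`, `metabolite_id`, `beta`
#'   (s.d. per allele), `var_explained` (fraction of metabolite variance).
#' @slot plantedGims data.frame: `region_id`, `gim_id`, `variant_id`,
#'   `metabolite_id` (long format; one row per planted variant-metabolite pair).
#' @slot phecodeEffects data.frame: `metabolite_id`, `phecode_id`,
#'   `log_odds` per s.d. of metabolite liability.
#'
#' @exportClass TruthTable
setClass("TruthTable",
  representation(
    causalEntries  = "data.frame",
    plantedGims    = "data.frame",
    phecodeEffects = "data.frame"
  )
)

setValidity("TruthTable", function(object) {
  msg <- character(0)
  ce <- object@causalEntries
  if (nrow(ce)) {
    need <- c("variant_id", "metabolite_id", "beta", "var_explained")
    if (!all(need %in% names(ce)))
      msg <- c(msg, "causalEntries missing required columns")
    else {
      tot <- tapply(ce$var_explained, ce$metabolite_id, sum)
      if (any(tot >= 1))
        msg <- c(msg, "summed variance_explained targets must be < 1 per metabolite")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TruthTable
#'
#' @param causalEntries,plantedGims,phecodeEffects see [TruthTable-class].
#' @return A [TruthTable-class] object.
#' @export
TruthTable <- function(causalEntries = data.frame(),
                       plantedGims = data.frame(),
                       phecodeEffects = data.frame()) {
  new("TruthTable", causalEntries = as.data.frame(causalEntries),
      plantedGims = as.data.frame(plantedGims),
      phecodeEffects = as.data.frame(phecodeEffects))
}

#' @rdname TruthTable-class
#' @param x a `TruthTable`
#' @export
causalEntries <- function(x) x@causalEntries

#' @rdname TruthTable-class
#' @export
plantedGims <- function(x) x@plantedGims

#' @rdname TruthTable-class
#' @export
phecodeEffects <- function(x) x@phecodeEffects

setMethod("show", "TruthTable", function(object) {
  cat("TruthTable: ", nrow(object@causalEntries), " causal variant-metabolite entries, ",
      length(unique(object@plantedGims$gim_id)), " planted GIMs, ",
      nrow(object@phecodeEffects), " phecode effects\n", sep = "")
})

#' PreparedMetabolites: analysis-ready metabolite residuals
#'
#' Result of [preprocessMetabolites()]: per metabolite, natural-log
#' transformed, winsorized, covariate-residualized and standardized values
#' (mean 0, s.d. 1 over non-missing entries), plus the inclusion mask and a
#' per-metabolite provenance record of winsorized counts.
#'
#' @slot residuals samples x metabolites matrix of standardized residuals
#'   (NA where the raw value was missing).
#' @slot inclusionMask named logical; TRUE for metabolites retained.
#' @slot provenance data.frame: `metabolite_id`, `n_obs`, `n_winsorized`.
#'
#' @exportClass PreparedMetabolites
setClass("PreparedMetabolites",
  representation(
    residuals     = "matrix",
    inclusionMask = "logical",
    provenance    = "data.frame"
  )
)

setValidity("PreparedMetabolites", function(object) {
  r <- object@residuals
  for (j in seq_len(ncol(r))) {
    v <- r[, j][!is.na(r[, j])]
    if (length(v) > 1) {
      if (abs(mean(v)) > 1e-8) return(sprintf("column %d mean not 0", j))
      if (abs(sd(v) - 1) > 1e-8) return(sprintf("column %d s.d. not 1", j))
    }
  }
  TRUE
})

#' @rdname PreparedMetabolites-class
#' @param x a `PreparedMetabolites`
#' @export
residualMatrix <- function(x) x@residuals

#' @rdname PreparedMetabolites-class
#' @export
inclusionMask <- function(x) x@inclusionMask

#' @rdname PreparedMetabolites-class
#' @export
provenance <- function(x) x@provenance

setMethod("show", "PreparedMetabolites", function(object) {
  cat("PreparedMetabolites: ", nrow(object@residuals), " samples x ",
      ncol(object@residuals), " retained metabolites (",
      sum(!object@inclusionMask), " dropped)\n", sep = "")
})
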
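#' Write a simulated cohort to flat files
#'
#' Writes the dosage matrix, variant map (chrom, pos, ref, alt, MAF),
#' metabolite matrix and covariates as TSV into `dir`.
#'
#' @param cohort a [CohortData-class].
#' @param dir output directory (created if needed).
#' @return vector of file paths, invisibly.
#' @export
writeCohortTSV <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- cohortId(cohort)
  paths <- c(
    dosages = file.path(dir, paste0(id, "_dosages.tsv")),
    variants = file.path(dir, paste0(id, "_variants.tsv")),
    metabolites = file.path(dir, paste0(id, "_metabolites.tsv")),
    covariates = file.path(dir, paste0(id, "_covariates.tsv")))
  data.table::fwrite(as.data.frame(dosages(cohort)), paths["dosages"], sep = "\t")
  data.table::fwrite(variantInfo(cohort), paths["variants"], sep = "\t")
  data.table::fwrite(as.data.frame(metabolites(cohort)), paths["metabolites"], sep = "\t")
  data.table::fwrite(covariates(cohort), paths["covariates"], sep = "\t")
  invisible(paths)
}

#' Write summary statistics to TSV
#'
#' @param meta meta-analysis table from [ivwMeta()] (optionally merged with
#'   variant metadata).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeSummaryStats <- function(meta, file) {
  data.table::fwrite(meta, file, sep = "\t")
  invisible(file)
}

#' Write conditional-model results to TSV
#'
#' @param conditional the `conditional` element of
#'   [runDiscoveryPipeline()]'s result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeConditionalTSV <- function(conditional, file) {
  data.table::fwrite(conditional, file, sep = "\t")
  invisible(file)
}

#' Write GIM membership to TSV
#'
#' One row per (GIM, variant, metabolite) triple.
#'
#' @param gimsByRegion named list of GIM lists (`gims` element of the
#'   pipeline result).
#' @param file output path.
#' @return the membership data.frame, invisibly.
#' @export
writeGimTSV <- function(gimsByRegion, file) {
  rows <- list()
  for (rid in names(gimsByRegion)) for (g in gimsByRegion[[rid]]) {
    rows[[length(rows) + 1L]] <- expand.grid(
      gim_id = g$id, region_id = rid,
      variant_id = g$variants$variant_id,
      metabolite_id = g$metabolites, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gim_id = character(0), region_id = character(0),
               variant_id = character(0), metabolite_id = character(0))
  data.table::fwrite(out, file, sep = "\t")
  invisible(out)
}
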
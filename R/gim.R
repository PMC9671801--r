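#' Greedy conditional selection of the minimal regional variant set
#'
#' Implements the matrix.ref / matrix.out algorithm for one region. Rows of
#' matrix.ref are the union of conditionally independent variants over all
#' regional metabolites; columns are the regional metabolites; entries are
#' -log10(P) for the conditional association of each variant with each
#' metabolite, conditioning on the variants already moved to matrix.out.
#' The largest entry is selected (provided the same variant-metabolite
#' association has a consistent direction of effect with P < `cohortP` in
#' both discovery cohorts; failing pairs are masked and the next-largest
#' considered), the variant moves to matrix.out with the next marker order,
#' all matrix.ref entries are recomputed by exact refitting, and the loop
#' stops when no entry exceeds -log10(`stopThreshold`).
#'
#' Each matrix.out row stores the signed -log10(P) of that variant with
#' every regional metabolite conditional on only the variants with lower
#' marker order (sign = direction of the conditional effect).
#'
#' @param Y pooled samples x regional-metabolites matrix of standardized
#'   residuals.
#' @param G pooled samples x regional-variants dosage matrix (the row
#'   universe of matrix.ref).
#' @param cohort cohort labels for the pooled rows.
#' @param covariates optional extra covariates.
#' @param stopThreshold selection stop threshold (default 5e-8).
#' @param cohortP per-cohort consistency threshold (default 0.01).
#' @return list of class `GimMatrix`: `out_matrix` (selected variants x
#'   metabolites, signed -log10 P, rows in marker order), `marker_order`
#'   named integer vector, `threshold`.
#' @export
gimSelect <- function(Y, G, cohort = NULL, covariates = NULL,
                      stopThreshold = 5e-8, cohortP = 0.01) {
  Y <- as.matrix(Y); G <- as.matrix(G)
  mets <- colnames(Y)
  nl10stop <- -log10(stopThreshold)
  checkCohorts <- !is.null(cohort) && length(unique(cohort)) > 1
  out <- character(0)
  outRows <- list()
  remaining <- colnames(G)
  repeat {
    if (!length(remaining)) break
    # matrix.ref: conditional scan per metabolite (complete-case per column)
    refP <- matrix(NA_real_, length(remaining), length(mets),
                   dimnames = list(remaining, mets))
    refB <- refP
    for (m in seq_along(mets)) {
      keep <- !is.na(Y[, m])
      X <- .condDesign(sum(keep), if (is.null(cohort)) NULL else cohort[keep],
                       if (is.null(covariates)) NULL else
                         as.data.frame(covariates)[keep, , drop = FALSE])
      X <- cbind(X, G[keep, out, drop = FALSE])
      sc <- .condScan(Y[keep, m], X, G[keep, remaining, drop = FALSE])
      refP[, m] <- sc$pval
      refB[, m] <- sc$beta
    }
    masked <- matrix(FALSE, nrow(refP), ncol(refP))
    pick <- NULL
    repeat {
      pv <- refP
      pv[masked] <- NA
      if (all(is.na(pv)) || min(pv, na.rm = TRUE) >= stopThreshold) break
      ij <- which(pv == min(pv, na.rm = TRUE), arr.ind = TRUE)[1, ]
      v <- remaining[ij[1]]; m <- mets[ij[2]]
      if (checkCohorts && !.cohortConsistent(
        Y[, m], NULL, G, out, v, cohort, covariates, cohortP)) {
        masked[ij[1], ij[2]] <- TRUE
        next
      }
      pick <- v
      break
    }
    if (is.null(pick)) break
    i <- match(pick, remaining)
    outRows[[pick]] <- setNames(sign(refB[i, ]) * (-log10(refP[i, ])), mets)
    out <- c(out, pick)
    remaining <- setdiff(remaining, pick)
  }
  om <- if (length(outRows))
    do.call(rbind, outRows) else
      matrix(numeric(0), 0, length(mets), dimnames = list(NULL, mets))
  structure(list(out_matrix = om,
                 marker_order = setNames(seq_along(out), out),
                 threshold = stopThreshold),
            class = "GimMatrix")
}

#' Cluster a region's matrix.out into genetically influenced metabotypes
#'
#' Builds the bipartite graph of significant variant-metabolite pairs
#' (|signed -log10 P| > -log10(`threshold`)) and returns its connected
#' components, enumerated seeded by ascending marker order.
#'
#' @param gimMatrix a `GimMatrix` from [gimSelect()].
#' @param threshold significance threshold for graph edges (default the
#'   matrix's own stop threshold).
#' @param regionId optional region label attached to each GIM.
#' @return list of `GIM` objects: each a list with `id`, `region_id`,
#'   `variants` (data.frame `variant_id`, `marker_order`), `metabolites`,
#'   and the signed -log10 P `submatrix`.
#' @export
clusterGims <- function(gimMatrix, threshold = gimMatrix$threshold,
                        regionId = NA_character_) {
  om <- gimMatrix$out_matrix
  if (!nrow(om)) return(list())
  sig <- abs(om) > -log10(threshold)
  sig[is.na(sig)] <- FALSE
  pairs <- which(sig, arr.ind = TRUE)
  if (!nrow(pairs)) return(list())
  vn <- rownames(om)[pairs[, 1]]
  mn <- paste0("met::", colnames(om)[pairs[, 2]])
  g <- igraph::graph_from_data_frame(data.frame(from = vn, to = mn),
                                     directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership
  gims <- list()
  for (k in seq_len(comp$no)) {
    nodes <- names(memb)[memb == k]
    vs <- nodes[!startsWith(nodes, "met::")]
    ms <- sub("^met::", "", nodes[startsWith(nodes, "met::")])
    ord <- gimMatrix$marker_order[vs]
    gims[[k]] <- list(
      region_id = regionId,
      variants = data.frame(variant_id = vs[order(ord)],
                            marker_order = unname(sort(ord))),
      metabolites = sort(ms),
      submatrix = om[vs[order(ord)], ms, drop = FALSE],
      seed_order = min(ord))
  }
  gims <- gims[order(vapply(gims, `[[`, numeric(1), "seed_order"))]
  for (k in seq_along(gims)) {
    gims[[k]]$id <- if (is.na(regionId)) sprintf("GIM%d", k) else
      sprintf("%s_GIM%d", regionId, k)
    gims[[k]]$seed_order <- NULL
    class(gims[[k]]) <- "GIM"
  }
  gims
}

#' @export
print.GIM <- function(x, ...) {
  cat("GIM", x$id, ":", nrow(x$variants), "variant(s) x",
      length(x$metabolites), "metabolite(s)\n")
  invisible(x)
}

#' Merge adjacent regions sharing associated metabolites and recompute GIMs
#'
#' Consecutive same-chromosome regions whose gap is at most `gapMax` and
#' that share at least one significantly associated metabolite are merged;
#' GIMs are recomputed on the merged region via the supplied `recompute`
#' callback (which must rerun conditional selection and clustering on the
#' pooled data for a given interval). The process iterates to a fixpoint.
#'
#' @param regions [GenomicRanges::GRanges] of final regions with
#'   `region_id` metadata.
#' @param gimsByRegion named list (by region_id) of GIM lists, as returned
#'   by [clusterGims()].
#' @param recompute function(chrom, start, end, region_id) returning the
#'   GIM list for that interval.
#' @param gapMax maximum bp gap between region end and next region start to
#'   count as adjacent (default 1e6).
#' @return list with updated `regions` (GRanges) and `gims` (named list).
#' @export
mergeAdjacentRegions <- function(regions, gimsByRegion, recompute,
                                 gapMax = 1e6) {
  regionMets <- function(rid) {
    unique(unlist(lapply(gimsByRegion[[rid]], `[[`, "metabolites")))
  }
  repeat {
    if (length(regions) < 2) break
    ord <- order(as.character(seqnames(regions)), start(regions))
    regions <- regions[ord]
    mergedAny <- FALSE
    for (i in seq_len(length(regions) - 1)) {
      r1 <- regions[i]; r2 <- regions[i + 1]
      if (as.character(seqnames(r1)) != as.character(seqnames(r2))) next
      gap <- start(r2) - end(r1) - 1L
      if (gap > gapMax) next
      id1 <- mcols(r1)$region_id; id2 <- mcols(r2)$region_id
      if (!length(intersect(regionMets(id1), regionMets(id2)))) next
      newId <- paste0(id1, "+", id2)
      merged <- GRanges(seqnames(r1), IRanges(start(r1), end(r2)))
      mcols(merged)$region_id <- newId
      mcols(merged)$sentinels <- paste(mcols(r1)$sentinels,
                                       mcols(r2)$sentinels, sep = ",")
      gimsByRegion[[id1]] <- NULL
      gimsByRegion[[id2]] <- NULL
      gimsByRegion[[newId]] <- recompute(as.character(seqnames(merged)),
                                         start(merged), end(merged), newId)
      regions <- c(regions[-c(i, i + 1)], merged)
      mergedAny <- TRUE
      break
    }
    if (!mergedAny) break
  }
  ord <- order(as.character(seqnames(regions)), start(regions))
  list(regions = regions[ord], gims = gimsByRegion)
}

#' Export a region's signed -log10 P matrix for display
#'
#' Values are capped at `cap` in magnitude for display only (the underlying
#' matrix is not modified elsewhere).
#'
#' @param gimMatrix a `GimMatrix`.
#' @param cap display cap (default 50).
#' @return metabolites x variants matrix (transposed display layout).
#' @export
gimDisplayMatrix <- function(gimMatrix, cap = 50) {
  om <- gimMatrix$out_matrix
  t(pmin(pmax(om, -cap), cap))
}
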
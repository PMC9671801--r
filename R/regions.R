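#' @importFrom GenomicRanges GRanges reduce findOverlaps start end seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
NULL

# deterministic ordering of candidates: largest -log10 P first, ties broken
# by smaller position, then lexicographic alleles
.orderCandidates <- function(cand) {
  order(cand$pval, cand$pos, cand$ref, cand$alt)
}

#' Per-metabolite LD-defined association intervals
#'
#' Iteratively peels sentinels from one metabolite's candidate associations:
#' the remaining candidate with the largest -log10(P) becomes a sentinel and
#' its interval spans the minimum to maximum position of candidates in LD
#' with it (`r2 >= r2Partner`, same chromosome); a sentinel without any LD
#' partner gets `sentinel +/- flank` bp. Covered candidates (those inside
#' the interval on the same chromosome) are removed and the process repeats
#' until no candidate remains.
#'
#' @param candidates data.frame for one metabolite with `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `pval` (meta-analysis P).
#' @param ld symmetric r-squared matrix covering all candidate variants.
#' @param r2Partner LD threshold for interval definition (default 0.1).
#' @param flank fallback half-width in bp for isolated sentinels
#'   (default 5e5).
#' @return data.frame of intervals: `chrom`, `start`, `end` (1-based,
#'   closed), `sentinel_id`, `sentinel_pval`, `metabolite_id`.
#' @export
metaboliteRegions <- function(candidates, ld, r2Partner = 0.1, flank = 5e5) {
  cand <- as.data.frame(candidates)
  if (!all(cand$variant_id %in% rownames(ld)))
    stop("candidate variant(s) absent from the LD matrix: ",
         paste(setdiff(cand$variant_id, rownames(ld)), collapse = ", "))
  met <- if ("metabolite_id" %in% names(cand)) cand$metabolite_id[1] else NA_character_
  out <- list()
  while (nrow(cand)) {
    cand <- cand[.orderCandidates(cand), , drop = FALSE]
    s <- cand[1, ]
    r2 <- ld[s$variant_id, cand$variant_id]
    partners <- cand$variant_id[r2 >= r2Partner & cand$chrom == s$chrom &
                                  cand$variant_id != s$variant_id]
    if (length(partners)) {
      pos <- cand$pos[cand$variant_id %in% c(s$variant_id, partners)]
      lo <- min(pos); hi <- max(pos)
    } else {
      lo <- s$pos - flank; hi <- s$pos + flank
    }
    lo <- max(1, lo)
    out[[length(out) + 1L]] <- data.frame(
      chrom = s$chrom, start = lo, end = hi,
      sentinel_id = s$variant_id, sentinel_pval = s$pval,
      metabolite_id = met, stringsAsFactors = FALSE)
    covered <- cand$chrom == s$chrom & cand$pos >= lo & cand$pos <= hi
    cand <- cand[!covered, , drop = FALSE]
  }
  do.call(rbind, out)
}

#' Merge per-metabolite intervals into final non-overlapping regions
#'
#' Intervals whose sentinel variants are in LD (`r2 > r2Merge`) are merged
#' (transitively, same chromosome), `pad` bp is added to both ends of every
#' region, and overlapping intervals are merged repeatedly until all regions
#' are pairwise disjoint. Intervals are 1-based closed; padded intervals
#' that merely abut (end + 1 == start) are NOT merged.
#'
#' @param intervals row-bound output of [metaboliteRegions()] over all
#'   metabolites.
#' @param sentinelLd r-squared matrix covering all sentinel variants.
#' @param r2Merge sentinel-LD merge threshold (default 0.6, strict `>`).
#' @param pad bp added to each side after the LD merge (default 2.5e5).
#' @return [GenomicRanges::GRanges] of disjoint regions with metadata
#'   columns `region_id` and `sentinels` (comma-separated sentinel ids).
#' @export
mergeRegions <- function(intervals, sentinelLd, r2Merge = 0.6, pad = 2.5e5) {
  iv <- as.data.frame(intervals)
  n <- nrow(iv)
  if (!n) return(GRanges())
  # union-find over intervals linked by sentinel LD (within chromosome)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (iv$chrom[i] != iv$chrom[j]) next
      si <- iv$sentinel_id[i]; sj <- iv$sentinel_id[j]
      r2 <- if (si %in% rownames(sentinelLd) && sj %in% rownames(sentinelLd))
        sentinelLd[si, sj] else 0
      if (isTRUE(r2 > r2Merge)) parent[find(i)] <- find(j)
    }
  }
  grp <- vapply(seq_len(n), find, integer(1))
  merged <- do.call(rbind, lapply(split(seq_len(n), grp), function(idx) {
    stopifnot(length(unique(iv$chrom[idx])) == 1L)  # LD is within-chromosome
    data.frame(chrom = iv$chrom[idx[1]],
               start = min(iv$start[idx]), end = max(iv$end[idx]),
               sentinels = paste(sort(unique(iv$sentinel_id[idx])), collapse = ","))
  }))
  merged$start <- pmax(1, merged$start - pad)
  merged$end <- merged$end + pad
  gr <- GRanges(merged$chrom, IRanges(merged$start, merged$end))
  mcols(gr)$sentinels <- merged$sentinels
  # closed-interval overlap merge to a fixpoint; min.gapwidth = 0 keeps
  # abutting-but-not-overlapping intervals separate
  red <- reduce(gr, min.gapwidth = 0L)
  hit <- findOverlaps(gr, red)
  sent <- vapply(seq_along(red), function(k) {
    paste(sort(unique(unlist(strsplit(
      mcols(gr)$sentinels[queryHits(hit)[subjectHits(hit) == k]], ",")))),
      collapse = ",")
  }, character(1))
  ord <- order(as.character(seqnames(red)), start(red))
  red <- red[ord]
  mcols(red)$region_id <- sprintf("region%03d", seq_along(red))
  mcols(red)$sentinels <- sent[ord]
  red
}

#' Assign candidate variants to final regions
#'
#' @param variants data.frame with `variant_id`, `chrom`, `pos`.
#' @param regions [GenomicRanges::GRanges] from [mergeRegions()].
#' @return `variants` with a `region_id` column (NA if uncovered).
#' @export
assignToRegions <- function(variants, regions) {
  v <- as.data.frame(variants)
  gr <- GRanges(v$chrom, IRanges(v$pos, v$pos))
  hit <- findOverlaps(gr, regions)
  v$region_id <- NA_character_
  v$region_id[queryHits(hit)] <- mcols(regions)$region_id[subjectHits(hit)]
  v
}

#' Export regions as BED
#'
#' Converts the internal 1-based closed convention to BED's 0-based
#' half-open convention (start - 1, end unchanged).
#'
#' @param regions [GenomicRanges::GRanges] from [mergeRegions()].
#' @param file path to write; tab-separated, no header.
#' @return the BED data.frame, invisibly.
#' @export
exportRegionsBED <- function(regions, file) {
  bed <- data.frame(chrom = as.character(seqnames(regions)),
                    start = start(regions) - 1L,
                    end = end(regions),
                    name = mcols(regions)$region_id,
                    sentinels = mcols(regions)$sentinels)
  utils::write.table(bed, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bed)
}
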
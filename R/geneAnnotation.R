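.normalizeText <- function(x) {
  x <- tolower(x)
  gsub("[^a-z0-9]", "", x)
}

.trigrams <- function(x) {
  n <- nchar(x)
  if (n < 3) return(character(0))
  unique(substring(x, 1:(n - 2), 3:n))
}

#' Trigram Dice similarity between two strings
#'
#' Strings are case-folded and stripped of non-alphanumeric characters;
#' similarity is the Dice coefficient over their sets of character
#' trigrams: `2 |A intersect B| / (|A| + |B|)`. Symmetric, in \[0, 1\];
#' equal normalized strings score 1, strings sharing no trigram score 0.
#' Strings empty after normalization score 0.
#'
#' @param a,b character strings.
#' @return similarity in \[0, 1\].
#' @export
fuzzyScore <- function(a, b) {
  na <- .normalizeText(a); nb <- .normalizeText(b)
  if (!nzchar(na) || !nzchar(nb)) return(0)
  if (na == nb) return(1)
  ta <- .trigrams(na); tb <- .trigrams(nb)
  if (!length(ta) || !length(tb)) return(0)
  2 * length(intersect(ta, tb)) / (length(ta) + length(tb))
}

#' Rank the protein-coding genes closest to a variant
#'
#' Distance is 0 if the variant lies inside the gene body (transcription
#' start to transcription end), otherwise base pairs to the nearest end.
#' The `k` closest protein-coding genes on the variant's chromosome are
#' returned in ascending distance (ties broken by gene name); fewer are
#' returned if fewer exist.
#'
#' @param chrom,pos variant location.
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `protein_coding` (logical).
#' @param k number of genes (default 20).
#' @return data.frame `gene_id`, `distance`, `distance_rank`.
#' @export
rankNearestGenes <- function(chrom, pos, genes, k = 20) {
  g <- genes[genes$chrom == chrom & genes$protein_coding, , drop = FALSE]
  if (!nrow(g))
    return(data.frame(gene_id = character(0), distance = numeric(0),
                      distance_rank = integer(0)))
  d <- ifelse(pos >= g$start & pos <= g$end, 0,
              pmin(abs(pos - g$start), abs(pos - g$end)))
  ord <- order(d, g$gene_id)
  g <- g[ord, , drop = FALSE]; d <- d[ord]
  n <- min(k, nrow(g))
  data.frame(gene_id = g$gene_id[seq_len(n)], distance = d[seq_len(n)],
             distance_rank = seq_len(n), row.names = NULL)
}

#' Disease/GO stop-word lists shipped with the package
#'
#' @param which `"disease"` (whole-word and suffix removal) or `"go"`
#'   (substring removal).
#' @return character vector of stop words.
#' @export
stopWords <- function(which = c("disease", "go")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0(which, "_stopwords.txt"),
                   package = "metabotyper")
  readLines(f)
}

# disease names: remove stop words as whole tokens and as word suffixes
.stripDiseaseStopwords <- function(x, sw = stopWords("disease")) {
  toks <- strsplit(tolower(x), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  out <- character(0)
  for (t in toks) {
    if (t %in% sw) next
    for (s in sw) {
      if (endsWith(t, s) && nchar(t) > nchar(s)) {
        t <- substr(t, 1, nchar(t) - nchar(s))
        break
      }
    }
    if (nzchar(t)) out <- c(out, t)
  }
  paste(out, collapse = " ")
}

# GO biological-process names: remove stop phrases as substrings
.stripGoStopwords <- function(x, sw = stopWords("go")) {
  x <- tolower(x)
  for (s in sw) x <- gsub(s, " ", x, fixed = TRUE)
  trimws(gsub("\\s+", " ", x))
}

#' Score candidate-gene evidence for a GIM across all annotation channels
#'
#' For each metabolite of the GIM and each candidate gene, applies seven
#' evidence channels: fuzzy match of metabolite synonyms to gene names and
#' to protein names, fuzzy match of the metabolite class to protein names,
#' fuzzy match of metabolite synonyms to gene-linked disease names (after
#' stop-word removal), lookup in the interacting-metabolites annotation,
#' co-occurrence on any shared pathway map (no direct connection required),
#' and fuzzy match of metabolite synonyms to GO biological processes with
#' fewer than `goMaxGenes` member genes (after stop-substring removal).
#' Fuzzy channels record a hit when the similarity exceeds `cutoff`.
#'
#' @param metaboliteIds metabolites of the GIM.
#' @param candidateGenes data.frame from [rankNearestGenes()] (`gene_id`,
#'   `distance_rank`).
#' @param resources named list of flat tables (any may be omitted; missing
#'   tables skip that channel with a warning):
#'   `metabolite_synonyms` (`metabolite_id`, `synonym`),
#'   `metabolite_classes` (`metabolite_id`, `class_name`),
#'   `gene_names` (`gene_id`, `name`),
#'   `protein_names` (`gene_id`, `name`),
#'   `gene_diseases` (`gene_id`, `disease_name`),
#'   `interacting_metabolites` (`gene_id`, `metabolite_id`),
#'   `gene_pathways` (`gene_id`, `map_id`),
#'   `metabolite_pathways` (`metabolite_id`, `map_id`),
#'   `go_bp` (`gene_id`, `term`, `n_genes`).
#' @param cutoff fuzzy-match threshold (default 0.5, strict `>`).
#' @param goMaxGenes GO terms with at least this many member genes are
#'   excluded (default 500).
#' @return data.frame of evidence hits: `gene_id`, `distance_rank`,
#'   `metabolite_id`, `source`, `matched_a`, `matched_b`, `score`;
#'   attribute `"flagged_causal"` is `"none"` (causal flagging is a manual
#'   review step downstream of this table).
#' @export
annotateGim <- function(metaboliteIds, candidateGenes, resources,
                        cutoff = 0.5, goMaxGenes = 500) {
  hits <- list()
  add <- function(gene, rank, met, source, a, b, s) {
    hits[[length(hits) + 1L]] <<- data.frame(
      gene_id = gene, distance_rank = rank, metabolite_id = met,
      source = source, matched_a = a, matched_b = b, score = s,
      stringsAsFactors = FALSE)
  }
  need <- function(nm) {
    if (is.null(resources[[nm]])) {
      warning("resource table '", nm, "' missing; channel skipped")
      return(NULL)
    }
    resources[[nm]]
  }
  syn <- need("metabolite_synonyms")
  cls <- need("metabolite_classes")
  gn <- need("gene_names"); pn <- need("protein_names")
  dis <- need("gene_diseases")
  im <- need("interacting_metabolites")
  gp <- need("gene_pathways"); mp <- need("metabolite_pathways")
  go <- need("go_bp")
  if (!is.null(go)) go <- go[go$n_genes < goMaxGenes, , drop = FALSE]

  for (i in seq_len(nrow(candidateGenes))) {
    gene <- candidateGenes$gene_id[i]
    rank <- candidateGenes$distance_rank[i]
    for (met in metaboliteIds) {
      syns <- if (is.null(syn)) character(0) else
        syn$synonym[syn$metabolite_id == met]
      # 1/2: metabolite synonym vs gene name / protein name
      for (ch in list(list(tab = gn, src = "gene_name"),
                      list(tab = pn, src = "protein_name"))) {
        if (is.null(ch$tab)) next
        nms <- ch$tab$name[ch$tab$gene_id == gene]
        for (s1 in syns) for (s2 in nms) {
          sc <- fuzzyScore(s1, s2)
          if (sc > cutoff) add(gene, rank, met, ch$src, s1, s2, sc)
        }
      }
      # 3: metabolite class vs protein name
      if (!is.null(cls) && !is.null(pn)) {
        cl <- cls$class_name[cls$metabolite_id == met]
        nms <- pn$name[pn$gene_id == gene]
        for (s1 in cl) for (s2 in nms) {
          sc <- fuzzyScore(s1, s2)
          if (sc > cutoff) add(gene, rank, met, "class_name", s1, s2, sc)
        }
      }
      # 4: metabolite synonym vs disease names, stop words removed
      if (!is.null(dis)) {
        dn <- dis$disease_name[dis$gene_id == gene]
        for (s1 in syns) for (s2 in dn) {
          s2r <- .stripDiseaseStopwords(s2)
          if (!nzchar(s2r)) next  # guard: never match on an emptied string
          sc <- fuzzyScore(s1, s2r)
          if (sc > cutoff) add(gene, rank, met, "disease_name", s1, s2, sc)
        }
      }
      # 5: interacting-metabolite lookup (exact id match)
      if (!is.null(im) &&
          any(im$gene_id == gene & im$metabolite_id == met))
        add(gene, rank, met, "interacting_protein", met, gene, 1)
      # 6: pathway-map co-occurrence
      if (!is.null(gp) && !is.null(mp)) {
        shared <- intersect(gp$map_id[gp$gene_id == gene],
                            mp$map_id[mp$metabolite_id == met])
        for (mapId in shared)
          add(gene, rank, met, "pathway_map", met, mapId, 1)
      }
      # 7: metabolite synonym vs small GO biological processes
      if (!is.null(go)) {
        terms <- go$term[go$gene_id == gene]
        for (s1 in syns) for (s2 in terms) {
          s2r <- .stripGoStopwords(s2)
          if (!nzchar(s2r)) next
          sc <- fuzzyScore(s1, s2r)
          if (sc > cutoff) add(gene, rank, met, "go_bp", s1, s2, sc)
        }
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(gene_id = character(0), distance_rank = integer(0),
               metabolite_id = character(0), source = character(0),
               matched_a = character(0), matched_b = character(0),
               score = numeric(0))
  attr(out, "flagged_causal") <- "none"
  out
}

#' Enrichment of inborn-error-of-metabolism genes among tested genes
#'
#' Compares the proportion of IEM genes among the tested genes to the
#' background proportion `nIemBackground / nBackground` (785 of 19817
#' protein-coding genes, i.e. ~4%) using a two-tailed binomial test
#' (minimum-likelihood method: the two-tailed P sums the probabilities of
#' all outcomes no more likely than the observed one).
#'
#' @param testedGenes character vector of genes annotated to
#'   metabolite-associated regions.
#' @param iemGenes character vector of known IEM-causing genes.
#' @param nBackground genome-wide protein-coding gene count (default 19817).
#' @param nIemBackground background IEM gene count (default 785).
#' @return list of class `EnrichmentResult`: `k` observed IEM genes, `n`
#'   tested genes, `p0` background proportion, `fold` enrichment, `pval`
#'   two-tailed binomial P.
#' @export
iemEnrichment <- function(testedGenes, iemGenes, nBackground = 19817,
                          nIemBackground = 785) {
  if (!length(testedGenes)) stop("testedGenes must be non-empty")
  testedGenes <- unique(testedGenes)
  k <- length(intersect(testedGenes, unique(iemGenes)))
  n <- length(testedGenes)
  p0 <- nIemBackground / nBackground
  fold <- (k / n) / p0
  pval <- binom.test(k, n, p0, alternative = "two.sided")$p.value
  structure(list(k = k, n = n, p0 = p0, fold = fold, pval = pval),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("IEM enrichment: %d/%d tested genes (background %.2f%%), fold = %.2f, P = %.3g\n",
              x$k, x$n, 100 * x$p0, x$fold, x$pval))
  invisible(x)
}
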
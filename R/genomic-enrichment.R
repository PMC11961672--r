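## Genome-category classification and enrichment statistics.
##
## Genome segments scored for enhancer enrichment (a p-value and a log2FC per
## segment, plus a 3D-interaction hub flag from Hi-C) are classified into four
## categories; categories are then profiled with three statistics: TF-target
## enrichment (observed/expected targets per category), a rank-based tissue
## specificity score, and permutation SNP-overlap enrichment against shuffled
## intervals. A hypergeometric test scores overlap of gene sets with published
## signature modules.

#' @importFrom GenomicRanges GRanges start end width seqnames countOverlaps
#'   findOverlaps reduce
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols
#' @importFrom GenomeInfoDb seqlevels
NULL

.SEGMENT_CATEGORIES <- c("PTC", "very_active", "moderately_active", "inactive",
                         "unclassified_depleted")

#' Classify genome segments by enhancer enrichment
#'
#' Four-way rule on a segment's enhancer-enrichment p-value, log2
#' fold-change and 3D-hub flag:
#' \itemize{
#'  \item PTC: p <= 0.05, log2FC >= 0 and high 3D interaction (hub);
#'  \item very_active: p <= 0.05, log2FC >= 0, not a hub;
#'  \item moderately_active: p > 0.05, log2FC >= 0;
#'  \item inactive: p > 0.05, log2FC < 0.
#' }
#' The cell p <= 0.05 with log2FC < 0 (significant depletion) is not covered
#' by the four rules and is flagged \code{unclassified_depleted}.
#'
#' @param enrichmentP numeric in [0, 1]; vectorized.
#' @param log2fc numeric.
#' @param hub logical or 0/1.
#' @return factor with levels PTC, very_active, moderately_active, inactive,
#'   unclassified_depleted.
#' @examples
#' classifySegment(c(0.04, 0.01, 1), c(0.5, 1, -1), c(1, 0, 0))
#' @export
classifySegment <- function(enrichmentP, log2fc, hub) {
  if (any(enrichmentP < 0 | enrichmentP > 1, na.rm = TRUE))
    stop("enrichmentP must lie in [0, 1]", call. = FALSE)
  hub <- as.logical(hub)
  sig <- enrichmentP <= 0.05
  out <- ifelse(sig & log2fc >= 0 & hub, "PTC",
         ifelse(sig & log2fc >= 0, "very_active",
         ifelse(!sig & log2fc >= 0, "moderately_active",
         ifelse(!sig & log2fc < 0, "inactive", "unclassified_depleted"))))
  factor(out, levels = .SEGMENT_CATEGORIES)
}

#' Classify a segment table
#'
#' @param segments data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{p}, \code{log2fc}, \code{hub} (0-based half-open
#'   intervals).
#' @return the data.frame with a \code{category} factor column appended.
#' @export
classifySegmentTable <- function(segments) {
  need <- c("chrom", "start", "end", "p", "log2fc", "hub")
  miss <- setdiff(need, names(segments))
  if (length(miss))
    stop("segment table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(segments$start >= segments$end))
    stop("segment intervals must satisfy start < end", call. = FALSE)
  segments$category <- classifySegment(segments$p, segments$log2fc, segments$hub)
  segments
}

#' TF-target enrichment per genomic category
#'
#' For each transcription factor, the expected number of its targets in a
#' category is (share of the gene universe that the TF targets) x (number of
#' genes in the category); the score is observed targets in the category
#' divided by that expectation. Scores weighted by category gene counts
#' average exactly 1 per TF.
#'
#' @param targets named list: TF id -> character vector of target gene ids.
#' @param geneCategory named character/factor: gene id -> category; the names
#'   define the gene universe.
#' @return data.frame with columns \code{tf}, \code{category},
#'   \code{observed}, \code{expected}, \code{score} (NA where the category is
#'   empty).
#' @export
tfTargetEnrichment <- function(targets, geneCategory) {
  universe <- names(geneCategory)
  if (is.null(universe)) stop("geneCategory must be named by gene id", call. = FALSE)
  cats <- unique(as.character(geneCategory))
  catCount <- table(factor(as.character(geneCategory), levels = cats))
  rows <- list()
  for (tf in names(targets)) {
    tg <- intersect(targets[[tf]], universe)
    if (!length(tg)) {
      warning("TF '", tf, "' has no targets in the universe; skipped")
      next
    }
    frac <- length(tg) / length(universe)
    tgCat <- table(factor(as.character(geneCategory[tg]), levels = cats))
    for (cc in cats) {
      expd <- frac * catCount[[cc]]
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, category = cc,
        observed = as.integer(tgCat[[cc]]), expected = expd,
        score = if (catCount[[cc]] > 0) tgCat[[cc]] / expd else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Tissue-specificity rank score
#'
#' Within each tissue, genes carry their expression rank (higher expression =
#' numerically higher rank; replicate datasets of one tissue averaged
#' beforehand). The score of a gene for a focal tissue (e.g. blood) is the
#' fraction of the other tissues whose rank for that gene is strictly lower
#' than its focal-tissue rank: 1 means the gene ranks highest in the focal
#' tissue, 0 lowest. Ties count as not lower.
#'
#' @param rankMatrix numeric genes x tissues matrix of expression ranks, with
#'   rownames (gene ids) and colnames (tissues).
#' @param gene gene id(s); default all genes.
#' @param focalTissue column name of the focal tissue.
#' @return named numeric vector of scores in [0, 1].
#' @export
tissueSpecificityScore <- function(rankMatrix, gene = rownames(rankMatrix),
                                   focalTissue) {
  if (!focalTissue %in% colnames(rankMatrix))
    stop("focal tissue '", focalTissue, "' not in rank matrix", call. = FALSE)
  missing <- setdiff(gene, rownames(rankMatrix))
  if (length(missing))
    stop("gene(s) missing from the rank matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  sub <- rankMatrix[gene, , drop = FALSE]
  if (anyNA(sub))
    stop("rank matrix contains missing ranks for requested genes", call. = FALSE)
  others <- setdiff(colnames(rankMatrix), focalTissue)
  focal <- sub[, focalTissue]
  lower <- rowSums(sub[, others, drop = FALSE] < focal)
  setNames(lower / length(others), gene)
}

#' Rank a gene-by-tissue expression table
#'
#' Converts expression values to within-tissue ranks (ties averaged; higher
#' expression gets a higher rank), averaging replicate datasets mapped to the
#' same tissue first.
#'
#' @param expr numeric genes x datasets matrix with rownames.
#' @param tissueOf character vector mapping each column to a tissue label;
#'   default: column names themselves.
#' @return genes x tissues matrix of average ranks.
#' @export
rankTissueMatrix <- function(expr, tissueOf = colnames(expr)) {
  stopifnot(ncol(expr) == length(tissueOf))
  ranks <- apply(expr, 2, rank)
  tissues <- unique(tissueOf)
  out <- vapply(tissues, function(t)
    rowMeans(ranks[, tissueOf == t, drop = FALSE]), numeric(nrow(expr)))
  rownames(out) <- rownames(expr)
  out
}

#' Shuffle intervals across a genome
#'
#' Re-places each interval, preserving its length, on a chromosome drawn with
#' probability proportional to chromosome length among chromosomes long enough
#' to host it, with a uniform start over valid positions. Shuffled intervals
#' may overlap one another. 0-based half-open convention.
#'
#' @param intervals data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, or a \code{GRanges}.
#' @param genome named numeric vector of chromosome lengths.
#' @param seed integer.
#' @return data.frame with columns chrom, start, end (same lengths, new
#'   placements).
#' @export
shuffleIntervals <- function(intervals, genome, seed = 1L) {
  iv <- .asIntervalFrame(intervals)
  lens <- iv$end - iv$start
  if (any(lens > max(genome)))
    stop("interval longer than every chromosome: cannot place", call. = FALSE)
  .withSeed(seed, {
    chrom <- character(nrow(iv)); start <- numeric(nrow(iv))
    for (i in seq_len(nrow(iv))) {
      ok <- genome >= lens[i]
      cand <- names(genome)[ok]
      ch <- if (length(cand) == 1L) cand else
        sample(cand, 1L, prob = genome[ok])
      chrom[i] <- ch
      maxStart <- genome[[ch]] - lens[i]
      start[i] <- floor(runif(1, 0, maxStart + 1))
      if (start[i] > maxStart) start[i] <- maxStart   # guard runif boundary
    }
    data.frame(chrom = chrom, start = start, end = start + lens,
               stringsAsFactors = FALSE)
  })
}

.asIntervalFrame <- function(x) {
  if (is(x, "GRanges"))
    return(data.frame(chrom = as.character(seqnames(x)),
                      start = start(x) - 1L, end = end(x),
                      stringsAsFactors = FALSE))
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  x[, c("chrom", "start", "end")]
}

.asGRanges0 <- function(iv) {
  iv <- .asIntervalFrame(iv)
  GRanges(iv$chrom, IRanges(iv$start + 1L, iv$end))
}

#' Permutation SNP-overlap enrichment
#'
#' Counts SNPs falling inside at least one interval of a genomic category
#' (each SNP counted once, point-in-interval with start <= pos < end), then
#' shuffles the intervals across the genome \code{nPerm} times and recomputes
#' the overlap. Enrichment = observed / mean(permuted overlaps).
#'
#' @param intervals data.frame (chrom, start, end; 0-based half-open) or
#'   GRanges.
#' @param snps data.frame with columns \code{chrom}, \code{pos} (0-based
#'   positions) or GRanges of width-1 features.
#' @param genome named numeric chromosome lengths.
#' @param nPerm number of permutations (default 100).
#' @param seed integer.
#' @return list with \code{observed}, \code{permuted} (integer vector length
#'   \code{nPerm}), \code{enrichment} (NA when the mean permuted overlap is 0,
#'   flagged \code{undefined = TRUE}).
#' @export
snpOverlapEnrichment <- function(intervals, snps, genome, nPerm = 100L, seed = 1L) {
  stopifnot(nPerm >= 1)
  iv <- .asIntervalFrame(intervals)
  if (is(snps, "GRanges")) {
    snps <- data.frame(chrom = as.character(seqnames(snps)),
                       pos = start(snps) - 1L, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("chrom", "pos") %in% names(snps)))
  snpGr <- GRanges(snps$chrom, IRanges(snps$pos + 1L, width = 1L))
  countIn <- function(frame) {
    gr <- .asGRanges0(frame)
    sum(countOverlaps(snpGr, gr) > 0)
  }
  observed <- countIn(iv)
  permuted <- vapply(seq_len(nPerm), function(i)
    countIn(shuffleIntervals(iv, genome, seed = seed + i - 1L)), numeric(1))
  m <- mean(permuted)
  enr <- if (observed == 0) 0 else if (m > 0) observed / m else NA_real_
  list(observed = observed, permuted = as.integer(permuted),
       enrichment = enr, undefined = observed > 0 && m == 0)
}

#' Hypergeometric module-overlap test
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' overlap between a gene cluster and a signature module drawn from a common
#' gene universe.
#'
#' @param clusterGenes,moduleGenes character vectors of gene ids (subsets of
#'   the universe), or integers giving the set sizes together with
#'   \code{overlap}.
#' @param universeSize integer.
#' @param overlap optional integer; computed from the sets when ids are given.
#' @return p-value.
#' @examples
#' moduleOverlapTest(10, 10, 20, overlap = 10)  # 1 / choose(20, 10)
#' @export
moduleOverlapTest <- function(clusterGenes, moduleGenes, universeSize,
                              overlap = NULL) {
  if (is.character(clusterGenes) || is.character(moduleGenes)) {
    k <- length(intersect(clusterGenes, moduleGenes))
    nC <- length(unique(clusterGenes)); nM <- length(unique(moduleGenes))
  } else {
    nC <- clusterGenes; nM <- moduleGenes
    if (is.null(overlap)) stop("overlap required when passing set sizes", call. = FALSE)
    k <- overlap
  }
  if (k > min(nC, nM))
    stop("overlap cannot exceed the smaller set", call. = FALSE)
  if (max(nC, nM) > universeSize)
    stop("sets cannot exceed the universe", call. = FALSE)
  phyper(k - 1, nM, universeSize - nM, nC, lower.tail = FALSE)
}
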
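## PTC gene filtering, timepoint-membership clustering, Day-0-relative
## expression. Genes associate with putative transcriptional condensates at
## up to three transdifferentiation timepoints (Day 0, Day 1, Day 7); the
## pattern of membership defines seven clusters.

.MEMBERSHIP_CLUSTERS <- c("Invariant", "Early", "Early-Intermediate",
                          "Intermediate", "Intermediate-Late", "Late",
                          "Early-Late")

#' Gene-PTC membership by gene-body overlap
#'
#' Flags each gene as a PTC member at a timepoint when its gene body overlaps
#' any PTC segment of that timepoint (any-overlap rule; 0-based half-open
#' intervals).
#'
#' @param genes data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (gene body, 0-based half-open).
#' @param ptcSegments data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, or a GRanges.
#' @return logical vector, one entry per gene.
#' @export
ptcMembership <- function(genes, ptcSegments) {
  g <- .asGRanges0(genes)
  p <- .asGRanges0(ptcSegments)
  countOverlaps(g, p) > 0
}

#' Filter PTC-associated genes
#'
#' Keeps genes that are protein-coding, have mean TPM strictly above 1 across
#' the three timepoints, have at least one H3K27ac peak within +/- \code{window}
#' bp (closed interval) of their promoter anchor (TSS), and belong to a PTC at
#' at least one timepoint.
#'
#' @param genes data.frame with columns \code{gene}, \code{biotype},
#'   \code{chrom}, \code{tss} (promoter anchor position), \code{tpm_d0},
#'   \code{tpm_d1}, \code{tpm_d7}, \code{member_d0}, \code{member_d1},
#'   \code{member_d7} (logical membership flags per timepoint). Genes with a
#'   missing (NA) \code{tss} are skipped with a warning.
#' @param peaks H3K27ac peaks: data.frame (chrom, start, end; 0-based
#'   half-open) or GRanges.
#' @param window half-width in bp of the closed promoter window (default 1000).
#' @return the filtered data.frame, with a \code{cluster} factor column from
#'   [clusterMembership()] appended.
#' @export
filterPtcGenes <- function(genes, peaks, window = 1000L) {
  need <- c("gene", "biotype", "chrom", "tss",
            "tpm_d0", "tpm_d1", "tpm_d7",
            "member_d0", "member_d1", "member_d7")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stop("gene table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  noAnchor <- is.na(genes$tss)
  if (any(noAnchor)) {
    warning(sum(noAnchor), " gene(s) without a promoter anchor skipped")
    genes <- genes[!noAnchor, , drop = FALSE]
  }
  pk <- .asGRanges0(peaks)
  ## closed +/- window around the TSS point (tss is a 0-based position)
  prom <- GRanges(genes$chrom,
                  IRanges(pmax(genes$tss - window, 0L) + 1L, genes$tss + window + 1L))
  hasPeak <- countOverlaps(prom, pk) > 0
  meanTpm <- rowMeans(cbind(genes$tpm_d0, genes$tpm_d1, genes$tpm_d7))
  member <- genes$member_d0 | genes$member_d1 | genes$member_d7
  keep <- genes$biotype == "protein_coding" & meanTpm > 1 & hasPeak & member
  out <- genes[keep, , drop = FALSE]
  out$cluster <- clusterMembership(out$member_d0, out$member_d1, out$member_d7)
  rownames(out) <- NULL
  out
}

#' Seven-way PTC membership clustering
#'
#' Maps the triplet of PTC membership flags at (Day 0, Day 1, Day 7) to one of
#' seven clusters: (1,1,1) Invariant; (1,0,0) Early; (1,1,0)
#' Early-Intermediate; (0,1,0) Intermediate; (0,1,1) Intermediate-Late;
#' (0,0,1) Late; (1,0,1) Early-Late. A gene with no membership at any
#' timepoint is an error.
#'
#' @param d0,d1,d7 logical (or 0/1) vectors.
#' @return factor with the seven cluster levels.
#' @examples
#' clusterMembership(c(1, 0), c(1, 1), c(1, 1))  # Invariant, Intermediate-Late
#' @export
clusterMembership <- function(d0, d1, d7) {
  d0 <- as.integer(as.logical(d0)); d1 <- as.integer(as.logical(d1))
  d7 <- as.integer(as.logical(d7))
  key <- paste0(d0, d1, d7)
  if (any(key == "000"))
    stop("gene(s) with no PTC membership at any timepoint cannot be clustered",
         call. = FALSE)
  map <- c("111" = "Invariant", "100" = "Early", "110" = "Early-Intermediate",
           "010" = "Intermediate", "011" = "Intermediate-Late", "001" = "Late",
           "101" = "Early-Late")
  factor(unname(map[key]), levels = .MEMBERSHIP_CLUSTERS)
}

#' Expression relative to Day 0
#'
#' Normalizes each gene's variance-stabilized counts at the three timepoints
#' to its Day-0 value. Genes with any value below \code{floor} (very low
#' counts, for which the ratio is unstable) are excluded.
#'
#' @param counts numeric genes x 3 matrix (columns Day 0, Day 1, Day 7) with
#'   rownames, on the variance-stabilized scale.
#' @param floor exclusion floor (default 1).
#' @return data.frame with columns \code{gene}, \code{d0}, \code{d1},
#'   \code{d7} (ratios; \code{d0} is exactly 1 for every retained gene).
#' @export
relativeExpressionToDay0 <- function(counts, floor = 1) {
  stopifnot(is.matrix(counts), ncol(counts) == 3)
  keep <- apply(counts, 1, min) >= floor & counts[, 1] > 0
  kept <- counts[keep, , drop = FALSE]
  data.frame(gene = rownames(kept),
             d0 = kept[, 1] / kept[, 1],
             d1 = kept[, 2] / kept[, 1],
             d7 = kept[, 3] / kept[, 1],
             row.names = NULL, stringsAsFactors = FALSE)
}
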
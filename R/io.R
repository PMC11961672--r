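## Readers and writers for the plain-text formats the analyses consume:
## BED intervals, TSV tables, multi-page TIFF stacks, JSON reports.

#' Read a BED file of intervals
#'
#' Reads >= 3 tab-separated columns into a 0-based half-open interval table.
#' Track and comment lines are skipped. Malformed rows (too few fields,
#' non-numeric coordinates, start >= end) raise an error naming the offending
#' line number.
#'
#' @param path file path.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end} and,
#'   when present, \code{name}.
#' @export
readBedFile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  rows <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("line ", i, ": BED rows need >= 3 tab-separated fields", call. = FALSE)
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e))
      stop("line ", i, ": non-numeric start/end", call. = FALSE)
    if (s >= e)
      stop("line ", i, ": start (", f[2], ") must be < end (", f[3], ")",
           call. = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = f[1], start = s, end = e,
      name = if (length(f) >= 4) f[4] else NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (is.null(out)) out <- data.frame(chrom = character(0), start = numeric(0),
                                      end = numeric(0), name = character(0))
  if (all(is.na(out$name))) out$name <- NULL
  out
}

#' Write intervals as BED
#'
#' @param intervals data.frame with chrom, start, end (0-based half-open) and
#'   optionally name.
#' @param path output path.
#' @export
writeBedFile <- function(intervals, path) {
  iv <- .asIntervalFrame(intervals)
  if ("name" %in% names(intervals)) iv$name <- intervals$name
  iv$start <- format(iv$start, scientific = FALSE, trim = TRUE)
  iv$end <- format(iv$end, scientific = FALSE, trim = TRUE)
  utils::write.table(iv, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an expression-by-genotype TSV
#'
#' Expects a header with columns \code{batch}, \code{replicate}, \code{x1},
#' \code{x2}, \code{expression}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readExpressionTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  .checkObsFrame(d)
  d
}

#' Write an expression-by-genotype TSV
#' @param data data.frame as produced by [simulateExpressionData()].
#' @param path output path.
#' @export
writeExpressionTable <- function(data, path) {
  utils::write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF channel into an array
#'
#' @param path TIFF file with one page per z-slice.
#' @return numeric \code{H x W x Z} array in [0, 1].
#' @export
readChannelTiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  array(unlist(pages), c(dim(pages[[1]]), length(pages)))
}

#' Write one channel of a stack as a multi-page TIFF
#'
#' @param channel numeric \code{H x W x Z} array in [0, 1].
#' @param path output path.
#' @export
writeChannelTiff <- function(channel, path) {
  if (is.matrix(channel)) channel <- array(channel, c(dim(channel), 1L))
  slices <- lapply(seq_len(dim(channel)[3]), function(z) channel[, , z])
  tiff::writeTIFF(slices, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a three-channel stack as DAPI/FISH/marker TIFF files
#'
#' @param stack a [ChannelStack-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the three paths.
#' @export
writeChannelStackTiff <- function(stack, dir, prefix = "stack") {
  stopifnot(is(stack, "ChannelStack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(dapi = file.path(dir, paste0(prefix, "_dapi.tif")),
             fish = file.path(dir, paste0(prefix, "_fish.tif")),
             marker = file.path(dir, paste0(prefix, "_marker.tif")))
  writeChannelTiff(dapi(stack), paths[["dapi"]])
  writeChannelTiff(fish(stack), paths[["fish"]])
  writeChannelTiff(marker(stack), paths[["marker"]])
  paths
}

#' Read DAPI/FISH/marker TIFFs into a ChannelStack
#'
#' @param dapiPath,fishPath,markerPath multi-page TIFF paths.
#' @return a [ChannelStack-class].
#' @export
readChannelStackTiff <- function(dapiPath, fishPath, markerPath) {
  ChannelStack(readChannelTiff(dapiPath), readChannelTiff(fishPath),
               readChannelTiff(markerPath))
}

#' Write a model-comparison report as JSON
#'
#' Emits per-family coefficients, sigma, log-likelihood, parameter and
#' observation counts, BIC and deltaBIC, the best set and the seed, so a run
#' is fully reproducible from its report.
#'
#' @param selection an [EnhancerModelSet-class].
#' @param path output path.
#' @param seed seed used for the fits (recorded in the report).
#' @return the report list, invisibly.
#' @export
writeFitReport <- function(selection, path, seed = NA_integer_) {
  stopifnot(is(selection, "EnhancerModelSet"))
  fits <- modelFits(selection)
  rep <- list(
    seed = seed,
    threshold = selection@threshold,
    best_set = bestModels(selection),
    models = lapply(fits, function(f) list(
      model = f@model,
      coefficients = as.list(f@coefficients),
      sigma = f@sigma, logLik = f@logLik,
      n_obs = f@nObs, n_params = f@nPar,
      bic = f@bic,
      delta_bic = deltaBIC(selection)[[f@model]])))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(rep)
}

#' Write an 11x11 enrichment map as TSV matrices
#'
#' @param map an [EnrichmentMap-class].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return named character vector of the three paths.
#' @export
writeEnrichmentMapTsv <- function(map, dir, prefix = "enrichment") {
  stopifnot(is(map, "EnrichmentMap"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(spot = file.path(dir, paste0(prefix, "_spot_median.tsv")),
             random = file.path(dir, paste0(prefix, "_random_median.tsv")),
             ratio = file.path(dir, paste0(prefix, "_ratio.tsv")))
  utils::write.table(spotMedianMap(map), paths[["spot"]], sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(randomMedianMap(map), paths[["random"]], sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(enrichmentRatio(map), paths[["ratio"]], sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  paths
}
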
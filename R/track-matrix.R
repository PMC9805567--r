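#' Build a fixed-resolution genome grid
#'
#' Tiles every chromosome into consecutive `binSize`-bp bins; the last
#' bin of each chromosome is truncated at the chromosome end. 5 kb is
#' the default resolution: large enough that chromatin-contact data can
#' later be pooled per bin, small enough to resolve enhancer-scale
#' signal.
#'
#' @param chromSizes named numeric vector (or 2-column data.frame of
#'   name, length) of chromosome lengths in bp.
#' @param binSize bin width in bp (default 5000).
#' @return a [GenomeGrid].
#' @examples
#' makeGenomeGrid(c(chr1 = 12000), binSize = 5000)
#' @export
makeGenomeGrid <- function(chromSizes, binSize = 5000L) {
  if (is.data.frame(chromSizes))
    chromSizes <- setNames(as.numeric(chromSizes[[2L]]),
                           as.character(chromSizes[[1L]]))
  binSize <- as.integer(binSize)
  if (length(binSize) != 1L || is.na(binSize) || binSize <= 0L)
    stop("binSize must be a single positive integer")
  if (is.null(names(chromSizes)) || any(names(chromSizes) == ""))
    stop("chromSizes must be named by chromosome")
  if (anyDuplicated(names(chromSizes)))
    stop("duplicate chromosome name in chromSizes: ",
         paste(unique(names(chromSizes)[duplicated(names(chromSizes))]),
               collapse = ", "))
  if (any(is.na(chromSizes)) || any(chromSizes <= 0))
    stop("all chromosome lengths must be positive")
  chromSizes <- setNames(as.integer(chromSizes), names(chromSizes))

  per <- lapply(names(chromSizes), function(chr) {
    len <- chromSizes[[chr]]
    s <- seq.int(1L, len, by = binSize)
    data.frame(chrom = chr, start = s, end = pmin(s + binSize - 1L, len))
  })
  df <- do.call(rbind, per)
  bins <- GRanges(factor(df$chrom, levels = names(chromSizes)),
                  IRanges(df$start, df$end),
                  seqlengths = chromSizes)
  new("GenomeGrid", bins = bins, binSize = binSize)
}

#' Read a two-column chromosome sizes file
#'
#' @param path TSV with chromosome name and length (no header).
#' @return named integer vector of lengths.
#' @export
readChromSizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  setNames(as.integer(df$length), df$chrom)
}

#' Bin a coverage track onto a genome grid
#'
#' Distributes interval signal mass over grid bins: each bin receives
#' the sum over overlapping intervals of value x overlap-length, so an
#' interval spanning a bin boundary is split proportionally and total
#' mass is conserved. Intervals use 0-based half-open (bedGraph)
#' coordinates.
#'
#' @param intervals data.frame with columns chrom, start, end, value
#'   (0-based half-open), or a `GRanges` with a `score` column.
#' @param grid a [GenomeGrid].
#' @return numeric vector of per-bin signal, length `nBins(grid)`.
#' @export
binTrack <- function(intervals, grid) {
  stopifnot(is(grid, "GenomeGrid"))
  bins <- gridBins(grid)
  if (is(intervals, "GRanges")) {
    gr <- intervals
    vals <- mcols(gr)$score
    if (is.null(vals)) stop("GRanges intervals need a 'score' column")
  } else {
    if (nrow(intervals) == 0L) return(numeric(length(bins)))
    chrom <- as.character(intervals[[1L]])
    unknown <- setdiff(unique(chrom), seqlevels(bins))
    if (length(unknown))
      stop("unknown chromosome(s) in track: ",
           paste(unknown, collapse = ", "))
    # 0-based half-open -> 1-based closed
    gr <- GRanges(factor(chrom, levels = seqlevels(bins)),
                  IRanges(as.integer(intervals[[2L]]) + 1L,
                          as.integer(intervals[[3L]])))
    vals <- as.numeric(intervals[[4L]])
  }
  if (length(gr) == 0L) return(numeric(length(bins)))
  if (any(vals < 0)) stop("interval values must be non-negative")
  sl <- seqlengths(bins)
  over <- end(gr) > sl[as.character(seqnames(gr))] | start(gr) < 1L
  if (any(over)) {
    i <- which(over)[1L]
    stop(sprintf("interval %s:%d-%d extends beyond the chromosome end",
                 as.character(seqnames(gr))[i], start(gr)[i] - 1L,
                 end(gr)[i]))
  }
  hits <- findOverlaps(gr, bins)
  if (length(hits) == 0L) return(numeric(length(bins)))
  ov <- width(pintersect(gr[S4Vectors::queryHits(hits)],
                         bins[S4Vectors::subjectHits(hits)]))
  mass <- vals[S4Vectors::queryHits(hits)] * ov
  out <- numeric(length(bins))
  agg <- rowsum(mass, S4Vectors::subjectHits(hits))
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Read a coverage track file (bedGraph or bigWig)
#'
#' Thin wrapper over [rtracklayer::import()]; returns intervals ready
#' for [binTrack()].
#'
#' @param path path to a `.bedGraph`/`.bg` or `.bw`/`.bigWig` file.
#' @return `GRanges` with a `score` column.
#' @export
readTrackFile <- function(path) {
  gr <- rtracklayer::import(path)
  if (is.null(mcols(gr)$score)) stop("track file has no score column: ", path)
  gr
}

#' Assemble a binned track matrix from per-track bin vectors or files
#'
#' @param tracks a named list of per-bin numeric vectors (as from
#'   [binTrack()]), a named list of file paths, or a bins x tracks
#'   matrix with column names.
#' @param grid a [GenomeGrid].
#' @return a [BinnedTrackMatrix] with `normTag = "raw"`.
#' @export
buildTrackMatrix <- function(tracks, grid) {
  stopifnot(is(grid, "GenomeGrid"))
  if (is.list(tracks)) {
    if (is.null(names(tracks)) || any(names(tracks) == ""))
      stop("tracks must be named")
    tracks <- vapply(tracks, function(tr) {
      if (is.character(tr)) binTrack(readTrackFile(tr), grid)
      else as.numeric(tr)
    }, numeric(nBins(grid)))
  }
  m <- as.matrix(tracks)
  if (nrow(m) != nBins(grid))
    stop("track length does not match grid bin count")
  if (is.null(colnames(m))) stop("track matrix must have column names")
  se <- SummarizedExperiment(assays = list(signal = m),
                             rowRanges = gridBins(grid))
  new("BinnedTrackMatrix", se, normTag = "raw", binSize = binSize(grid))
}

#' Depth-normalize the tracks of a binned matrix
#'
#' `cpm` scales each track so its bin values sum to 1e6 (counts per
#' million of total binned mass); `rpkm` additionally divides by bin
#' length in kb, so on a uniform grid it equals cpm / (binSize/1000);
#' `raw` is the identity.
#'
#' @param btm a [BinnedTrackMatrix].
#' @param method `"cpm"`, `"rpkm"` or `"raw"`.
#' @return a [BinnedTrackMatrix] with updated assay and `normTag`.
#' @export
normalizeTracks <- function(btm, method = c("cpm", "rpkm", "raw")) {
  stopifnot(is(btm, "BinnedTrackMatrix"))
  method <- match.arg(method)
  if (method == "raw") return(btm)
  m <- assay(btm, "signal")
  cs <- colSums(m)
  if (any(cs <= 0))
    stop("all-zero track(s) cannot be ", method, "-normalized: ",
         paste(colnames(m)[cs <= 0], collapse = ", "))
  m <- sweep(m, 2L, cs, "/") * 1e6
  if (method == "rpkm")
    m <- m / (width(rowRanges(btm)) / 1000)
  out <- btm
  out@normTag <- method
  SummarizedExperiment::assay(out, "signal") <- m
  validObject(out)
  out
}

#' Log10 + Z-score transform of a track matrix
#'
#' Per track: `z = (log10(x + pseudocount) - mean) / sd`, with the
#' population SD (divide by n). The transform makes tracks of very
#' different dynamic range comparable, and is the scale on which
#' enhancer bins are called and on which PCA is run by default.
#'
#' @param btm a [BinnedTrackMatrix] (or a plain bins x tracks matrix).
#' @param pseudocount added before the log (default 1).
#' @return bins x tracks matrix of Z-scores (column means 0, SDs 1).
#' @export
logZScore <- function(btm, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  m <- if (is(btm, "BinnedTrackMatrix")) assay(btm, "signal") else
    as.matrix(btm)
  lm <- log10(m + pseudocount)
  mu <- colMeans(lm)
  n <- nrow(lm)
  sdp <- sqrt(colMeans(sweep(lm, 2L, mu)^2))  # population SD
  if (any(sdp == 0))
    stop("constant track(s) cannot be Z-scored: ",
         paste(colnames(m)[sdp == 0], collapse = ", "))
  sweep(sweep(lm, 2L, mu), 2L, sdp, "/")
}

#' First principal component of a standardized track matrix
#'
#' Projects the bins x experiments matrix onto the leading eigenvector
#' of its column covariance, yielding the one-dimensional signal that
#' is segmented. The eigenvector sign is arbitrary, so PC1 is oriented
#' to correlate non-negatively with the per-bin mean of the input
#' (activity tracks then contribute positively); when that correlation
#' is degenerate (zero row means) the first loading is made
#' non-negative instead.
#'
#' @param zmat standardized bins x experiments matrix (see
#'   [logZScore()]); needs >= 2 bins and >= 2 experiments.
#' @return a [PCAResult].
#' @export
computePC1 <- function(zmat) {
  zmat <- as.matrix(zmat)
  if (nrow(zmat) < 2L || ncol(zmat) < 2L)
    stop("need at least 2 bins and 2 experiments")
  p <- prcomp(zmat, center = TRUE, scale. = FALSE)
  if (all(p$sdev < 1e-12)) stop("matrix has rank 0 after centering")
  varpct <- 100 * p$sdev^2 / sum(p$sdev^2)
  v <- p$rotation[, 1L]
  scores <- p$x[, 1L]
  rowmean <- rowMeans(zmat)
  cc <- if (sd(rowmean) > 0 && sd(scores) > 0)
    suppressWarnings(stats::cor(scores, rowmean)) else NA_real_
  flip <- if (!is.na(cc) && abs(cc) > 1e-12) cc < 0 else v[1L] < 0
  if (flip) { v <- -v; scores <- -scores }
  new("PCAResult", pc1 = unname(scores),
      varianceExplainedPct = varpct[1L],
      allVariancePct = unname(varpct),
      loadings = setNames(as.numeric(v), colnames(zmat)),
      signFlipped = flip)
}

#' Write / read a binned track matrix as TSV
#'
#' The pre-binned exchange format: header row, first three columns
#' chrom / start (0-based) / end, then one column per track. Reading
#' reconstructs the grid from the bins (bin size inferred from the
#' first bin) and restores the normalization tag from an optional
#' `# normalization:` comment line.
#'
#' @param btm a [BinnedTrackMatrix].
#' @param path TSV path.
#' @return `writeTrackMatrixTsv` returns `path` invisibly;
#'   `readTrackMatrixTsv` a [BinnedTrackMatrix].
#' @export
writeTrackMatrixTsv <- function(btm, path) {
  bins <- rowRanges(btm)
  df <- data.frame(chrom = as.character(seqnames(bins)),
                   start = start(bins) - 1L, end = end(bins),
                   as.data.frame(assay(btm, "signal")),
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# normalization: ", normTag(btm)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrackMatrixTsv
#' @export
readTrackMatrixTsv <- function(path) {
  first <- readLines(path, n = 1L)
  tag <- "raw"
  skip <- 0L
  if (startsWith(first, "# normalization:")) {
    tag <- trimws(sub("# normalization:", "", first, fixed = TRUE))
    skip <- 1L
  }
  df <- read.table(path, sep = "\t", header = TRUE, skip = skip,
                   check.names = FALSE, stringsAsFactors = FALSE)
  chrom <- as.character(df[[1L]])
  sizes <- tapply(df[[3L]], chrom, max)[unique(chrom)]
  binsz <- df[[3L]][1L] - df[[2L]][1L]
  grid <- makeGenomeGrid(setNames(as.integer(sizes), unique(chrom)),
                         binsz)
  m <- as.matrix(df[, -(1:3), drop = FALSE])
  btm <- buildTrackMatrix(m, grid)
  btm@normTag <- tag
  validObject(btm)
  btm
}
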
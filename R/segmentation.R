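#' Segmentation configuration
#'
#' Parameters of the sliding-window changepoint segmentation. Defaults
#' follow the pipeline's operating point on 5-kb bins: 1000-bin (5 Mb)
#' windows slid by 500 bins, and a minimum segment size of 5% of the
#' window (250 kb), which also caps the number of breaks a window can
#' return at `floor(1/minSegFrac) - 1`.
#'
#' @param windowBins window length in bins (default 1000).
#' @param stepBins slide between consecutive windows (default 500).
#' @param minSegFrac minimum segment size as a fraction of the window
#'   (default 0.05); must be in (0, 0.5].
#' @param maxBreaksPerWindow cap on breaks per window; default
#'   `floor(1/minSegFrac) - 1`.
#' @param mergeTolBins boundaries closer than this many bins are
#'   merged (single linkage, cluster replaced by its median); default
#'   one minimal segment, `ceiling(minSegFrac * windowBins)`, since two
#'   boundaries closer than a minimal segment cannot both be real.
#' @return a list of class `SegmentationConfig`.
#' @export
segmentationConfig <- function(windowBins = 1000L, stepBins = 500L,
                               minSegFrac = 0.05,
                               maxBreaksPerWindow = NULL,
                               mergeTolBins = NULL) {
  windowBins <- as.integer(windowBins); stepBins <- as.integer(stepBins)
  if (minSegFrac <= 0 || minSegFrac > 0.5)
    stop("minSegFrac must be in (0, 0.5]")
  if (stepBins > windowBins) stop("stepBins must be <= windowBins")
  h <- as.integer(ceiling(minSegFrac * windowBins))
  if (windowBins < 2L * h)
    stop("windowBins must be >= 2 * minimum segment size")
  if (is.null(maxBreaksPerWindow))
    maxBreaksPerWindow <- as.integer(floor(1 / minSegFrac)) - 1L
  if (is.null(mergeTolBins)) mergeTolBins <- h
  structure(list(windowBins = windowBins, stepBins = stepBins,
                 minSegFrac = minSegFrac, minSegBins = h,
                 maxBreaksPerWindow = as.integer(maxBreaksPerWindow),
                 mergeTolBins = as.integer(mergeTolBins)),
            class = "SegmentationConfig")
}

# RSS of fitting one mean to signal[i..j], vectorized over i, from
# prefix sums. s1/s2 have a leading 0 (s1[k+1] = sum of first k values).
.seg_rss <- function(s1, s2, i, j) {
  n <- j - i + 1
  pmax(0, (s2[j + 1] - s2[i]) - (s1[j + 1] - s1[i])^2 / n)
}

#' Detect structural breakpoints in a 1D signal
#'
#' Fits piecewise-constant mean models with up to `maxBreaks` breaks by
#' dynamic programming: for each break count m the break positions
#' globally minimize the residual sum of squares subject to every
#' segment holding at least `minSegBins` points (the Bai-Perron
#' construction; the F-test/Chow-test view of a structural break and
#' this RSS view select identical positions). The number of breaks is
#' then chosen by BIC, `n*log(RSS/n) + (2m + 2)*log(n)` (m break dates,
#' m+1 segment means, one variance), smallest m winning ties.
#'
#' @param signal numeric vector.
#' @param minSegBins minimum number of points per segment.
#' @param maxBreaks maximum number of breaks to consider.
#' @return integer vector of break indices, `b` meaning the fitted mean
#'   changes between positions `b` and `b + 1` (1-based); empty when no
#'   break improves the criterion. Signals shorter than `2*minSegBins`
#'   return an empty vector with a warning (chromosome-tail windows),
#'   never an error.
#' @export
detectBreakpoints <- function(signal, minSegBins, maxBreaks) {
  n <- length(signal)
  h <- as.integer(minSegBins)
  if (h < 1L) stop("minSegBins must be >= 1")
  if (maxBreaks < 0L) stop("maxBreaks must be >= 0")
  if (n < 2L * h) {
    warning("signal shorter than two minimum segments; no breaks returned")
    return(integer(0))
  }
  M <- min(as.integer(maxBreaks), n %/% h - 1L)
  s1 <- c(0, cumsum(signal))
  s2 <- c(0, cumsum(signal^2))
  if (M == 0L) return(integer(0))

  # dp[m+1, j]: minimal RSS of splitting 1..j into m+1 segments >= h
  dp <- matrix(Inf, nrow = M + 1L, ncol = n)
  bt <- matrix(NA_integer_, nrow = M + 1L, ncol = n)
  jr <- h:n
  dp[1L, jr] <- .seg_rss(s1, s2, 1L, jr)
  for (m in seq_len(M)) {
    for (j in seq.int((m + 1L) * h, n)) {
      b <- seq.int(m * h, j - h)           # last index of previous part
      tot <- dp[m, b] + .seg_rss(s1, s2, b + 1L, j)
      k <- which.min(tot)
      dp[m + 1L, j] <- tot[k]
      bt[m + 1L, j] <- b[k]
    }
  }

  rss <- dp[, n]
  feasible <- is.finite(rss)
  # floor the RSS at the rounding noise of the prefix-sum cancellation,
  # so constant signals (RSS 0 up to float error) always select m = 0
  eps <- 1e-10 * max(s2[n + 1L], 1e-300)
  bic <- n * log(pmax(rss, eps) / n) +
    (2 * (seq_len(M + 1L) - 1L) + 2) * log(n)
  bic[!feasible] <- Inf
  mstar <- which.min(bic) - 1L             # ties -> smallest m
  if (mstar == 0L) return(integer(0))
  breaks <- integer(mstar)
  j <- n
  for (m in seq.int(mstar, 1L)) {
    breaks[m] <- bt[m + 1L, j]
    j <- breaks[m]
  }
  breaks
}

#' Per-break F statistics (Chow test) for a fitted break set
#'
#' For reporting only: the F statistic of each single break against the
#' no-break model on the subsignal spanning its two flanking segments.
#'
#' @param signal numeric vector.
#' @param breaks break indices as from [detectBreakpoints()].
#' @return numeric vector of F statistics, one per break.
#' @export
breakFStatistics <- function(signal, breaks) {
  if (length(breaks) == 0L) return(numeric(0))
  bounds <- c(0L, sort(breaks), length(signal))
  vapply(seq_along(breaks), function(i) {
    lo <- bounds[i] + 1L; b <- bounds[i + 1L]; hi <- bounds[i + 2L]
    x <- signal[lo:hi]
    n <- length(x)
    rss0 <- sum((x - mean(x))^2)
    x1 <- signal[lo:b]; x2 <- signal[(b + 1L):hi]
    rss1 <- sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)
    if (rss1 <= 0) return(Inf)
    (rss0 - rss1) / (rss1 / (n - 2L))
  }, numeric(1))
}

# single-linkage clustering of sorted integer positions; clusters are
# runs with consecutive gaps <= tol, each replaced by its (floored) median
.merge_boundaries <- function(pos, tol) {
  if (length(pos) == 0L) return(integer(0))
  pos <- sort(pos)
  cl <- cumsum(c(1L, diff(pos) > tol))
  as.integer(floor(tapply(pos, cl, median)))
}

#' Segment one chromosome's PC1 signal
#'
#' Slides overlapping windows of `windowBins` by `stepBins` across the
#' chromosome (the final window is right-anchored at the chromosome end
#' so tail bins are scanned with full context; chromosomes shorter than
#' one window get a single whole-chromosome window), detects breaks per
#' window with [detectBreakpoints()], merges window-level boundaries
#' that fall within `mergeTolBins` of each other (single linkage,
#' cluster median), and emits the segments between consecutive merged
#' boundaries and the chromosome ends.
#'
#' @param pc1 numeric vector, one value per bin of the chromosome.
#' @param chrom chromosome name.
#' @param grid a [GenomeGrid] containing `chrom`.
#' @param cfg a [segmentationConfig()].
#' @return `GRanges` of segments with mcols `segment_id`, `mean_pc1`,
#'   `sd_pc1`, `n_bins`.
#' @export
segmentChromosome <- function(pc1, chrom, grid, cfg = segmentationConfig()) {
  stopifnot(is(grid, "GenomeGrid"))
  bins <- gridBins(grid)
  cbins <- bins[seqnames(bins) == chrom]
  n <- length(cbins)
  if (n == 0L) stop("chromosome not on grid: ", chrom)
  if (length(pc1) != n)
    stop("pc1 length does not match chromosome bin count")

  W <- cfg$windowBins
  starts <- if (n <= W) 1L else {
    s <- seq.int(1L, n - W + 1L, by = cfg$stepBins)
    if (s[length(s)] != n - W + 1L) s <- c(s, n - W + 1L)
    s
  }
  breaks <- integer(0)
  for (s in starts) {
    e <- min(s + W - 1L, n)
    wb <- suppressWarnings(
      detectBreakpoints(pc1[s:e], cfg$minSegBins, cfg$maxBreaksPerWindow))
    breaks <- c(breaks, wb + s - 1L)
  }
  breaks <- .merge_boundaries(unique(breaks), cfg$mergeTolBins)
  breaks <- breaks[breaks >= 1L & breaks < n]

  lo <- c(1L, breaks + 1L)
  hi <- c(breaks, n)
  segs <- GRanges(chrom,
                  IRanges(start(cbins)[lo], end(cbins)[hi]),
                  seqlengths = seqlengths(bins)[seqlevels(bins)])
  mcols(segs)$segment_id <- sprintf("%s_seg%03d", chrom, seq_along(segs))
  mcols(segs)$mean_pc1 <- vapply(seq_along(lo), function(i)
    mean(pc1[lo[i]:hi[i]]), numeric(1))
  mcols(segs)$sd_pc1 <- vapply(seq_along(lo), function(i)
    sd(pc1[lo[i]:hi[i]]), numeric(1))
  mcols(segs)$n_bins <- hi - lo + 1L
  segs
}

#' Segment a whole genome from its PC1 signal
#'
#' Applies [segmentChromosome()] per chromosome and concatenates.
#'
#' @param pc1 numeric vector over all grid bins (grid order).
#' @param grid a [GenomeGrid].
#' @param cfg a [segmentationConfig()].
#' @return `GRanges` of segments, grid chromosome order.
#' @export
segmentGenome <- function(pc1, grid, cfg = segmentationConfig()) {
  stopifnot(is(grid, "GenomeGrid"))
  bins <- gridBins(grid)
  if (length(pc1) != length(bins))
    stop("pc1 length does not match grid bin count")
  idx <- split(seq_along(bins), as.character(seqnames(bins)))
  segs <- lapply(seqlevels(bins), function(chr)
    segmentChromosome(pc1[idx[[chr]]], chr, grid, cfg))
  do.call(c, segs)
}

#' Per-segment diagnostics of a segmentation
#'
#' Reports, per segment, its size, the absolute difference of its mean
#' PC1 from each neighbouring segment's (NA at chromosome ends) and the
#' within-segment SD -- the three quantities used to pick the
#' minimum-segment-size cutoff.
#'
#' @param segments `GRanges` from [segmentChromosome()] (one
#'   chromosome, ordered).
#' @return data.frame with columns segment_id, n_bins, width_bp,
#'   diff_prev, diff_next, sd_pc1.
#' @export
segmentationDiagnostics <- function(segments) {
  m <- mcols(segments)$mean_pc1
  k <- length(segments)
  dprev <- c(NA_real_, abs(diff(m)))
  dnext <- c(abs(diff(m)), NA_real_)
  data.frame(segment_id = mcols(segments)$segment_id,
             n_bins = mcols(segments)$n_bins,
             width_bp = width(segments),
             diff_prev = dprev, diff_next = dnext,
             sd_pc1 = mcols(segments)$sd_pc1,
             row.names = NULL)
}

#' Write / read segments as BED6-style TSV
#'
#' Columns: chrom, start (0-based), end, segment_id, mean_pc1, strand
#' ('.'); extra columns sd_pc1 and n_bins are appended after the six
#' BED fields.
#'
#' @param segments segment `GRanges`.
#' @param path output path.
#' @return `writeSegmentsBed` returns `path` invisibly;
#'   `readSegmentsBed` returns the segment `GRanges`.
#' @export
writeSegmentsBed <- function(segments, path) {
  df <- data.frame(chrom = as.character(seqnames(segments)),
                   start = start(segments) - 1L,
                   end = end(segments),
                   segment_id = mcols(segments)$segment_id,
                   mean_pc1 = mcols(segments)$mean_pc1,
                   strand = ".",
                   sd_pc1 = mcols(segments)$sd_pc1,
                   n_bins = mcols(segments)$n_bins)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeSegmentsBed
#' @export
readSegmentsBed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "segment_id",
                                 "mean_pc1", "strand", "sd_pc1", "n_bins"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "numeric", "character",
                                  "numeric", "integer"))
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  mcols(gr)$segment_id <- df$segment_id
  mcols(gr)$mean_pc1 <- df$mean_pc1
  mcols(gr)$sd_pc1 <- df$sd_pc1
  mcols(gr)$n_bins <- df$n_bins
  gr
}
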
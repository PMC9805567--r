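# Independent brute-force oracles used across the suite. These are
# deliberately naive (enumeration / closure / direct summation) and
# share no code with the package implementations they check.

# exhaustive piecewise-constant changepoint search: enumerate every
# admissible break placement with 0..maxBreaks breaks and >= h points
# per segment, score by RSS, then pick the break count by
# BIC(m) = n log(RSS/n) + (2m + 2) log(n), smallest m on ties
bf_breakpoints <- function(signal, h, maxBreaks) {
  n <- length(signal)
  seg_rss <- function(i, j) {
    x <- signal[i:j]
    sum((x - mean(x))^2)
  }
  best_for_m <- function(m) {
    if (m == 0L) return(list(rss = seg_rss(1L, n), breaks = integer(0)))
    cand <- utils::combn(seq_len(n - 1L), m, simplify = FALSE)
    cand <- Filter(function(b) {
      all(diff(c(0L, b, n)) >= h)
    }, cand)
    if (length(cand) == 0L) return(NULL)
    rss <- vapply(cand, function(b) {
      bounds <- c(0L, b, n)
      sum(vapply(seq_len(m + 1L), function(k)
        seg_rss(bounds[k] + 1L, bounds[k + 1L]), numeric(1)))
    }, numeric(1))
    list(rss = min(rss), breaks = cand[[which.min(rss)]])
  }
  fits <- lapply(0:maxBreaks, best_for_m)
  keep <- !vapply(fits, is.null, logical(1))
  ms <- (0:maxBreaks)[keep]
  fits <- fits[keep]
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  bic <- n * log(pmax(rss, .Machine$double.xmin) / n) +
    (2 * ms + 2) * log(n)
  fits[[which.min(bic)]]$breaks
}

# connected components by boolean transitive closure over an adjacency
# matrix; returns a list of sorted member vectors, sorted by first member
bf_components <- function(nodes, edges) {
  k <- length(nodes)
  adj <- diag(TRUE, k)
  dimnames(adj) <- list(nodes, nodes)
  if (nrow(edges) > 0L)
    for (i in seq_len(nrow(edges))) {
      adj[edges[i, 1L], edges[i, 2L]] <- TRUE
      adj[edges[i, 2L], edges[i, 1L]] <- TRUE
    }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj > 0)) break
    adj <- nxt
  }
  comp <- unique(lapply(seq_len(k), function(i) sort(nodes[adj[i, ]])))
  comp[order(vapply(comp, `[`, character(1), 1L))]
}

# upper tail of the ZINB by direct pmf summation over the tail (the
# summation runs far enough out that the truncated mass is < 1e-16)
bf_zinb_upper <- function(obs, pi0, mu, theta) {
  if (obs <= 0) return(1)
  K <- obs + max(1000L, ceiling(50 * (mu + mu^2 / theta)))
  sum(dzinb(obs:K, pi0, mu, theta))
}

# a tiny two-chromosome grid for unit tests
toy_grid <- function(nbins = c(chrT1 = 200L, chrT2 = 150L),
                     binSize = 1000L)
  makeGenomeGrid(setNames(nbins * binSize, names(nbins)), binSize)

# bin-aligned segments on a toy grid from 1-based inclusive bin ranges
toy_segments <- function(grid, chrom, startBin, endBin,
                         ids = NULL, meanPc1 = 0) {
  bs <- binSize(grid)
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges((startBin - 1L) * bs + 1L, endBin * bs),
    seqlengths = GenomeInfoDb::seqlengths(gridBins(grid)))
  if (is.null(ids)) ids <- sprintf("seg%02d", seq_along(gr))
  S4Vectors::mcols(gr)$segment_id <- ids
  S4Vectors::mcols(gr)$mean_pc1 <- rep_len(meanPc1, length(gr))
  S4Vectors::mcols(gr)$sd_pc1 <- 0
  S4Vectors::mcols(gr)$n_bins <- endBin - startBin + 1L
  gr
}

# minimal annotation table marking the given ids enriched
toy_annotation <- function(ids, enriched = ids) {
  S4Vectors::DataFrame(
    segment_id = ids,
    label = ifelse(ids %in% enriched, "enhancer_enriched",
                   "enhancer_depleted"))
}

# contact records between bp positions on one chromosome
toy_contacts <- function(chrom, pos1, pos2, score)
  condseg:::.contact_set(
    data.frame(chrom1 = chrom, pos1 = pos1, chrom2 = chrom,
               pos2 = pos2, score = score), "external_normalized")
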
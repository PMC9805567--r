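#' Specification of a synthetic multi-omics fixture
#'
#' Describes a small synthetic genome with planted structure at every
#' level the pipeline sees: piecewise-constant track means (the
#' segmentation truth), enhancer-dense regions whose bins jointly boost
#' the H3K27ac and ATAC tracks (the annotation truth), and 3D hubs --
#' sets of enhancer regions whose bin pairs receive elevated contact
#' scores (the PTC truth). The default genome is 2 chromosomes of 1500
#' five-kb bins (15 Mb total): small enough for exhaustive oracles,
#' large enough that full 1000-bin segmentation windows, the 2 Mb
#' contact cap and multi-segment hubs are all exercised.
#'
#' Default planted structure: per-bin track mean 2 outside planted
#' segments and 7 inside (a step of 5 at noise SD 1); six 60-bin
#' enhancer regions at density 0.9 grouped into three hubs of 2-3
#' regions (members within 2 Mb); one enhancer region and one plain
#' high-signal segment left out of any hub so the Enhancer and Active
#' categories are populated; hub bin pairs score `hubScoreMean` = 20
#' over a `backgroundScoreMean` = 0 background (unit SD both).
#'
#' @param chromSizes named vector of chromosome lengths (bp).
#' @param binSize bin width (default 5000).
#' @param trackNames track names; the first two are the joint enhancer
#'   marks.
#' @param baselineMean,plantedSegments baseline per-bin track mean, and
#'   a data.frame (chrom, start_bin, end_bin, mean_level; 1-based
#'   inclusive bins) of planted elevated segments.
#' @param enhancerRegions data.frame (chrom, start_bin, end_bin,
#'   density) of enhancer-dense regions; density is the fraction of
#'   region bins boosted on both marks.
#' @param hubs list of integer vectors indexing `enhancerRegions` rows;
#'   each vector is one 3D hub.
#' @param hubScoreMean,backgroundScoreMean,noiseSd,enhancerBoost score
#'   and signal parameters (see above; `enhancerBoost` = 30 added to
#'   both mark tracks on boosted bins).
#' @param nBackgroundContacts background contact records per
#'   chromosome (default 20000).
#' @param nHubContactsPerPair contact records per hub region pair,
#'   including each region with itself (default 500).
#' @param seed integer seed used by the generators.
#' @return list of class `FixtureSpec`.
#' @export
fixtureSpec <- function(
    chromSizes = c(chrS1 = 7500000L, chrS2 = 7500000L),
    binSize = 5000L,
    trackNames = c("H3K27ac", "ATAC", "H3K4me3", "TF1"),
    baselineMean = 2,
    plantedSegments = NULL,
    enhancerRegions = NULL,
    hubs = NULL,
    hubScoreMean = 20,
    backgroundScoreMean = 0,
    noiseSd = 1,
    enhancerBoost = 30,
    nBackgroundContacts = 20000L,
    nHubContactsPerPair = 500L,
    seed = 1L) {
  if (is.null(plantedSegments))
    plantedSegments <- data.frame(
      chrom = c(rep("chrS1", 5L), rep("chrS2", 4L)),
      start_bin = c(201L, 321L, 801L, 921L, 1041L,
                    401L, 521L, 1001L, 1201L),
      end_bin = c(260L, 380L, 860L, 980L, 1100L,
                  460L, 580L, 1060L, 1300L),
      mean_level = 7)
  if (is.null(enhancerRegions))
    enhancerRegions <- data.frame(
      chrom = c("chrS1", "chrS1", "chrS1", "chrS1", "chrS1",
                "chrS2", "chrS2", "chrS2"),
      start_bin = c(201L, 321L, 801L, 921L, 1041L, 401L, 521L, 1001L),
      end_bin = c(260L, 380L, 860L, 980L, 1100L, 460L, 580L, 1060L),
      density = 0.9)
  if (is.null(hubs))
    hubs <- list(c(1L, 2L), c(3L, 4L, 5L), c(6L, 7L))

  ps <- plantedSegments
  o <- order(ps$chrom, ps$start_bin)
  ps <- ps[o, , drop = FALSE]
  bychrom <- split(ps, ps$chrom)
  for (df in bychrom)
    if (nrow(df) > 1L && any(df$start_bin[-1L] <= df$end_bin[-nrow(df)]))
      stop("planted segments overlap on ", df$chrom[1L])
  if (any(enhancerRegions$density < 0 | enhancerRegions$density > 1))
    stop("enhancer densities must be in [0, 1]")

  structure(list(chromSizes = chromSizes, binSize = as.integer(binSize),
                 trackNames = trackNames, baselineMean = baselineMean,
                 plantedSegments = plantedSegments,
                 enhancerRegions = enhancerRegions, hubs = hubs,
                 hubScoreMean = hubScoreMean,
                 backgroundScoreMean = backgroundScoreMean,
                 noiseSd = noiseSd, enhancerBoost = enhancerBoost,
                 nBackgroundContacts = as.integer(nBackgroundContacts),
                 nHubContactsPerPair = as.integer(nHubContactsPerPair),
                 seed = as.integer(seed)),
            class = "FixtureSpec")
}

#' A fixture with no planted signal
#'
#' Same genome and noise as [fixtureSpec()] but a flat mean everywhere,
#' no enhancer regions and no hubs: pure noise at every level, so the
#' pipeline should find no enriched segments and call no PTC on it.
#'
#' @param ... overrides passed to [fixtureSpec()].
#' @return a `FixtureSpec`.
#' @export
noSignalFixtureSpec <- function(...) {
  fixtureSpec(plantedSegments = data.frame(chrom = character(),
                                           start_bin = integer(),
                                           end_bin = integer(),
                                           mean_level = numeric()),
              enhancerRegions = data.frame(chrom = character(),
                                           start_bin = integer(),
                                           end_bin = integer(),
                                           density = numeric()),
              hubs = list(), ...)
}

# global bin indices (grid order) of 1-based bin range on a chromosome
.fixture_bin_index <- function(spec, chrom, startBin, endBin) {
  offs <- c(0L, cumsum(ceiling(spec$chromSizes / spec$binSize)))
  ci <- match(chrom, names(spec$chromSizes))
  offs[ci] + seq.int(startBin, endBin)
}

#' Generate the planted coverage tracks of a fixture
#'
#' Each track is the planted piecewise-constant mean plus Gaussian
#' noise (SD `noiseSd`), truncated at zero; within enhancer regions a
#' seeded Bernoulli(density) subset of bins additionally gets
#' `enhancerBoost` added on the first two (mark) tracks jointly, so
#' those bins pass the joint Z >= 1 enhancer call after the log10 +
#' Z-score transform. Gaussian noise keeps the fixture analytic and
#' tiny; `mode = "poisson"` instead draws each bin from a Poisson with
#' the planted mean (read-count-like).
#'
#' @param spec a [fixtureSpec()].
#' @param mode `"gaussian"` (default) or `"poisson"`.
#' @return list with `grid` (a [GenomeGrid]), `btm` (a
#'   [BinnedTrackMatrix]), `enhancerTruth` (0/1 vector of boosted
#'   bins).
#' @export
generateTracks <- function(spec, mode = c("gaussian", "poisson")) {
  mode <- match.arg(mode)
  set.seed(spec$seed)
  grid <- makeGenomeGrid(spec$chromSizes, spec$binSize)
  n <- nBins(grid)
  mu <- rep(spec$baselineMean, n)
  ps <- spec$plantedSegments
  for (i in seq_len(nrow(ps)))
    mu[.fixture_bin_index(spec, ps$chrom[i], ps$start_bin[i],
                          ps$end_bin[i])] <- ps$mean_level[i]
  boosted <- integer(n)
  er <- spec$enhancerRegions
  for (i in seq_len(nrow(er))) {
    idx <- .fixture_bin_index(spec, er$chrom[i], er$start_bin[i],
                              er$end_bin[i])
    boosted[idx[runif(length(idx)) < er$density[i]]] <- 1L
  }
  m <- matrix(0, nrow = n, ncol = length(spec$trackNames),
              dimnames = list(NULL, spec$trackNames))
  for (j in seq_along(spec$trackNames)) {
    base <- mu
    if (j <= 2L) base <- base + boosted * spec$enhancerBoost
    m[, j] <- if (mode == "poisson") rpois(n, base)
    else pmax(0, base + rnorm(n, 0, spec$noiseSd))
  }
  btm <- buildTrackMatrix(m, grid)
  list(grid = grid, btm = btm, enhancerTruth = boosted)
}

#' Generate the planted contact score set of a fixture
#'
#' Background: per chromosome, `nBackgroundContacts` records with a
#' uniformly drawn first bin, a geometric distance decay (mean ~100
#' bins, capped at 450) and scores ~ Normal(backgroundScoreMean, 1).
#' Hubs: every ordered pair of regions of a hub -- including each
#' region with itself, so intra-segment scores are elevated too --
#' receives `nHubContactsPerPair` records between uniformly drawn bins
#' of the two regions, scored ~ Normal(hubScoreMean, 1). Positions are
#' bin midpoints (0-based bp).
#'
#' @param spec a [fixtureSpec()].
#' @param grid the fixture's [GenomeGrid].
#' @return contact score set (see [loadContactScores()]),
#'   `sourceTag = "external_normalized"`.
#' @export
generateContacts <- function(spec, grid) {
  set.seed(spec$seed + 1L)
  bs <- spec$binSize
  mid <- function(binIdx) as.integer((binIdx - 1L) * bs + bs %/% 2L)
  recs <- list()
  for (chr in names(spec$chromSizes)) {
    nb <- as.integer(ceiling(spec$chromSizes[[chr]] / bs))
    nc <- spec$nBackgroundContacts
    b1 <- sample.int(nb, nc, replace = TRUE)
    dd <- pmin(1L + stats::rgeom(nc, 1 / 100), 450L)
    b2 <- pmin(b1 + dd, nb)
    recs[[length(recs) + 1L]] <- data.frame(
      chrom1 = chr, pos1 = mid(b1), chrom2 = chr, pos2 = mid(b2),
      score = rnorm(nc, spec$backgroundScoreMean, 1))
  }
  er <- spec$enhancerRegions
  for (hub in spec$hubs) {
    for (a in hub) for (b in hub[hub >= a]) {
      ra <- er[a, ]; rb <- er[b, ]
      nh <- spec$nHubContactsPerPair
      ba <- sample(seq.int(ra$start_bin, ra$end_bin), nh, replace = TRUE)
      bb <- sample(seq.int(rb$start_bin, rb$end_bin), nh, replace = TRUE)
      recs[[length(recs) + 1L]] <- data.frame(
        chrom1 = ra$chrom, pos1 = mid(ba), chrom2 = rb$chrom,
        pos2 = mid(bb), score = rnorm(nh, spec$hubScoreMean, 1))
    }
  }
  .contact_set(do.call(rbind, recs), "external_normalized")
}

#' Generate genes and expression for a fixture
#'
#' One gene per enhancer region (spanning it) plus one gene per 100
#' background bins, with log-normal TPM per condition; genes in hub
#' regions are expressed in all conditions. Mostly exercises the
#' candidate-gene plumbing; condition-specific patterns are built in
#' tests directly.
#'
#' @param spec a [fixtureSpec()].
#' @param grid the fixture's [GenomeGrid].
#' @param conditions condition names (default c("c1", "c2", "c3")).
#' @return list with `genes` (`GRanges`) and `tpm` (long data.frame).
#' @export
generateGenes <- function(spec, grid, conditions = c("c1", "c2", "c3")) {
  set.seed(spec$seed + 2L)
  bs <- spec$binSize
  er <- spec$enhancerRegions
  gr_list <- list()
  if (nrow(er) > 0L)
    gr_list$enh <- GRanges(er$chrom,
                           IRanges((er$start_bin - 1L) * bs + 1L,
                                   er$end_bin * bs))
  for (chr in names(spec$chromSizes)) {
    nb <- as.integer(ceiling(spec$chromSizes[[chr]] / bs))
    at <- seq.int(50L, nb - 10L, by = 100L)
    gr_list[[chr]] <- GRanges(chr, IRanges((at - 1L) * bs + 1L,
                                           (at + 3L) * bs))
  }
  genes <- suppressWarnings(do.call(c, unname(gr_list)))
  seqlevels(genes) <- seqlevels(gridBins(grid))
  seqlengths(genes) <- seqlengths(gridBins(grid))
  mcols(genes)$gene_id <- sprintf("gene%03d", seq_along(genes))
  strand(genes) <- "+"
  mcols(genes)$tss <- start(genes)
  tpm <- do.call(rbind, lapply(conditions, function(cd)
    data.frame(gene_id = mcols(genes)$gene_id, condition = cd,
               tpm = round(stats::rlnorm(length(genes), 1, 1), 3))))
  list(genes = genes, tpm = tpm)
}

#' Write a complete fixture directory
#'
#' Emits bedGraph tracks, chrom.sizes, the contact score TSV, genes
#' BED, TPM TSV and a truth JSON (planted boundaries in bins, boosted
#' enhancer bins, hub region spans) under `dir`.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory (created).
#' @return invisibly, a named list of the written paths.
#' @export
writeFixture <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- generateTracks(spec)
  contacts <- generateContacts(spec, tr$grid)
  gn <- generateGenes(spec, tr$grid)
  bins <- gridBins(tr$grid)
  paths <- list()

  paths$chromSizes <- file.path(dir, "chrom.sizes")
  write.table(data.frame(names(spec$chromSizes),
                         as.integer(spec$chromSizes)),
              paths$chromSizes, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  m <- assay(tr$btm, "signal")
  for (trk in colnames(m)) {
    p <- file.path(dir, paste0(trk, ".bedGraph"))
    write.table(data.frame(as.character(seqnames(bins)),
                           start(bins) - 1L, end(bins),
                           round(m[, trk], 4)),
                p, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    paths[[trk]] <- p
  }
  paths$contacts <- file.path(dir, "contacts.tsv")
  write.table(contacts, paths$contacts, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  paths$genes <- file.path(dir, "genes.bed")
  write.table(data.frame(as.character(seqnames(gn$genes)),
                         start(gn$genes) - 1L, end(gn$genes),
                         mcols(gn$genes)$gene_id, 0L,
                         as.character(strand(gn$genes))),
              paths$genes, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  paths$tpm <- file.path(dir, "tpm.tsv")
  write.table(gn$tpm, paths$tpm, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(fixtureTruth(spec), paths$truth,
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Planted truth of a fixture
#'
#' @param spec a [fixtureSpec()].
#' @return list with `boundaries` (per chromosome, the bin indices
#'   after which a planted mean change occurs), `enhancer_regions` and
#'   `hubs` (region indices per hub).
#' @export
fixtureTruth <- function(spec) {
  ps <- spec$plantedSegments
  boundaries <- lapply(names(spec$chromSizes), function(chr) {
    nb <- as.integer(ceiling(spec$chromSizes[[chr]] / spec$binSize))
    df <- ps[ps$chrom == chr, , drop = FALSE]
    b <- sort(unique(c(df$start_bin - 1L, df$end_bin)))
    b[b >= 1L & b < nb]
  })
  names(boundaries) <- names(spec$chromSizes)
  list(boundaries = boundaries,
       enhancer_regions = spec$enhancerRegions,
       hubs = spec$hubs)
}

#' Boundary recovery against planted truth
#'
#' Fraction of planted boundaries with a called segment boundary
#' within `tolBins` bins.
#'
#' @param segments called segment `GRanges` (whole genome).
#' @param spec the [fixtureSpec()].
#' @param grid the fixture [GenomeGrid].
#' @param tolBins tolerance in bins (default 2).
#' @return list with `recovered`, `total`, `fraction`,
#'   `displacements` (per planted boundary, bins to nearest call; Inf
#'   when the chromosome has no internal boundary).
#' @export
evaluateBoundaryRecovery <- function(segments, spec, grid, tolBins = 2L) {
  truth <- fixtureTruth(spec)$boundaries
  disp <- numeric(0)
  for (chr in names(truth)) {
    segs <- segments[seqnames(segments) == chr]
    called <- (end(segs) %/% binSize(grid))
    called <- called[-length(called)]  # drop the chromosome end
    for (b in truth[[chr]])
      disp <- c(disp, if (length(called)) min(abs(called - b)) else Inf)
  }
  list(recovered = sum(disp <= tolBins), total = length(disp),
       fraction = if (length(disp)) mean(disp <= tolBins) else NA_real_,
       displacements = disp)
}

#' Hub recovery against planted truth
#'
#' Maps each planted hub to its truth segment set (for each member
#' region, the called segment with the largest overlap) and reports,
#' per hub, the best Jaccard index between that set and any called
#' PTC's member set, plus whether exactly one PTC attains it.
#'
#' @param ptcs PTC `GRanges` from [callPTCs()].
#' @param segments called segment `GRanges`.
#' @param spec the [fixtureSpec()].
#' @return data.frame with hub, n_regions, best_jaccard, n_best_ptcs.
#' @export
evaluateHubRecovery <- function(ptcs, segments, spec) {
  er <- spec$enhancerRegions
  bs <- spec$binSize
  ids <- mcols(segments)$segment_id
  region_seg <- vapply(seq_len(nrow(er)), function(i) {
    rg <- GRanges(er$chrom[i], IRanges((er$start_bin[i] - 1L) * bs + 1L,
                                       er$end_bin[i] * bs))
    hits <- findOverlaps(rg, segments)
    if (length(hits) == 0L) return(NA_character_)
    ov <- width(pintersect(rep(rg, length(hits)),
                           segments[S4Vectors::subjectHits(hits)]))
    ids[S4Vectors::subjectHits(hits)[which.max(ov)]]
  }, character(1))
  memb <- mcols(ptcs)$members
  res <- lapply(seq_along(spec$hubs), function(h) {
    truth_set <- unique(stats::na.omit(region_seg[spec$hubs[[h]]]))
    jac <- vapply(seq_along(ptcs), function(p) {
      m <- memb[[p]]
      length(intersect(m, truth_set)) / length(union(m, truth_set))
    }, numeric(1))
    best <- if (length(jac)) max(jac) else 0
    data.frame(hub = h, n_regions = length(spec$hubs[[h]]),
               best_jaccard = best,
               n_best_ptcs = sum(jac == best & best > 0))
  })
  do.call(rbind, res)
}
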
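test_that("loadContactScores canonicalizes and validates records", {
  p <- tempfile(fileext = ".tsv")
  on.exit(unlink(p))
  writeLines(c("chr1\t100\tchr1\t500\t3.5",
               "chr1\t900\tchr1\t200\t1.0",
               "chr1\t50\tchr2\t60\t2.0"), p)
  cs <- loadContactScores(p)
  expect_equal(nrow(cs), 3L)
  expect_equal(cs$pos1[2], 200)   # swapped on load
  expect_equal(cs$pos2[2], 900)
  expect_equal(attr(cs, "nInterChrom"), 1L)
  expect_equal(attr(cs, "sourceTag"), "external_normalized")

  empty <- tempfile(); file.create(empty); on.exit(unlink(empty),
                                                   add = TRUE)
  expect_warning(e <- loadContactScores(empty), "empty")
  expect_equal(nrow(e), 0L)

  bad <- tempfile(); on.exit(unlink(bad), add = TRUE)
  writeLines(c("chr1\t100\tchr1\t500\t3.5", "chr1\toops"), bad)
  expect_error(loadContactScores(bad), "malformed")
})

test_that("fallbackScoreContacts computes distance-decay log ratios", {
  grid <- toy_grid(c(chrT1 = 100L), 1000L)

  # uniform contacts at one distance: observed == expected everywhere,
  # scores ~ log2((1+1)/(1+1)) = 0
  pairs <- data.frame(chrom = "chrT1",
                      pos1 = (0:98) * 1000 + 500,
                      pos2 = (1:99) * 1000 + 500)
  cs <- fallbackScoreContacts(pairs, grid)
  expect_equal(cs$score, rep(0, nrow(cs)), tolerance = 1e-12)

  # one bin pair with 8x the stratum mean: score ~ 3 when counts are
  # large enough that the +1 regularizer is negligible
  rep8 <- pairs[rep(1:99, each = 50), ]
  extra <- pairs[rep(10, 350), ]
  cs2 <- fallbackScoreContacts(rbind(rep8, extra), grid)
  hot <- cs2$score[cs2$pos1 == pairs$pos1[10]]
  # stratum mean = (99*50 + 350)/99 ~ 53.5; hot bin 400 contacts
  expect_equal(hot, log2((400 + 1) / ((99 * 50 + 350) / 99 + 1)),
               tolerance = 1e-12)
  expect_gt(hot, 2.5)

  e <- fallbackScoreContacts(
    data.frame(chrom = character(), pos1 = integer(), pos2 = integer()),
    grid)
  expect_equal(nrow(e), 0L)
  expect_equal(attr(cs2, "sourceTag"), "fallback")
})

test_that("scoreSegmentPairs pools by median within the distance cap", {
  grid <- toy_grid(c(chrT1 = 2000L), 1000L)
  segs <- toy_segments(grid, "chrT1", c(1, 101, 1800), c(50, 200, 1900))
  # seg1-seg2 pair: scores 10, 20, 30; seg1 intra: single score 7;
  # seg1-seg3 is ~1.6 Mb apart (within 2 Mb), seg gap 1.75Mb; make a
  # pair beyond the cap on a second call below
  cs <- toy_contacts("chrT1",
                     pos1 = c(10500, 20500, 30500, 5500, 25000),
                     pos2 = c(150500, 120500, 110500, 40500, 1850500),
                     score = c(10, 20, 30, 7, 99))
  tab <- scoreSegmentPairs(cs, segs, dMaxBp = 2e6)
  expect_s3_class(tab, "InteractionTable")
  expect_equal(pairScore(tab, "seg01", "seg02"), 20)
  expect_equal(pairScore(tab, "seg02", "seg01"), 20)  # symmetric lookup
  expect_equal(pairScore(tab, "seg01", "seg01"), 7)
  expect_equal(tab$n_contacts[tab$seg_a == "seg01" &
                                tab$seg_b == "seg02"], 3L)
  # the 1.75 Mb pair is inside the cap...
  expect_equal(pairScore(tab, "seg01", "seg03"), 99)
  # ...and outside a 1 Mb cap
  tab2 <- scoreSegmentPairs(cs, segs, dMaxBp = 1e6)
  expect_true(is.na(pairScore(tab2, "seg01", "seg03")))

  # contacts outside any segment are dropped and counted
  cs2 <- toy_contacts("chrT1", 500500, 600500, 5)
  tab3 <- scoreSegmentPairs(cs2, segs)
  expect_equal(nrow(tab3), 0L)
  expect_equal(attr(tab3, "nOutside"), 1L)
})

test_that("median pooling equals a brute-force median on random toys", {
  grid <- toy_grid(c(chrT1 = 500L), 1000L)
  segs <- toy_segments(grid, "chrT1", c(1, 101, 201, 301),
                       c(100, 200, 300, 400))
  set.seed(71)
  n <- 400
  p1 <- sample(0:399999, n)
  p2 <- sample(0:399999, n)
  cs <- toy_contacts("chrT1", pmin(p1, p2), pmax(p1, p2),
                     round(rnorm(n, 5, 3), 3))
  tab <- scoreSegmentPairs(cs, segs, dMaxBp = 2e6)
  segof <- function(pos) 1L + pos %/% 100000L  # 100-bin segments
  sa <- pmin(segof(cs$pos1), segof(cs$pos2))
  sb <- pmax(segof(cs$pos1), segof(cs$pos2))
  for (i in seq_len(nrow(tab))) {
    a <- match(tab$seg_a[i], mcols(segs)$segment_id)
    b <- match(tab$seg_b[i], mcols(segs)$segment_id)
    expect_equal(tab$median_score[i], median(cs$score[sa == a & sb == b]),
                 info = paste(a, b))
  }
  # every populated pair is present
  expect_equal(nrow(tab), nrow(unique(data.frame(sa, sb))))
})

test_that("estimateCutoff maximizes true-minus-random pair counts", {
  grid <- toy_grid(c(chrT1 = 400L), 1000L)
  segs <- toy_segments(grid, "chrT1", c(41, 141), c(60, 160))
  # dense high scores inside the two true segments, sparse low
  # background elsewhere
  set.seed(81)
  hub <- toy_contacts("chrT1",
                      pos1 = sample(40000:59999, 200, TRUE),
                      pos2 = sample(140000:159999, 200, TRUE),
                      score = 100)
  bg <- toy_contacts("chrT1",
                     pos1 = sample(200000:390000, 300, TRUE),
                     pos2 = sample(200000:390000, 300, TRUE),
                     score = rnorm(300, 0, 1))
  cs <- rbind(hub, bg)
  set.seed(82)
  est <- estimateCutoff(cs, segs, grid, nPerm = 30L)
  # grid spans the scores; the argmax keeps the true pair (median 100)
  # while excluding essentially all random placements
  expect_lte(est$cutoff, 100)
  expect_gt(est$cutoff, 0)
  expect_equal(max(est$objective),
               est$objective[match(est$cutoff, est$grid)])

  # all-identical scores: flat objective, smallest grid point returned
  flat <- toy_contacts("chrT1", c(45000, 150000), c(55000, 155000),
                       c(5, 5))
  set.seed(83)
  est2 <- estimateCutoff(flat, segs, grid, nPerm = 5L,
                         cutoffGrid = c(1, 3, 5))
  expect_equal(est2$cutoff, 1)

  # determinism under a fixed seed
  set.seed(84); c1 <- estimateCutoff(cs, segs, grid, nPerm = 10L)$cutoff
  set.seed(84); c2 <- estimateCutoff(cs, segs, grid, nPerm = 10L)$cutoff
  expect_identical(c1, c2)
})

test_that("callPTCs forms connected components under the joint rule", {
  grid <- toy_grid(c(chrT1 = 1000L), 1000L)
  segs <- toy_segments(grid, "chrT1", c(1, 201, 401, 601),
                       c(100, 300, 500, 700),
                       ids = c("A", "B", "C", "D"))
  ann <- toy_annotation(c("A", "B", "C", "D"),
                        enriched = c("A", "B", "C"))
  tab <- data.frame(seg_a = c("A", "B", "A", "C", "D"),
                    seg_b = c("B", "C", "C", "D", "D"),
                    median_score = c(20, 18, 5, 30, 40),
                    n_contacts = 5L,
                    distance_bp = c(1e5, 1e5, 3e5, 1e5, 0))
  class(tab) <- c("InteractionTable", "data.frame")

  ptcs <- callPTCs(tab, ann, segs, cutoff = 17)
  # A-B and B-C link; A-C is weak but transitivity joins all three;
  # C-D scores 30 but D is depleted -> no edge, and D's intra score 40
  # cannot rescue a depleted segment
  expect_length(ptcs, 1L)
  expect_setequal(mcols(ptcs)$members[[1]], c("A", "B", "C"))
  expect_equal(start(ptcs), 1L)
  expect_equal(end(ptcs), 500000L)

  # score exactly at the cutoff counts (inclusive >=)
  tab17 <- tab; tab17$median_score[1] <- 17
  expect_length(callPTCs(tab17, ann, segs, 17), 1L)
  tab16 <- tab; tab16$median_score[1] <- 16.999
  p2 <- callPTCs(tab16, ann, segs, 17)
  expect_setequal(unlist(mcols(p2)$members), c("B", "C"))

  # an enriched segment with a passing intra score forms a singleton
  tabi <- rbind(tab, data.frame(seg_a = "A", seg_b = "A",
                                median_score = 50, n_contacts = 3L,
                                distance_bp = 0))
  class(tabi) <- c("InteractionTable", "data.frame")
  p3 <- callPTCs(tabi, ann, segs, cutoff = 45)
  expect_length(p3, 1L)
  expect_equal(mcols(p3)$members[[1]], "A")

  expect_error(callPTCs(tab, ann, segs, Inf), "finite")
})

test_that("callPTCs equals transitive-closure components on random graphs", {
  grid <- toy_grid(c(chrT1 = 2000L), 1000L)
  set.seed(91)
  for (rep in 1:25) {
    k <- sample(3:10, 1)
    ids <- LETTERS[1:k]
    segs <- toy_segments(grid, "chrT1",
                         startBin = (seq_len(k) - 1L) * 150L + 1L,
                         endBin = (seq_len(k) - 1L) * 150L + 50L,
                         ids = ids)
    ann <- toy_annotation(ids)
    pairs <- t(utils::combn(k, 2))
    keep <- runif(nrow(pairs)) < 0.3
    score <- ifelse(keep, 20, 1)
    tab <- data.frame(seg_a = ids[pairs[, 1]], seg_b = ids[pairs[, 2]],
                      median_score = score, n_contacts = 1L,
                      distance_bp = 1e5)
    # random intra entries so singletons occur
    intra <- data.frame(seg_a = ids, seg_b = ids,
                        median_score = ifelse(runif(k) < 0.3, 20, 1),
                        n_contacts = 1L, distance_bp = 0)
    tab <- rbind(tab, intra)
    class(tab) <- c("InteractionTable", "data.frame")

    ptcs <- callPTCs(tab, ann, segs, cutoff = 17)
    got <- lapply(mcols(ptcs)$members, sort)
    got <- got[order(vapply(got, `[`, character(1), 1L))]

    edges <- tab[tab$seg_a != tab$seg_b & tab$median_score >= 17,
                 c("seg_a", "seg_b")]
    qualifying <- union(unlist(edges),
                        tab$seg_a[tab$seg_a == tab$seg_b &
                                    tab$median_score >= 17])
    want <- bf_components(sort(qualifying), as.matrix(edges))
    expect_equal(got, want, info = paste("rep", rep))
  }
})

test_that("raising the cutoff never adds edges, merges PTCs or grows membership", {
  grid <- toy_grid(c(chrT1 = 2000L), 1000L)
  k <- 8
  ids <- LETTERS[1:k]
  segs <- toy_segments(grid, "chrT1",
                       startBin = (seq_len(k) - 1L) * 200L + 1L,
                       endBin = (seq_len(k) - 1L) * 200L + 60L,
                       ids = ids)
  ann <- toy_annotation(ids)
  set.seed(92)
  pairs <- t(utils::combn(k, 2))
  tab <- data.frame(seg_a = ids[pairs[, 1]], seg_b = ids[pairs[, 2]],
                    median_score = runif(nrow(pairs), 0, 30),
                    n_contacts = 1L, distance_bp = 1e5)
  class(tab) <- c("InteractionTable", "data.frame")
  prev_edges <- Inf; prev_members <- Inf; prev_sizes <- NULL
  for (cutoff in seq(0, 32, by = 2)) {
    p <- callPTCs(tab, ann, segs, cutoff)
    ne <- nrow(attr(p, "edges"))
    nm <- sum(mcols(p)$n_segments)
    expect_lte(ne, prev_edges)
    expect_lte(nm, prev_members)
    prev_edges <- ne; prev_members <- nm
  }
})

test_that("overlapPTCs counts each query PTC once", {
  g <- function(chrom, s, e) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e))
    S4Vectors::mcols(gr)$ptc_id <- sprintf("p%d", seq_along(gr))
    gr
  }
  a <- g("chr1", c(1, 1000, 5000), c(500, 1500, 5600))
  expect_equal(overlapPTCs(a, a), 3L)
  b <- g("chr2", 1, 100)
  expect_equal(overlapPTCs(a, b), 0L)
  # one query spanning two subjects counts once
  wide <- g("chr1", 1, 1400)
  expect_equal(overlapPTCs(wide, a), 1L)
  expect_equal(overlapPTCs(a, wide), 2L)
  expect_equal(overlapPTCs(a, g("chr1", 10000, 10010)), 0L)
})
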
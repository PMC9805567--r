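test_that("callEnhancerBins requires every mark to pass jointly", {
  z <- cbind(H3K27ac = c(1.2, 1.2, 1.0, 0.9, 2.0),
             ATAC    = c(1.2, 0.5, 1.0, 2.0, 0.99),
             other   = c(-1, -1, -1, -1, -1))
  e <- callEnhancerBins(z, c("H3K27ac", "ATAC"), 1)
  expect_equal(e, c(1L, 0L, 1L, 0L, 0L))  # >= is inclusive
  expect_error(callEnhancerBins(z, c("H3K27ac", "nope")), "nope")
})

test_that("countPerSegment sums bins and conserves totals over a partition", {
  grid <- toy_grid(c(chrT1 = 10L), 1000L)
  enh <- c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L, 1L)
  segs <- toy_segments(grid, "chrT1", c(1, 5), c(4, 10))
  cts <- countPerSegment(enh, segs, grid)
  expect_equal(cts, c(3L, 3L))
  expect_equal(sum(cts), sum(enh))
  expect_equal(countPerSegment(integer(10), segs, grid), c(0L, 0L))
})

test_that("shuffleBackground is seeded, uniform and length-consistent", {
  grid <- toy_grid()
  n <- nBins(grid)

  expect_equal(shuffleBackground(10L, grid, integer(n), 50L),
               rep(0L, 50))
  expect_equal(shuffleBackground(10L, grid, rep(1L, n), 50L),
               rep(10L, 50))

  # enhancer density p, segment of L bins: mean count ~ p * L
  set.seed(5)
  enh <- rbinom(n, 1L, 0.2)
  set.seed(6)
  bg <- shuffleBackground(25L, grid, enh, 1000L)
  se <- sd(bg) / sqrt(length(bg))
  expect_lt(abs(mean(bg) - mean(enh) * 25), 3 * se + 0.05)

  # bit-identical under the same seed
  set.seed(11); a <- shuffleBackground(25L, grid, enh, 200L)
  set.seed(11); b <- shuffleBackground(25L, grid, enh, 200L)
  expect_identical(a, b)

  expect_error(shuffleBackground(10000L, grid, enh, 10L),
               "no chromosome")

  # chromosome-matched mode stays on the requested chromosome
  enh2 <- c(rep(1L, 200), rep(0L, 150))  # chrT1 all 1, chrT2 all 0
  set.seed(12)
  expect_equal(shuffleBackground(5L, grid, enh2, 100L,
                                 chromMatched = "chrT2"),
               rep(0L, 100))
})

test_that("ZINB pmf normalizes and the upper tail matches brute force", {
  for (par in list(c(0.3, 5, 2), c(0.05, 20, 0.7), c(0.8, 2, 10))) {
    K <- 0:5000
    expect_equal(sum(dzinb(K, par[1], par[2], par[3])), 1,
                 tolerance = 1e-8)
    fit <- structure(list(pi0 = par[1], mu = par[2], theta = par[3],
                          loglik = 0, converged = TRUE),
                     class = "ZINBParams")
    expect_equal(zinbPvalue(fit, 0), 1)
    for (obs in c(1L, 3L, 17L))
      expect_equal(zinbPvalue(fit, obs),
                   bf_zinb_upper(obs, par[1], par[2], par[3]),
                   tolerance = 1e-12)
  }
  # pure zero inflation: any positive observation is impossible
  degen <- structure(list(pi0 = 1, mu = NA_real_, theta = NA_real_,
                          loglik = 0, converged = FALSE),
                     class = "ZINBParams")
  expect_equal(zinbPvalue(degen, 1), 0)
  expect_equal(zinbPvalue(degen, 0), 1)
})

test_that("fitZinb recovers parameters and honors boundary cases", {
  set.seed(21)
  x <- rzinb(5000, 0.3, 5, 2)
  f <- fitZinb(x)
  expect_true(f$converged)
  expect_lt(abs(f$pi0 - 0.3) / 0.3, 0.10)
  expect_lt(abs(f$mu - 5) / 5, 0.10)
  expect_lt(abs(f$theta - 2) / 2, 0.10)

  # counts with no zeros push pi0 to ~0
  set.seed(22)
  y <- stats::rnbinom(2000, size = 5, mu = 30)
  y <- y[y > 0]
  expect_lt(fitZinb(y)$pi0, 0.02)

  expect_warning(f0 <- fitZinb(integer(100)), "degenerate")
  expect_equal(f0$pi0, 1)
  expect_false(f0$converged)

  expect_error(fitZinb(c(-1, 2)), "non-negative")
  expect_warning(fitZinb(c(0L, 1L, 2L)), "fewer than 30")
})

test_that("AIC model comparison behaves across generating models", {
  # ZINB data: ZINB wins
  set.seed(31)
  tab <- compareBackgroundModels(rzinb(1000, 0.4, 5, 2))
  expect_equal(tab$model[tab$best], "ZINB")
  expect_equal(tab$aic, 2 * tab$k_params - 2 * tab$loglik)

  # plain NB data: NB within 2 AIC of ZINB (nested, one parameter less)
  set.seed(32)
  tab2 <- compareBackgroundModels(stats::rnbinom(1000, size = 2, mu = 5))
  d <- tab2$aic[tab2$model == "NB"] - tab2$aic[tab2$model == "ZINB"]
  expect_lte(abs(d), 2 + 1e-6)

  # zero-truncated normal data: the censored model beats the plain one
  set.seed(33)
  z <- pmax(0, rnorm(1000, 1, 2))
  tab3 <- compareBackgroundModels(round(z))
  expect_lt(tab3$aic[tab3$model == "TobitNormal"],
            tab3$aic[tab3$model == "Normal"])
})

test_that("annotateSegments applies the p-value AND positive-enrichment rule", {
  grid <- toy_grid(c(chrT1 = 300L, chrT2 = 300L), 1000L)
  n <- nBins(grid)
  # dense enhancer block inside segment 1, sparse elsewhere
  set.seed(41)
  enh <- rbinom(n, 1L, 0.05)
  enh[11:40] <- 1L
  segs <- toy_segments(grid, "chrT1", c(1, 41, 151), c(40, 150, 300))
  set.seed(42)
  ann <- annotateSegments(segs, enh, grid, nShuffles = 500L)
  expect_equal(ann$label[1], "enhancer_enriched")
  expect_gt(ann$enrichment[1], 0)
  expect_lt(ann$pvalue[1], 0.05)
  expect_equal(ann$observed, countPerSegment(enh, segs, grid))
  # sparse segments stay depleted
  expect_equal(ann$label[2], "enhancer_depleted")

  # empty genome: degenerate background, observed 0 everywhere -> depleted
  set.seed(43)
  ann0 <- suppressWarnings(
    annotateSegments(segs, integer(n), grid, nShuffles = 100L))
  expect_true(all(ann0$label == "enhancer_depleted"))
  expect_true(all(ann0$pvalue == 1))

})

test_that("a significant p-value without positive enrichment stays depleted", {
  # heavy zero inflation makes even a below-expectation count land in
  # the 5% tail: one 60-bin enhancer block in a 2500-bin genome gives
  # P(hit) ~ 0.048 but a mean background count well above 1, so a
  # segment observing a single enhancer bin has p < 0.05 yet negative
  # enrichment -- and must NOT be called enriched
  grid <- toy_grid(c(chrT1 = 2500L), 1000L)
  enh <- integer(2500)
  enh[1001:1060] <- 1L
  seg <- toy_segments(grid, "chrT1", 1060, 1119)  # overlaps one bin
  set.seed(61)
  ann <- annotateSegments(seg, enh, grid, nShuffles = 2000L)
  expect_equal(ann$observed, 1L)
  expect_lt(ann$pvalue, 0.05)
  expect_lt(ann$enrichment, 0)
  expect_equal(ann$label, "enhancer_depleted")
})

test_that("annotation TSV round-trips", {
  grid <- toy_grid(c(chrT1 = 300L), 1000L)
  set.seed(51)
  enh <- rbinom(300, 1L, 0.1)
  segs <- toy_segments(grid, "chrT1", c(1, 101), c(100, 300))
  set.seed(52)
  ann <- annotateSegments(segs, enh, grid, nShuffles = 200L)
  p <- tempfile(fileext = ".tsv")
  on.exit(unlink(p))
  writeAnnotation(ann, p)
  back <- readAnnotation(p)
  expect_equal(back$segment_id, ann$segment_id)
  expect_equal(back$pvalue, ann$pvalue, tolerance = 1e-12)
  expect_equal(back$label, ann$label)
})
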
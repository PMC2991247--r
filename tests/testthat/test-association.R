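test_that("distances to nearest marker match the O(n*m) brute force", {
  lay <- ChromLayout("chrA", 10000)
  mk <- PeakSet(rep("chrA", 2), c(50, 350), c(150, 450), lay,
                summit = c(100, 400))
  q <- SiteSet(rep("chrA", 3), c(150, 5, 995), lay)
  expect_equal(markerDistances(q, mk, "summit")[1], 50)
  one <- PeakSet("chrA", 450, 550, lay, summit = 500)
  expect_equal(markerDistances(q, one, "summit")[2:3], c(495, 495))

  ## boundary mode: inside -> 0, outside -> distance to nearest edge
  p <- PeakSet("chrA", 101, 300, lay)
  qb <- SiteSet(rep("chrA", 3), c(200, 90, 320), lay)
  expect_equal(markerDistances(qb, p, "boundary"), c(0, 11, 20))

  ## sites on chromosomes without peaks are infinitely far
  lay2 <- toyLayout()
  mk2 <- PeakSet("chrA", 100, 200, lay2)
  qc <- SiteSet(c("chrA", "chrB"), c(150, 100), lay2)
  expect_equal(markerDistances(qc, mk2, "summit")[2], Inf)
  expect_error(markerDistances(qc, PeakSet(character(), numeric(),
                                           numeric(), lay2), "summit"),
               "empty", class = "rm_input_error")

  ## randomized brute-force property, both modes
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(1:8, 1); m <- sample(1:8, 1)
    qpos <- sample.int(9000, n)
    st <- sample.int(8000, m); en <- st + sample.int(500, m)
    pk <- PeakSet(rep("chrA", m), st, en, lay,
                  summit = st + floor((en - st) / 2))
    qq <- SiteSet(rep("chrA", n), qpos, lay)
    expect_equal(markerDistances(qq, pk, "summit"),
                 bruteNearest(qpos, peakSummits(pk)))
    bEdge <- vapply(qpos, function(x) {
      if (any(x >= st & x <= en)) 0 else min(abs(x - st), abs(x - en))
    }, numeric(1))
    expect_equal(markerDistances(qq, pk, "boundary"), bEdge)
  }
})

test_that("contingency tables count inclusively at the window edge", {
  lay <- ChromLayout("chrA", 100000)
  mk <- PeakSet("chrA", 49000, 51000, lay, summit = 50000)
  sites <- SiteSet(rep("chrA", 4), c(50000, 48000, 52000, 90000), lay)
  ctrl <- SiteSet(rep("chrA", 4), c(10000, 20000, 30000, 52000), lay)
  tab <- buildContingency(sites, ctrl, mk, window = 2000)
  cnt <- tableCounts(tab)
  expect_equal(unname(cnt[c("tp", "fn", "fp", "tn")]), c(3, 1, 1, 3))
  ## w = 0 with no site exactly on a summit
  tab0 <- buildContingency(SiteSet("chrA", 50001, lay), ctrl, mk, window = 0)
  expect_equal(unname(tableCounts(tab0)["tp"]), 0)
  ## direct-count oracle on a planted fixture
  fx <- plantedFixture(seed = 301, V = 100, ratio = 2)
  ds <- markerDistances(fx$sites, fx$marker)
  dc <- markerDistances(fx$controls, fx$marker)
  tabf <- buildContingency(fx$sites, fx$controls, fx$marker, 2000)
  expect_equal(unname(tableCounts(tabf)[c("tp", "fp")]),
               c(sum(ds <= 2000), sum(dc <= 2000)))
})

test_that("exact Fisher p agrees with enumeration and handles extremes", {
  mkTab <- function(tp, fn, fp, tn, w = 2000)
    new("ContingencyTable", tp = tp, fn = fn, fp = fp, tn = tn, window = w)
  ## modal table: everything as extreme
  expect_equal(fisherPvalue(mkTab(5, 5, 50, 50), "exact")$p, 1)
  ## strong association, checked against enumeration and fisher.test
  r <- fisherPvalue(mkTab(10, 0, 0, 100), "exact")
  expect_lt(r$p, 1e-6)
  expect_equal(r$p, bruteFisherP(10, 0, 0, 100), tolerance = 1e-12)
  expect_equal(r$p, stats::fisher.test(matrix(c(10, 0, 0, 100), 2))$p.value,
               tolerance = 1e-9)
  ## degenerate margins
  d <- fisherPvalue(mkTab(0, 0, 0, 0), "exact")
  expect_equal(d$p, 1)
  expect_true(d$degenerate)
  ## deterministic sweep of tables with V+C <= 200 vs the enumeration oracle
  grid <- c(1, 2, 3, 5, 8, 13, 25, 50, 100, 150)
  for (V in grid) for (C in grid) {
    if (V + C > 200) next
    for (W in unique(pmin(c(1, ceiling((V + C) / 4), ceiling((V + C) / 2)),
                          V + C))) {
      for (tp in unique(c(max(0, W - C), min(V, W),
                          round(mean(c(max(0, W - C), min(V, W))))))) {
        p <- fisherPvalue(mkTab(tp, V - tp, W - tp, C - W + tp), "exact")$p
        po <- bruteFisherP(tp, V - tp, W - tp, C - W + tp)
        expect_equal(p, po, tolerance = 1e-12)
      }
    }
  }
  ## chi2 branch stays in log space for huge tables
  big <- fisherPvalue(mkTab(4000, 1000, 5000, 45000), "auto")
  expect_equal(big$method, "chi2")
  expect_lt(big$log10p, -300)
})

test_that("Bonferroni correction caps at 1 and works in log space", {
  expect_equal(bonferroni(0.004, 10), 0.04)
  expect_equal(bonferroni(0.5, 10), 1)
  expect_equal(retroMark:::bonferroniLog10(-300, 60), -300 + log10(60))
})

test_that("normalized F score reproduces the hand-computed cases", {
  mkTab <- function(tp, fn, fp, tn)
    new("ContingencyTable", tp = tp, fn = fn, fp = fp, tn = tn, window = 2000)
  perfect <- fScore(mkTab(100, 0, 0, 1000))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$fscore, 1)
  ## all-genome null predictor: P = 0.5, R = 1, F_0.5 = 5/9
  null <- fScore(mkTab(100, 0, 1000, 0))
  expect_equal(null$precision, 0.5)
  expect_equal(null$recall, 1)
  expect_equal(null$fscore, 5 / 9)
  ## V=100, C=1000, tp=60, fp=50 -> fp'=5, P=12/13, R=3/5, F=5/6
  h <- fScore(mkTab(60, 40, 50, 950))
  expect_equal(h$precision, 12 / 13)
  expect_equal(h$recall, 3 / 5)
  expect_equal(h$fscore, 5 / 6)
  expect_error(fScore(mkTab(0, 0, 5, 5)), "V > 0", class = "rm_input_error")
  ## zero-overlap marker
  z <- fScore(mkTab(0, 100, 0, 1000))
  expect_equal(z$fscore, 0)
})

test_that("associate recovers a planted within-fraction and flags markers", {
  fx <- plantedFixture(seed = 302, V = 200, q = 0.7, s = 500)
  res <- associate(fx$sites, fx$controls, fx$marker)
  pin <- 2 * pnorm(2000 / 500) - 1
  pbg <- coverageFraction(fx$marker, fx$layout, 2000)
  expected <- 0.7 * (pin + (1 - pin) * pbg) + 0.3 * pbg
  se <- sqrt(expected * (1 - expected) / 200)
  expect_lt(abs(res@wi - expected), 3 * se)
  expect_true(res@associated)
  expect_true(res@significant)

  ## marker nowhere near anything: F = 0, not associated
  lay <- fx$layout
  far <- PeakSet("chrS1", 1, 50, lay, summit = 25, label = "far")
  sFar <- SiteSet(rep("chrS2", 20), seq(1e6, 3e6, length.out = 20), lay)
  cFar <- SiteSet(rep("chrS2", 40), seq(1.1e6, 4e6, length.out = 40), lay)
  resFar <- associate(sFar, cFar, far)
  expect_equal(resFar@fscore, 0)
  expect_false(resFar@associated)
})

test_that("window sweep is monotone in counts and peaks near the planted scale", {
  fx <- plantedFixture(seed = 303, V = 400, q = 0.7, s = 800)
  windows <- c(250, 500, 1000, 2000, 4000, 8000, 16000)
  sw <- windowSweep(fx$sites, fx$controls, fx$marker, windows)
  expect_true(all(diff(sw$wi_pct) >= 0))
  ## argmax-F within a factor of 2 of ~2x the offset scale
  wBest <- sw$window[which.max(sw$F)]
  expect_gte(wBest, 800)
  expect_lte(wBest, 3200)
  expect_error(windowSweep(fx$sites, fx$controls, fx$marker, c(2000, 1000)),
               "increasing", class = "rm_input_error")
  ## degenerate single window = genome length: recall 1
  swAll <- windowSweep(fx$sites, fx$controls, fx$marker,
                       totalLength(fx$layout))
  expect_equal(swAll$R, 1)
})

test_that("F score is stable under downsampling and control-ratio changes", {
  fx <- plantedFixture(seed = 304, V = 500, q = 0.7, s = 500, ratio = 10)
  resFull <- associate(fx$sites, fx$controls, fx$marker)
  ## downsample V 500 -> 50 with the controls of the kept sites
  keep <- withr::with_seed(1, sample.int(500, 50))
  sub <- SiteSet(siteChroms(fx$sites)[keep], sitePositions(fx$sites)[keep],
                 fx$layout)
  subCtrl <- controlsForSources(fx$controls, keep)
  resSub <- associate(sub, subCtrl, fx$marker)
  expect_lt(abs(resSub@fscore - resFull@fscore), 0.05)
  expect_gt(resFull@log10p / resSub@log10p, 5)  # -log10 p shrinks > 5-fold
  ## control ratio 1 vs 10 at fixed V
  ctrl1 <- generateMatchedControls(fx$sites, fx$resites, 1, seed = 77)
  res1 <- associate(fx$sites, ctrl1, fx$marker)
  expect_lt(abs(res1@fscore - resFull@fscore), 0.05)
})

test_that("p-value formatting uses the reporting floor", {
  expect_equal(formatPvalue(-400), "<1E-350")
  expect_equal(formatPvalue(0), "1")
  expect_equal(formatPvalue(log10(0.004)), "4E-03")
})
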
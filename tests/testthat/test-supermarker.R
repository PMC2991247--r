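test_that("marker kernel density has Gaussian shape and unit mass", {
  lay <- ChromLayout("chrA", 1e6)
  pk <- PeakSet("chrA", 499800, 500200, lay, summit = 5e5, label = "one")
  cd <- markerDensity(pk, sigma = 400)
  expect_equal(densityAt(cd, "chrA", 5e5), 1 / (400 * sqrt(2 * pi)))
  expect_equal(densityAt(cd, "chrA", 5e5 + 400),
               exp(-0.5) / (400 * sqrt(2 * pi)))
  ## two equal peaks 10 sigma apart: mass splits 0.5/0.5 per 3-sigma window
  pk2 <- PeakSet(rep("chrA", 2), c(2e5, 2e5 + 4000) - 200,
                 c(2e5, 2e5 + 4000) + 200, lay,
                 summit = c(2e5, 2e5 + 4000), label = "two")
  cd2 <- markerDensity(pk2, sigma = 400)
  grid <- seq(2e5 - 1200, 2e5 + 1200, by = 4)
  mass <- sum(densityAt(cd2, "chrA", grid)) * 4
  expect_lt(abs(mass - 0.5), 0.002)
  ## sigma policy: default is the mean peak width
  expect_equal(retroMark:::sigmaFromPolicy(pk, "width"), 401)
  expect_equal(retroMark:::sigmaFromPolicy(pk, "fixed:250"), 250)
  expect_error(markerDensity(PeakSet(character(), numeric(), numeric(), lay)),
               "empty", class = "rm_input_error")
})

test_that("composite weights follow the F-score odds", {
  lay <- ChromLayout("chrA", 1e6)
  mkPk <- function(pos, label) PeakSet(rep("chrA", length(pos)), pos - 100,
                                       pos + 100, lay, summit = pos,
                                       label = label)
  a <- mkPk(c(1e5, 2e5), "a"); b <- mkPk(c(6e5, 7e5), "b")
  ## single component collapses to the marker density
  cdA <- compositeDensity(list(a = a), 0.7)
  mdA <- markerDensity(a, sigma = retroMark:::sigmaFromPolicy(a, "width"))
  xs <- seq(0.9e5, 2.1e5, by = 500)
  expect_equal(densityAt(cdA, "chrA", xs), densityAt(mdA, "chrA", xs))
  ## equal F -> equal weights
  cdE <- compositeDensity(list(a = a, b = b), c(0.6, 0.6))
  lamE <- vapply(cdE@components, `[[`, numeric(1), "lambda")
  expect_equal(lamE, c(0.5, 0.5))
  ## F 0.8 vs 0.5 -> odds 4:1 -> weights 4/5, 1/5
  cdO <- compositeDensity(list(a = a, b = b), c(0.8, 0.5))
  lamO <- vapply(cdO@components, `[[`, numeric(1), "lambda")
  expect_equal(lamO, c(4 / 5, 1 / 5))
  expect_error(compositeDensity(list(a = a), 1), "0 < F < 1",
               class = "rm_input_error")
})

test_that("peak extraction finds, merges and faithfully scores maxima", {
  lay <- ChromLayout("chrA", 1e6)
  one <- PeakSet("chrA", 3e5 - 200, 3e5 + 200, lay, summit = 3e5,
                 label = "one")
  cd <- markerDensity(one, sigma = 400)
  pk <- extractPeaks(cd, gridStep = 10)
  expect_equal(length(pk), 1L)
  expect_lte(abs(GenomicRanges::start(pk) - 3e5), 10)
  ## two components with coincident summits merge into one summed peak
  other <- PeakSet("chrA", 3e5 - 300, 3e5 + 300, lay, summit = 3e5,
                   label = "other")
  cd2 <- compositeDensity(list(a = one, b = other), c(0.6, 0.6),
                          sigmaPolicy = "fixed:400")
  pk2 <- extractPeaks(cd2, gridStep = 10)
  expect_equal(length(pk2), 1L)
  expect_equal(GenomicRanges::mcols(pk2)$amplitude,
               densityAt(cd2, "chrA", GenomicRanges::start(pk2)))
  ## amplitudes of extracted peaks equal direct density re-evaluation
  set.seed(61)
  pos <- sort(sample.int(9e5, 30) + 5e4)
  multi <- PeakSet(rep("chrA", 30), pos - 150, pos + 150, lay, summit = pos,
                   label = "multi")
  cdm <- markerDensity(multi, sigma = 300)
  pkm <- extractPeaks(cdm, gridStep = 10)
  expect_equal(GenomicRanges::mcols(pkm)$amplitude,
               densityAt(cdm, "chrA", GenomicRanges::start(pkm)))
  ## ranked by amplitude, descending
  expect_true(all(diff(GenomicRanges::mcols(pkm)$amplitude) <= 0))
  expect_error(extractPeaks(cdm, gridStep = 100), "gridStep",
               class = "rm_input_error")
})

test_that("threshold selection maximizes training F with smallest-k ties", {
  fx <- plantedFixture(seed = 401, V = 200, nPeaks = 300)
  cd <- compositeDensity(list(m = fx$marker), 0.7)
  pk <- extractPeaks(cd, 10)
  sel <- selectThreshold(pk, fx$sites, fx$controls)
  expect_true(all(sel$curve$fscore <= sel$trainF))
  expect_equal(sel$trainF, sel$curve$fscore[sel$curve$k == sel$kStar])
  ## first k attaining the max is chosen
  expect_equal(sel$kStar, min(sel$curve$k[sel$curve$fscore == sel$trainF]))
  ## a one-value grid returns that value
  sel1 <- selectThreshold(pk, fx$sites, fx$controls, kGrid = 25)
  expect_equal(sel1$kStar, 25)
  expect_equal(length(sel1$peaks), 25L)
})

test_that("supermarker fit prefers informative subsets over noise", {
  fx <- plantedFixture(seed = 402, V = 250, nPeaks = 300)
  noise <- suppressWarnings(simulatePeakSet(fx$layout, 300, 400, seed = 403,
                                            label = "noise"))
  model <- fitSupermarker(list(planted = fx$marker, noise = noise),
                          fx$sites, fx$controls)
  expect_true("planted" %in% model@markers)
  singleF <- model@meta$candidateF
  ## subset search includes singletons; allow grid-quantization slack
  expect_gte(model@trainF, max(singleF) - 0.01)
  ## one candidate: the model is the thresholded single marker
  m1 <- fitSupermarker(list(planted = fx$marker), fx$sites, fx$controls)
  expect_identical(m1@markers, "planted")
  expect_equal(unname(m1@weights), 1)
  ## mixture weights of the chosen subset sum to 1
  expect_equal(sum(model@weights), 1)
})

test_that("cross-validation partitions cleanly and generalizes", {
  fx <- plantedFixture(seed = 404, V = 150, nPeaks = 300, ratio = 5)
  second <- suppressWarnings(simulatePeakSet(fx$layout, 250, 500, seed = 405,
                                             label = "second"))
  cv1 <- crossvalidateSupermarker(list(a = fx$marker, b = second), fx$sites,
                                  fx$controls, folds = 5, seed = 9)
  cv2 <- crossvalidateSupermarker(list(a = fx$marker, b = second), fx$sites,
                                  fx$controls, folds = 5, seed = 9)
  expect_identical(cv1@perFold, cv2@perFold)   # seed-deterministic
  ## folds partition the sites with sizes differing by at most 1
  expect_equal(sum(cv1@perFold$nTest), length(fx$sites))
  expect_lte(diff(range(cv1@perFold$nTest)), 1)
  ## homogeneous synthetic data: held-out F close to training F
  s <- cvSummary(cv1)
  expect_lt(abs(s["meanTestF"] - s["meanTrainF"]), 0.1)
  expect_error(crossvalidateSupermarker(list(a = fx$marker), fx$sites,
                                        fx$controls, folds = 200),
               "folds", class = "rm_input_error")
  plain <- SiteSet(siteChroms(fx$controls), sitePositions(fx$controls),
                   fx$layout)
  expect_error(crossvalidateSupermarker(list(a = fx$marker), fx$sites,
                                        plain, folds = 5),
               "ControlSet", class = "rm_input_error")
})

test_that("locus probabilities are exact Gaussian masses summing to 1", {
  m <- singlePeakModel()
  expect_equal(locusProbability(m, "chrA", 1, 1e6), 1, tolerance = 1e-9)
  expect_equal(locusProbability(m, "chrA", 5e5 - 1200, 5e5 + 1200),
               2 * pnorm(3) - 1, tolerance = 1e-4)
  expect_lt(locusProbability(m, "chrA", 9e5, 9.5e5), 1e-6)
  expect_error(locusProbability(m, "chrA", 0, 10), "bounds",
               class = "rm_input_error")
  ## multi-peak fitted model integrates to 1 over the genome
  fx <- plantedFixture(seed = 406, V = 150, nPeaks = 200)
  model <- fitSupermarker(list(m = fx$marker), fx$sites, fx$controls)
  total <- sum(locusProbability(model, chromNames(fx$layout),
                                c(1, 1), unname(chromLengths(fx$layout))))
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("JSON serialization round-trips locus probabilities exactly", {
  fx <- plantedFixture(seed = 407, V = 120, nPeaks = 200)
  model <- fitSupermarker(list(m = fx$marker), fx$sites, fx$controls)
  f <- withr::local_tempfile(fileext = ".json")
  writeSupermarker(model, f)
  back <- readSupermarker(f)
  set.seed(71)
  chrom <- sample(chromNames(fx$layout), 100, TRUE)
  start <- sample.int(4e6, 100)
  end <- start + sample.int(1e5, 100)
  expect_equal(locusProbability(back, chrom, start, end),
               locusProbability(model, chrom, start, end),
               tolerance = 1e-12)
  expect_identical(back@markers, model@markers)
  expect_equal(back@trainF, model@trainF)
  ## Gamma* BED export carries the amplitude in the score column
  fb <- withr::local_tempfile(fileext = ".bed")
  exportSupermarkerBed(model, fb)
  bed <- read.table(fb)
  expect_equal(nrow(bed), model@kStar)
})

test_that("density-site correlation behaves across association regimes", {
  lay <- ChromLayout(c("chrA", "chrB"), c(5e6, 5e6))
  set.seed(81)
  pos <- sort(sample.int(4.9e6, 150) + 5e4)
  pk <- PeakSet(rep("chrA", 150), pos - 200, pos + 200, lay, summit = pos,
                label = "clustered")
  ## sites drawn from the model's own mixture
  mkSites <- function(n, model) {
    amp <- GenomicRanges::mcols(model@peaks)$amplitude
    j <- sample.int(length(amp), n, TRUE, prob = amp)
    p <- round(GenomicRanges::start(model@peaks)[j] +
               rnorm(n, 0, model@sigma))
    SiteSet(as.character(GenomicRanges::seqnames(model@peaks))[j],
            pmin(pmax(p, 1), 5e6), lay)
  }
  trainSites <- SiteSet(rep("chrA", 300),
                        pmin(pmax(pos[sample.int(150, 300, TRUE)] +
                                  round(rnorm(300, 0, 300)), 1), 5e6), lay)
  trainCtrl <- SiteSet(rep(c("chrA", "chrB"), each = 1500),
                       sample.int(5e6, 3000), lay)
  model <- fitSupermarker(list(m = pk), trainSites, trainCtrl)
  rs <- vapply(1:3, function(k) {
    set.seed(90 + k)
    densityCorrelation(model, mkSites(2000, model))$r
  }, numeric(1))
  expect_true(all(rs > 0.7))
  ## uniform sites vs clustered peaks: no correlation
  ru <- vapply(1:3, function(k) {
    set.seed(95 + k)
    u <- SiteSet(rep(c("chrA", "chrB"), each = 1000),
                 sample.int(5e6, 2000), lay)
    densityCorrelation(model, u)$r
  }, numeric(1))
  expect_true(all(abs(ru) < 0.1))
  ## counts proportional to density give r ~ 1
  dc <- densityCorrelation(model, mkSites(2000, model))
  mass <- dc$windows$density
  propSites <- do.call(rbind, lapply(which(mass > 0), function(i) {
    n <- round(mass[i] * 5e4)
    if (n == 0) return(NULL)
    data.frame(chrom = dc$windows$chrom[i],
               pos = (i - 1) %% 500 * 10000 + seq_len(n))
  }))
  ## rebuild positions inside each window on chrA/chrB tiling
  propSS <- SiteSet(propSites$chrom, propSites$pos +
                      ifelse(propSites$chrom == "chrB", 0, 0), lay)
  rP <- densityCorrelation(model, propSS)$r
  expect_gt(rP, 0.999)
  expect_error(densityCorrelation(model, trainSites, window = 4e6),
               "windows", class = "rm_input_error")
})
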
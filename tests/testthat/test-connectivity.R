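test_that("nuisance regression projects out the confound space exactly", {
  set.seed(2)
  T <- 120
  motion <- matrix(rnorm(T * 6), T, 6)
  # a signal that IS a motion regressor becomes numerically zero
  sig <- rbind(motion[, 3], rnorm(T))
  out <- preprocessTimeseries(sig, list(motion = motion), trS = 1)
  expect_lt(max(abs(out[1, ])), 1e-8)
  expect_lt(abs(mean(out[2, ])), 1e-10)
})

test_that("band-pass keeps 0.05 Hz and removes 0.2 Hz at TR 1 s", {
  tm <- 0:499
  pass <- sin(2 * pi * 0.05 * tm)
  stop <- sin(2 * pi * 0.2 * tm)
  out <- preprocessTimeseries(rbind(pass, stop), NULL, c(0.01, 0.1), 1)
  mid <- 100:400                       # avoid filter edge transients
  expect_gte(max(abs(out[1, mid])), 0.95)
  expect_lte(max(abs(out[2, mid])), 0.05)
  expect_error(preprocessTimeseries(rbind(pass), NULL, c(0.01, 0.6), 1),
               "Nyquist")
})

test_that("white noise loses roughly the stop-band variance share", {
  set.seed(4)
  x <- matrix(rnorm(30 * 2000), 30)
  out <- preprocessTimeseries(x, NULL, c(0.01, 0.1), 1)
  ratio <- mean(apply(out, 1, var)) / mean(apply(x, 1, var))
  # passband mass = (0.1 - 0.01)/0.5 = 0.18 of white-noise variance
  expect_gt(ratio, 0.12)
  expect_lt(ratio, 0.25)
})

test_that("correlation matrices: self-correlation, atanh, pair count", {
  set.seed(6)
  x <- rnorm(50)
  sig <- rbind(a = x, b = x, c = rnorm(50))
  expect_warning(pf <- pearsonFisherMatrix(rbind(sig, d = rep(1, 50))),
                 "constant")
  r <- cmValues(pf$r)
  expect_equal(r["a", "b"], 1)
  expect_true(all(is.finite(cmValues(pf$z))))
  expect_true(all(r["d", c("a", "b", "c")] == 0))
  expect_equal(atanh(0.9), 1.47222, tolerance = 1e-5)
  n <- 171
  fake <- matrix(rnorm(n * 10), n)
  expect_equal(pearsonFisherMatrix(fake)$nPairs, 14535)
})

test_that("group edge Z matches the hand-computed t and its normal deviate", {
  mkz <- function(v) {
    m <- matrix(0, 2, 2); m[1, 2] <- m[2, 1] <- v
    ConnectivityMatrix(m, "z", c("1", "2"))
  }
  gz <- groupEdgeZ(lapply(c(0.5, 0.6, 0.7, 0.8), mkz))
  # t = mean/sd*sqrt(4) = 10.0698; z = qnorm(pt(t, 3)) = 3.0778
  expect_equal(cmValues(gz)[1, 2], 3.077781, tolerance = 1e-5)
  gzNeg <- groupEdgeZ(lapply(-c(0.5, 0.6, 0.7, 0.8), mkz))
  expect_equal(cmValues(gzNeg)[1, 2], -cmValues(gz)[1, 2],
               tolerance = 1e-12)
  gz0 <- groupEdgeZ(lapply(c(0, 0, 0), mkz))
  expect_equal(cmValues(gz0)[1, 2], 0)
  # zero-variance edge gets the flagged sentinel
  gzc <- groupEdgeZ(lapply(c(0.5, 0.5, 0.5), mkz))
  expect_equal(cmValues(gzc)[1, 2], 10)
  expect_true(attr(gzc, "flagged")[1, 2])
})

test_that("thresholding keeps ties and matches a brute-force edge count", {
  set.seed(8)
  n <- 40
  z <- matrix(rnorm(n * n, 0, 2), n, n)
  z <- (z + t(z)) / 2; diag(z) <- 0
  z[2, 5] <- z[5, 2] <- 2.3            # exact tie kept
  cm <- ConnectivityMatrix(z, "group_z")
  bin <- thresholdBinarize(cm, 2.3)
  expect_equal(cmValues(bin)[2, 5], 1)
  brute <- sum(abs(z[upper.tri(z)]) >= 2.3)
  expect_equal(networkMetrics(bin)$nEdges, brute)
  low <- thresholdBinarize(ConnectivityMatrix(z * 1e-3, "group_z"), 2.3)
  expect_equal(networkMetrics(low)$nEdges, 0)
  expect_true(is.na(networkMetrics(low)$averagePathLength))
})

test_that("network metrics: complete graph, path graph, density identity", {
  n <- 7
  cm <- ConnectivityMatrix(matrix(1, n, n) - diag(n), "binary")
  m <- networkMetrics(cm)
  expect_true(all(m$degree == n - 1))
  expect_equal(m$density, 1)
  expect_equal(m$averagePathLength, 1)
  # path graph 1-2-3-4
  a <- matrix(0, 4, 4)
  a[cbind(1:3, 2:4)] <- 1; a <- a + t(a)
  mp <- networkMetrics(ConnectivityMatrix(a, "binary"))
  expect_equal(unname(mp$degree), c(1, 2, 2, 1))
  expect_equal(mp$density, 0.5)
  expect_equal(mp$averagePathLength, 5 / 3)
  # printed average degrees vs densities at N = 171
  expect_equal(round(20.83 / 170, 3), 0.123)
  expect_equal(round(12.78 / 170, 3), 0.075)
})

test_that("graph metrics agree with an independent brute-force oracle", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    a <- matrix(rbinom(n * n, 1, runif(1, 0.1, 0.5)), n, n)
    a <- pmax(a, t(a)); diag(a) <- 0
    m <- networkMetrics(ConnectivityMatrix(a, "binary"))
    expect_equal(unname(m$degree), rowSums(a))
    expect_equal(m$nEdges, sum(a) / 2)
    expect_equal(m$density, sum(a) / (n * (n - 1)))
    d <- floydWarshall(a)
    off <- d[upper.tri(d)]
    apl <- if (any(is.finite(off) & off > 0))
      mean(off[is.finite(off)]) else NA_real_
    expect_equal(m$averagePathLength, apl)
    expect_equal(m$nDisconnectedPairs, 2 * sum(!is.finite(off)))
    expect_true(all(m$degree <= n - 1))
    expect_equal(sum(m$degree), 2 * m$nEdges)
  }
})

test_that("kNN clustering separates blocks and collapses at k = N-1", {
  z <- matrix(0.1, 8, 8)
  z[1:4, 1:4] <- 5; z[5:8, 5:8] <- 5
  diag(z) <- 0
  cm <- ConnectivityMatrix(z, "group_z", as.character(1:8))
  mod <- clusterNodes(cm, k = 2)
  expect_equal(length(unique(mod)), 2L)
  expect_equal(length(unique(mod[1:4])), 1L)
  expect_equal(length(unique(clusterNodes(cm, k = 7))), 1L)
  expect_error(clusterNodes(cm, k = 0), "k must")
})

test_that("kNN modules recover the generator's modular structure", {
  skip_if_not_installed("mclust")
  cfg <- simConfig(seed = 12, boldAttenuation = 1, boldSubjectSdZ = 0,
                   boldBaseCor = 0.6, boldMotionAmp = 0, boldWmCsfAmp = 0,
                   boldDriftAmp = 0, boldNOutliers = 0L)
  atlas <- makePhantomAtlas(cfg)
  study <- simulateBoldStudy(cfg, atlas)
  cg <- connectivityByGroup(study, preprocess = FALSE)
  # four well-populated modules
  keep <- atlasRegions(atlas)$region_group %in%
    c("thalamus", "hippocampus", "basal ganglia", "cerebellum")
  gz <- cmValues(cg$sham$groupZ)[keep, keep]
  cm <- ConnectivityMatrix(gz, "group_z",
                           nodeLabels(cg$sham$groupZ)[keep])
  mod <- clusterNodes(cm, k = 4)
  truth <- study$groundTruth$moduleOf[nodeLabels(cm)]
  ari <- mclust::adjustedRandIndex(mod, truth)
  expect_gte(ari, 0.9)
})

test_that("Fisher Z is odd, monotone, and inverts tanh", {
  x <- seq(-5, 5, by = 0.25)
  expect_equal(atanh(tanh(x)), x, tolerance = 1e-12)
  expect_true(all(diff(atanh(seq(-0.99, 0.99, 0.01))) > 0))
  expect_equal(atanh(-0.5), -atanh(0.5))
})

test_that("degree comparison: identical nets unflagged, constant shift uses exact floor", {
  regions <- data.frame(label_id = 1:5, area_name = letters[1:5],
                        hemisphere = "left", region_group = "thalamus")
  mk <- function(deg) list(degree = setNames(deg, 1:5))
  same <- compareDegreeByRegion(mk(c(5, 6, 7, 8, 9)),
                                mk(c(5, 6, 7, 8, 9)), regions)
  expect_false(same$byRegion$flagged)
  expect_equal(same$byRegion$p, 1)
  shift <- compareDegreeByRegion(mk(c(5, 6, 7, 8, 9)),
                                 mk(c(1, 2, 3, 4, 5)), regions)
  # all paired differences equal -4: exact signed-rank floor at n = 5
  expect_equal(shift$byRegion$p, 0.0625)
  expect_equal(shift$byRegion$test, "signed_rank_floor")
  expect_equal(shift$byRegion$direction, -1)
  expect_error(compareDegreeByRegion(mk(1:5),
                                     list(degree = setNames(1:5, 2:6)),
                                     regions),
               "node sets")
})

test_that("attenuated thalamic coupling lowers thalamic and global degree", {
  cfg <- simConfig(seed = 14, boldAffectedGroups = "thalamus")
  atlas <- makePhantomAtlas(cfg)
  study <- simulateBoldStudy(cfg, atlas)
  cg <- connectivityByGroup(study)
  cmp <- compareDegreeByRegion(cg$sham$metrics, cg$impacted$metrics,
                               atlasRegions(atlas))
  thal <- cmp$byRegion[cmp$byRegion$region_group == "thalamus", ]
  expect_true(thal$flagged)
  expect_equal(thal$direction, -1)
  expect_lt(cg$impacted$metrics$averageDegree,
            cg$sham$metrics$averageDegree)
})
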
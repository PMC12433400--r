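# forward-simulate a known tensor through the b-table
forwardSignal <- function(D, bt, s0 = 500) {
  g <- t(bt$bvecs)
  s0 * exp(-bt$bvals * rowSums((g %*% D) * g))
}

test_that("noiseless log-linear fit recovers a known tensor to 1e-9", {
  bt <- defaultBTable(1000)
  D <- diag(c(1.7, 0.3, 0.3) * 1e-3)
  fit <- fitTensorLogLinear(forwardSignal(D, bt), bt)
  expect_lt(max(abs(fit@tensors[1, ] -
                    c(diag(D), 0, 0, 0))), 1e-9)
  expect_lt(max(abs(tensorEvals(fit)[1, ] -
                    sort(diag(D), decreasing = TRUE))), 1e-9)
  expect_equal(tensorFlags(fit)[1], 0L)
})

test_that("isotropic noiseless signals give three equal eigenvalues", {
  bt <- defaultBTable(1000)
  fit <- fitTensorLogLinear(forwardSignal(diag(rep(8e-4, 3)), bt), bt)
  ev <- tensorEvals(fit)[1, ]
  expect_lt(diff(range(ev)), 1e-9)
})

test_that("voxels with nonpositive signals are flagged and excluded", {
  bt <- defaultBTable(1000)
  s <- forwardSignal(diag(rep(8e-4, 3)), bt)
  bad <- s; bad[3] <- 0
  fit <- fitTensorLogLinear(rbind(s, bad), bt)
  expect_equal(tensorFlags(fit), c(0L, 1L))
  expect_true(all(is.na(fit@tensors[2, ])))
  maps <- scalarMaps(fit)
  expect_true(is.na(maps$adc[2]) && is.na(maps$fa[2]))
})

test_that("per-volume exclusion masks drop the flagged acquisitions", {
  bt <- defaultBTable(1000)
  D <- diag(c(1.2, 0.5, 0.5) * 1e-3)
  s <- forwardSignal(D, bt)
  sCorrupt <- s
  sCorrupt[5] <- s[5] * 10          # motion-artifact volume
  fit <- fitTensorLogLinear(sCorrupt, bt, excludeVolumes = 5)
  expect_lt(max(abs(fit@tensors[1, ] - c(diag(D), 0, 0, 0))), 1e-9)
  expect_error(fitTensorLogLinear(s, bt, excludeVolumes = 2:6), ">= 7")
})

test_that("ADC and FA match hand-evaluated closed forms", {
  bt <- defaultBTable(1000)
  fit <- fitTensorLogLinear(forwardSignal(diag(c(1.7, 0.3, 0.3) * 1e-3), bt),
                            bt)
  maps <- scalarMaps(fit)
  expect_equal(maps$adc[1], 0.7666667e-3, tolerance = 1e-6)
  # sqrt(3/2)*sqrt(sum((l-mean)^2))/sqrt(sum(l^2)) for (1.7,0.3,0.3)e-3
  expect_equal(maps$fa[1], 0.7990222, tolerance = 1e-6)
  # limits: isotropic -> 0, rank-1 -> 1, all-zero -> 0
  iso <- new("TensorFit", tensors = matrix(0, 1, 6), s0 = 1,
             evals = matrix(c(1, 1, 1) * 1e-3, 1), flag = 0L)
  expect_equal(scalarMaps(iso)$fa, 0)
  r1 <- new("TensorFit", tensors = matrix(0, 1, 6), s0 = 1,
            evals = matrix(c(1e-3, 0, 0), 1), flag = 0L)
  expect_equal(scalarMaps(r1)$fa, 1)
  z <- new("TensorFit", tensors = matrix(0, 1, 6), s0 = 1,
           evals = matrix(0, 1, 3), flag = 0L)
  expect_equal(scalarMaps(z)$fa, 0)
})

test_that("FA is invariant to tensor rotation and ADC to direction permutation", {
  set.seed(42)
  bt <- defaultBTable(1000)
  D0 <- diag(c(1.5, 0.4, 0.25) * 1e-3)
  ref <- scalarMaps(fitTensorLogLinear(forwardSignal(D0, bt), bt))
  for (i in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    D <- q %*% D0 %*% t(q)
    m <- scalarMaps(fitTensorLogLinear(forwardSignal(D, bt), bt))
    expect_equal(m$fa, ref$fa, tolerance = 1e-9)
    expect_equal(m$adc, ref$adc, tolerance = 1e-9)
  }
  perm <- c(1, sample(2:11))
  btp <- list(bvals = bt$bvals[perm], bvecs = bt$bvecs[, perm])
  class(btp) <- "BTable"
  mp <- scalarMaps(fitTensorLogLinear(forwardSignal(D0, btp), btp))
  expect_equal(mp$adc, ref$adc, tolerance = 1e-12)
})

test_that("noiseless simulate -> fit -> scalars round trip is exact to 1e-6", {
  cfg <- tinyConfig(dwiNoiseSd = 0)
  atlas <- tinyAtlas(cfg)
  dwi <- simulateDwiStudy(cfg, atlas)
  s <- dwi$subjects[[1]]
  fit <- fitTensorLogLinear(matrix(volData(s$volume), ncol = 11),
                            dwi$btable)
  agg <- aggregateRegionalScalars(scalarMaps(fit), atlas, s$id, s$group)
  gt <- dwi$groundTruth[dwi$groundTruth$subject_id == s$id, ]
  m <- merge(agg, gt, by = "label_id")
  expect_lt(max(abs(m$mean_adc / m$md_true - 1)), 1e-6)
  expect_lt(max(abs(m$mean_fa / m$fa_true - 1)), 1e-6)
})

test_that("constant maps aggregate to the constant; empty areas warn", {
  atlas <- tinyAtlas()
  n <- prod(dim(atlasLabels(atlas)))
  agg <- aggregateRegionalScalars(list(adc = rep(7e-4, n),
                                       fa = rep(0.3, n)), atlas)
  expect_true(all(agg$mean_adc == 7e-4))
  expect_true(all(agg$mean_fa == 0.3))
  reg <- rbind(atlasRegions(atlas),
               data.frame(label_id = 99L, area_name = "ghost",
                          hemisphere = "left", region_group = "cerebrum"))
  atlas2 <- LabelAtlas(atlasLabels(atlas), reg)
  expect_warning(aggregateRegionalScalars(list(adc = rep(1, n),
                                               fa = rep(1, n)), atlas2),
                 "99")
})

test_that("identical groups are not flagged by the regional KW test", {
  tbl <- data.frame(group = rep(c("sham", "impacted"), each = 8),
                    label_id = rep(1:8, 2),
                    region_group = "thalamus",
                    mean_adc = rep(seq(1, 8), 2))
  res <- compareRegionsNonparametric(tbl, "mean_adc")
  expect_false(res$flagged)
  expect_true(is.na(res$wilcox_p))
})

test_that("rank-sum p for fully separated 4 vs 4 matches exact enumeration", {
  tbl <- data.frame(group = rep(c("sham", "impacted"), each = 4),
                    label_id = c(1:4, 1:4),
                    region_group = "basal ganglia",
                    mean_adc = c(1, 2, 3, 4, 10, 11, 12, 13))
  res <- compareRegionsNonparametric(tbl, "mean_adc")
  expect_true(res$flagged)
  pOracle <- rankSumExactP(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_equal(pOracle, 2 / 70, tolerance = 1e-12)
  expect_equal(res$wilcox_p, pOracle, tolerance = 1e-9)
  expect_equal(res$direction, 1)     # impacted median higher
})

test_that("simulated basal-ganglia ADC shift is flagged with the right direction", {
  cfg <- simConfig(seed = 17)
  atlas <- makePhantomAtlas(cfg)
  dwi <- simulateDwiStudy(cfg, atlas)
  scal <- do.call(rbind, lapply(dwi$subjects, function(s) {
    fit <- fitTensorLogLinear(matrix(volData(s$volume), ncol = 11),
                              dwi$btable)
    aggregateRegionalScalars(scalarMaps(fit), atlas, s$id, s$group)
  }))
  scal <- scal[scal$region_group != "blood", ]
  res <- compareRegionsNonparametric(scal, "mean_adc")
  bg <- res[res$region_group == "basal ganglia", ]
  expect_true(bg$flagged)
  expect_equal(bg$direction, -1)     # impacted ADC lower
})
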
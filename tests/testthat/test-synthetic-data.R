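test_that("phantom atlas is deterministic, complete and guarded", {
  cfg <- simConfig(seed = 1, grid = c(24, 24, 24), nRegions = 12)
  a1 <- makePhantomAtlas(cfg)
  a2 <- makePhantomAtlas(cfg)
  expect_identical(atlasLabels(a1), atlasLabels(a2))
  expect_identical(atlasRegions(a1), atlasRegions(a2))
  grp <- atlasRegions(a1)$region_group
  expect_setequal(unique(grp),
                  c("thalamus", "hippocampus", "basal ganglia",
                    "cerebellum", "cerebrum", "blood"))
  expect_equal(sum(grp == "blood"), 1L)
  expect_error(makePhantomAtlas(simConfig(grid = c(2, 2, 2), nRegions = 9)),
               "too small")
})

test_that("uncoupled BOLD regions are near-independent", {
  cfg <- tinyConfig(boldBaseCor = 0, boldMotionAmp = 0, boldWmCsfAmp = 0,
                    boldDriftAmp = 0, boldNOutliers = 0L)
  study <- simulateBoldStudy(cfg, tinyAtlas(cfg))
  r <- cmValues(pearsonFisherMatrix(study$subjects[[1]]$signals)$r)
  off <- abs(r[upper.tri(r)])
  T <- cfg$nVolumes
  expect_gt(mean(off < 4 / sqrt(T)), 0.9)
})

test_that("two regions sharing a factor at c = 0.9 correlate as predicted", {
  # closed form: corr = c; sample estimate within the Fisher-Z 95% band
  cfg <- tinyConfig(seed = 5, boldBaseCor = 0.9, boldSubjectSdZ = 0,
                    boldMotionAmp = 0, boldWmCsfAmp = 0, boldDriftAmp = 0,
                    boldNOutliers = 0L)
  study <- simulateBoldStudy(cfg, tinyAtlas(cfg))
  sig <- study$subjects[[1]]$signals
  mods <- study$groundTruth$moduleOf
  thal <- names(mods)[mods == "thalamus"][1:2]
  r <- cor(sig[thal[1], ], sig[thal[2], ])
  T <- cfg$nVolumes
  expect_lt(abs(atanh(r) - atanh(0.9)), 1.96 / sqrt(T - 3))
})

test_that("attenuation lowers mean within-group correlation in affected regions", {
  rimp <- rsham <- numeric(0)
  for (seed in 1:10) {
    cfg <- tinyConfig(seed = seed, boldAttenuation = 0.5,
                      boldAffectedGroups = "thalamus",
                      boldMotionAmp = 0, boldWmCsfAmp = 0,
                      boldDriftAmp = 0, boldNOutliers = 0L)
    study <- simulateBoldStudy(cfg, tinyAtlas(cfg))
    mods <- study$groundTruth$moduleOf
    thal <- names(mods)[mods == "thalamus"]
    for (s in study$subjects) {
      r <- cor(t(s$signals[thal, ]))
      val <- mean(r[upper.tri(r)])
      if (s$group == "impacted") rimp <- c(rimp, val)
      else rsham <- c(rsham, val)
    }
  }
  expect_lt(mean(rimp), mean(rsham))
})

test_that("generators are bit-reproducible for a fixed seed and config", {
  cfg <- tinyConfig(seed = 42)
  atlas <- tinyAtlas(cfg)
  b1 <- simulateBoldStudy(cfg, atlas)
  b2 <- simulateBoldStudy(cfg, atlas)
  expect_identical(b1$subjects[[3]]$signals, b2$subjects[[3]]$signals)
  q1 <- simulateQuteceStudy(cfg, atlas)
  q2 <- simulateQuteceStudy(cfg, atlas)
  expect_identical(q1$regional, q2$regional)
  d1 <- simulateDwiStudy(cfg, atlas)
  d2 <- simulateDwiStudy(cfg, atlas)
  expect_identical(volData(d1$subjects[[1]]$volume),
                   volData(d2$subjects[[1]]$volume))
  t1 <- simulateBehaviorTracks(cfg)
  t2 <- simulateBehaviorTracks(cfg)
  expect_identical(t1$tracks[[1]], t2$tracks[[1]])
  expect_identical(t1$nor, t2$nor)
})

test_that("noise-free contrast study recovers constant or drifting CBV exactly", {
  cfg <- tinyConfig(qcbvNoiseSd = 0, nLeakSubjectsImpacted = 0L,
                    nLeakSubjectsSham = 0L)
  qs <- simulateQuteceStudy(cfg, tinyAtlas(cfg))
  tc <- qcbvRegionalTimecourse(qs$regional, bloodLabel(tinyAtlas(cfg)))
  spread <- tapply(tc$qcbv, paste(tc$subject_id, tc$label_id),
                   function(x) diff(range(x)))
  expect_lt(max(spread), 1e-12)

  # a leak of 1e-5 /s over 1800 s raises qCBV by exactly 0.018
  cfg2 <- tinyConfig(qcbvNoiseSd = 0, leakSlope = 1e-5,
                     nLeakSubjectsImpacted = 8L, nLeakRegionsImpacted = 11L,
                     nLeakSubjectsSham = 0L)
  qs2 <- simulateQuteceStudy(cfg2, tinyAtlas(cfg2))
  tc2 <- qcbvRegionalTimecourse(qs2$regional, bloodLabel(tinyAtlas(cfg2)))
  one <- tc2[tc2$subject_id == "impacted_1" & tc2$label_id == 1, ]
  one <- one[order(one$time_s), ]
  expect_equal(one$qcbv[length(one$qcbv)] - one$qcbv[1], 0.018,
               tolerance = 1e-12)
})

test_that("leak template has the configured subject and region counts", {
  cfg <- simConfig(seed = 9)
  qs <- simulateQuteceStudy(cfg, makePhantomAtlas(cfg))
  gt <- qs$groundTruth
  leakBySubj <- tapply(gt$leak, gt$subject_id, sum)
  imp <- leakBySubj[grep("impacted", names(leakBySubj))]
  sham <- leakBySubj[grep("sham", names(leakBySubj))]
  expect_equal(sum(imp > 0), 4L)
  expect_true(all(imp[imp > 0] == 12))
  expect_equal(sum(sham > 0), 2L)
  expect_true(all(sham[sham > 0] == 2))
})

test_that("voxelwise and regional contrast paths agree on the noiseless mean", {
  cfg <- tinyConfig(qcbvNoiseSd = 0)
  atlas <- tinyAtlas(cfg)
  vox <- simulateQuteceStudy(cfg, atlas, voxelwise = TRUE)
  reg <- simulateQuteceStudy(cfg, atlas, voxelwise = FALSE)
  expect_equal(vox$regional$post_mean, reg$regional$post_mean,
               tolerance = 1e-10)
})

test_that("regional QUTE-CE means match the noiseless construction within noise", {
  cfg <- tinyConfig(seed = 21)
  atlas <- tinyAtlas(cfg)
  vox <- simulateQuteceStudy(cfg, atlas, voxelwise = TRUE)
  cfg0 <- tinyConfig(seed = 21, qcbvNoiseSd = 0)
  ref <- simulateQuteceStudy(cfg0, atlas, voxelwise = FALSE)
  sdI <- cfg$qcbvNoiseSd * cfg$contrastStep
  dev <- abs(vox$regional$post_mean - ref$regional$post_mean) /
    (sdI / sqrt(vox$regional$n_voxels))
  expect_gte(mean(dev < 3), 0.985)   # 3-sigma bound holds as a rate
  expect_true(all(dev < 5))
})

test_that("isotropic noiseless DWI has identical signal in all directions", {
  bt <- defaultBTable(1000)
  lam <- 0.8e-3
  sig <- 500 * exp(-bt$bvals * lam)   # g' D g = lam for unit g, D = lam I
  expect_equal(length(unique(round(sig[-1], 9))), 1L)
})

test_that("simulated DWI signals equal the closed-form tensor forward model", {
  cfg <- tinyConfig(dwiNoiseSd = 0, dwiAreaJitter = 0, dwiSubjectJitter = 0)
  atlas <- tinyAtlas(cfg)
  dwi <- simulateDwiStudy(cfg, atlas)
  s <- dwi$subjects[[1]]
  gt <- dwi$groundTruth[dwi$groundTruth$subject_id == s$id, ]
  flat <- matrix(volData(s$volume), ncol = length(dwi$btable$bvals))
  lab <- as.vector(atlasLabels(atlas))
  # pick one voxel in region 1; its tensor is axially symmetric around
  # some rotation, but the b0 signal and the mean ADC across a full
  # direction shell follow from (md, fa) alone
  v <- which(lab == 1)[1]
  expect_equal(flat[v, 1], cfg$dwiS0)
  adcDir <- -log(flat[v, -1] / cfg$dwiS0) / cfg$bValue
  expect_true(all(adcDir > 0))
  md <- gt$md_true[gt$label_id == 1]
  expect_lt(abs(mean(adcDir) / md - 1), 0.25)  # 10 directions, exact only on average
})

test_that("impacted/sham ground-truth MD ratio in basal ganglia is 0.90 exactly", {
  cfg <- tinyConfig(dwiSubjectJitter = 0)
  dwi <- simulateDwiStudy(cfg, tinyAtlas(cfg))
  gt <- dwi$groundTruth
  bg <- gt[gt$region_group == "basal ganglia", ]
  ratio <- tapply(bg$md_true, bg$group, mean)
  expect_equal(unname(ratio["impacted"] / ratio["sham"]), 0.90,
               tolerance = 1e-12)
})

test_that("behavior generator respects arena confinement and IR design", {
  cfg <- tinyConfig(seed = 31)
  beh <- simulateBehaviorTracks(cfg)
  for (tr in beh$tracks) {
    expect_true(all(tr$x >= 0 & tr$x <= beh$arena$width))
    expect_true(all(tr$y >= 0 & tr$y <= beh$arena$height))
  }
  # expected IR recovered within 3 SE over many subjects
  cfg2 <- simConfig(seed = 32, nSham = 40, nImpacted = 40)
  beh2 <- simulateBehaviorTracks(cfg2)
  ir <- beh2$nor$novel_s / (beh2$nor$novel_s + beh2$nor$familiar_s)
  se <- sd(ir) / sqrt(length(ir))
  expect_lt(abs(mean(ir) - 0.65), 3 * se + 0.02)
})
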
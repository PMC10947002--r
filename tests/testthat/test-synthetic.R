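test_that("zero-amplitude surfaces are ellipsoids with quadrature-true area", {
  ax <- c(30, 26, 23)
  m <- generateSurface(24, axesMM = ax, amplitude = 0, nTheta = 32,
                       nPhi = 64)
  expect_true(isTRUE(isClosedManifold(m)))
  # oracle: area of the same radial surface from a much finer triangulation
  fine <- generateSurface(24, axesMM = ax, amplitude = 0, nTheta = 128,
                          nPhi = 256)
  expect_equal(computeSurfaceArea(m), computeSurfaceArea(fine),
               tolerance = 0.01)
  # enclosed volume against the closed-form ellipsoid volume
  expect_equal(meshVolume(fine), 4 / 3 * pi * prod(ax), tolerance = 0.005)
})

test_that("scaling laws: R doubled gives 8x volume, 4x area, half curvedness", {
  ph <- rep(1.3, 10)
  m1 <- generateSurface(24, axesMM = c(20, 17, 15), amplitude = 0.1,
                        phases = ph)
  m2 <- generateSurface(24, axesMM = 2 * c(20, 17, 15), amplitude = 0.1,
                        phases = ph)
  expect_equal(meshVolume(m2) / meshVolume(m1), 8, tolerance = 1e-9)
  expect_equal(computeSurfaceArea(m2) / computeSurfaceArea(m1), 4,
               tolerance = 1e-9)
  c1 <- median(curvednessValues(curvatureField(m1)))
  c2 <- median(curvednessValues(curvatureField(m2)))
  expect_equal(c2 / c1, 0.5, tolerance = 1e-6)
})

test_that("folding amplitude increases area and decreases shape parameter", {
  ph <- rep(0.7, 10)
  res <- t(vapply(c(0, 0.05, 0.1, 0.15), function(a) {
    m <- generateSurface(26, axesMM = c(30, 26, 23), amplitude = a,
                         phases = ph)
    c(area = computeSurfaceArea(m),
      shape = meshVolume(m) / computeSurfaceArea(m))
  }, numeric(2)))
  expect_true(all(diff(res[, "area"]) > 0))
  expect_true(all(diff(res[, "shape"]) < 0))
})

test_that("self-intersecting amplitudes and out-of-range GA are refused", {
  expect_error(generateSurface(24, axesMM = c(30, 26, 23), amplitude = 1),
               "self-intersection")
  expect_error(generateSurface(15, axesMM = c(30, 26, 23)), "20")
})

test_that("subjects regenerate bit-identically from (config, seed, index)", {
  cfg <- cohortConfig(seed = 5, structures = "ventricles")
  s1 <- generateSubject("OSB", cfg, 4)
  s2 <- generateSubject("OSB", cfg, 4)
  expect_identical(lapply(s1$volumes, labelArray),
                   lapply(s2$volumes, labelArray))
  expect_identical(s1$meta, s2$meta)
  expect_identical(s1$truth, s2$truth)
  # a different subject index gives different data
  s3 <- generateSubject("OSB", cfg, 5)
  expect_false(identical(s1$meta, s3$meta))
})

test_that("measured global ventricular rate recovers the programmed rate", {
  cfg <- cohortConfig(seed = 21, structures = "ventricles")
  s <- generateSubject("control", cfg, 1)
  v <- vapply(s$volumes, computeVolume, numeric(1), label = 2)
  ga <- s$truth$ga
  measured <- (v[3] - v[1]) / (ga[3] - ga[1])
  expect_equal(measured, s$truth$ventricularGlobalRate, tolerance = 0.15)
})

test_that("severe ventriculomegaly subjects classify as severe at baseline", {
  cfg <- cohortConfig(seed = 31, structures = "ventricles")
  found <- FALSE
  for (i in 1:12) {
    s <- generateSubject("OSB", cfg, i)
    if (s$meta$severity == "severe") {
      found <- TRUE
      expect_gt(s$meta$atrial_diameter_mm, 15)
      expect_equal(as.character(
        classifyVentriculomegaly(s$meta$atrial_diameter_mm)), "severe")
    }
  }
  expect_true(found)  # severe cases dominate the programmed mix (17/29)
})

test_that("pipeline measurements stay within 5% of ground-truth volumes", {
  cfg <- cohortConfig(seed = 13)
  s <- generateSubject("OSB", cfg, 2)
  for (t in 1:3) {
    vent <- computeVolume(s$volumes[[t]], 2)
    expect_equal(vent, s$truth$ventricularVolumes[t], tolerance = 0.05)
    wmPlusVent <- computeVolume(s$volumes[[t]], 1) + vent
    expect_equal(wmPlusVent, s$truth$volumes[[t]]$wm_outer, tolerance = 0.05)
    cereb <- computeVolume(s$volumes[[t]], 3)
    expect_equal(cereb, s$truth$volumes[[t]]$cerebellum, tolerance = 0.05)
  }
})

test_that("cohort manifests carry 41 subjects with covariates and GAs", {
  cfg <- cohortConfig(nOSB = 29, nControl = 12, seed = 2,
                      structures = "ventricles")
  coh <- generateCohort(cfg)
  expect_equal(nrow(coh$manifest), 41L)
  expect_equal(sum(coh$manifest$group == "OSB"), 29L)
  expect_true(all(coh$manifest$ga_t1 < coh$manifest$ga_t2 &
                    coh$manifest$ga_t2 < coh$manifest$ga_t3))
  expect_true(all(c("lesion_type", "persistent_HH", "cc_status",
                    "heterotopia", "atrial_diameter_mm") %in%
                    names(coh$manifest)))
  expect_length(coh$subjects, 41L)
})

test_that("written cohorts round-trip through NIfTI + CSV", {
  dir <- file.path(tempdir(), "cohtest")
  cfg <- cohortConfig(nOSB = 1, nControl = 1, seed = 3,
                      structures = "ventricles")
  coh <- generateCohort(cfg, dir = dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 2L)
  vol <- readLabelVolume(man$path_t1[1])
  expect_identical(labelArray(vol), labelArray(coh$subjects[[1]]$volumes[[1]]))
  expect_true(file.exists(file.path(dir, "truth.json")))
  unlink(dir, recursive = TRUE)
})

test_that("null-effect cohorts draw both groups from the control model", {
  cfg <- cohortConfig(seed = 17, effect = "null", structures = "ventricles")
  coh <- generateCohort(cfg)
  prog <- vapply(coh$subjects, function(s) s$truth$ventricularGlobalRate, 1)
  grp <- coh$manifest$group
  # same programmed distribution: medians of the two groups are close
  expect_lt(abs(log(median(prog[grp == "OSB"]) /
                      median(prog[grp == "control"]))), log(2))
  expect_true(all(coh$manifest$cc_status == "normal"))
})
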
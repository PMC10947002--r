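test_that("sphere principal curvatures recover 1/r within 2%", {
  ic <- icosphere(2, 4)
  pc <- principalCurvatures(ic)
  expect_lt(max(abs(pc$kappa1 - 0.5)) / 0.5, 0.02)
  expect_lt(max(abs(pc$kappa2 - 0.5)) / 0.5, 0.02)
  expect_true(all(pc$kappa1 >= pc$kappa2))
})

test_that("capped cylinder has kappa1 ~ 1/r, kappa2 ~ 0 away from the caps", {
  r <- 4; h <- 24; nu <- 64; nz <- 25
  th <- (seq_len(nu) - 1) * 2 * pi / nu
  zs <- seq(-h / 2, h / 2, length.out = nz)
  g <- expand.grid(th = th, z = zs)
  v <- cbind(r * cos(g$th), r * sin(g$th), g$z)
  idx <- function(i, j) (j - 1) * nu + ((i - 1) %% nu) + 1
  fl <- lapply(seq_len(nz - 1), function(j) {
    i <- seq_len(nu)
    rbind(cbind(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
          cbind(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1)))
  })
  nvb <- nrow(v)
  v <- rbind(v, c(0, 0, -h / 2), c(0, 0, h / 2))
  i <- seq_len(nu)
  caps <- rbind(cbind(nvb + 1, idx(i + 1, 1), idx(i, 1)),
                cbind(nvb + 2, idx(i, nz), idx(i + 1, nz)))
  cyl <- fetalmorpho:::.orientOutward(surfaceMesh(v, rbind(do.call(rbind, fl),
                                                           caps)))
  expect_true(isTRUE(isClosedManifold(cyl)))
  pc <- principalCurvatures(cyl)
  mid <- which(abs(vertices(cyl)[, 3]) < h / 4)
  expect_equal(median(pc$kappa1[mid]), 0.25, tolerance = 0.02)
  expect_lt(max(abs(pc$kappa2[mid])), 0.02)
})

test_that("torus curvatures match the closed-form within 3% at 95% of vertices", {
  tm <- torusMesh()
  pc <- principalCurvatures(tm)
  an <- torusAnalytic(tm)
  sc <- pmax(abs(an$kappa1), abs(an$kappa2))
  ok <- abs(pc$kappa1 - an$kappa1) <= 0.03 * sc &
    abs(pc$kappa2 - an$kappa2) <= 0.03 * sc
  expect_gte(mean(ok), 0.95)
})

test_that("curvedness and shape index follow their closed forms", {
  expect_equal(curvedness(0.25, 0.25), 0.25)  # sphere radius 4
  expect_equal(curvedness(0, 0), 0)           # plane
  expect_equal(curvedness(3, 4), sqrt(12.5))
  expect_equal(shapeIndex(0.3, 0.3), 1)       # convex umbilic: gyral dome
  expect_equal(shapeIndex(-0.2, -0.2), -1)    # concave umbilic: sulcal cup
  expect_equal(shapeIndex(0, 0), 0)
  expect_equal(shapeIndex(0.4, -0.4), 0)      # perfect saddle
  expect_equal(shapeIndex(0.7, 0), 0.5)       # convex cylindrical ridge
  expect_error(shapeIndex(0, 1), "kappa1")
})

test_that("curvature field is invariant under rigid motion", {
  pair <- gyriPair()
  m <- pair$a
  cf <- curvatureField(m)
  cf2 <- curvatureField(rigidCopy(m, randomRotation(7)))
  expect_equal(kappa1(cf2), kappa1(cf), tolerance = 1e-6)
  expect_equal(kappa2(cf2), kappa2(cf), tolerance = 1e-6)
  expect_equal(shapeIndexValues(cf2), shapeIndexValues(cf), tolerance = 1e-5)
})

test_that("curvatures scale as 1/lambda under uniform scaling, SI unchanged", {
  for (m in list(icosphere(3, 3), gyriPair()$a)) {
    lam <- 2.5
    ms <- m
    ms@vertices <- vertices(m) * lam
    cf <- curvatureField(m)
    cfs <- curvatureField(ms)
    expect_equal(kappa1(cfs), kappa1(cf) / lam, tolerance = 1e-6)
    expect_equal(curvednessValues(cfs), curvednessValues(cf) / lam,
                 tolerance = 1e-6)
    expect_equal(shapeIndexValues(cfs), shapeIndexValues(cf),
                 tolerance = 1e-5)
  }
})

test_that("integrated mean curvature of a convex surface is positive", {
  ell <- generateSurface(24, axesMM = c(20, 14, 11), amplitude = 0,
                         nTheta = 20, nPhi = 40)
  for (m in list(icosphere(5, 3), ell)) {
    pc <- principalCurvatures(m)
    expect_gt(mean((pc$kappa1 + pc$kappa2) / 2), 0)
  }
})

test_that("sphere curvature error decreases monotonically with subdivision", {
  errs <- vapply(2:4, function(s) {
    pc <- principalCurvatures(icosphere(2, s))
    max(abs(c(pc$kappa1, pc$kappa2) - 0.5)) / 0.5
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("unfolded ellipsoid is convex; folding creates a sulcal SI mode", {
  flat <- generateSurface(24, axesMM = c(30, 26, 23), amplitude = 0,
                          nTheta = 24, nPhi = 48)
  folded <- generateSurface(24, axesMM = c(30, 26, 23), amplitude = 0.18,
                            phases = rep(1, 10), nTheta = 24, nPhi = 48)
  siFlat <- shapeIndexValues(curvatureField(flat))
  siFold <- shapeIndexValues(curvatureField(folded))
  expect_gte(min(siFlat), 0.5)  # everywhere convex
  expect_gt(mean(siFold < 0), mean(siFlat < 0))
  expect_gt(mean(siFold < 0), 0.02)  # a real sulcal population exists
})

test_that("curvature fields export as PLY vertex scalars", {
  m <- icosphere(2, 2)
  cf <- curvatureField(m)
  f <- tempfile(fileext = ".ply")
  writeCurvaturePLY(m, cf, f)
  back <- readMesh(f)
  expect_equal(vertexData(back)$curvedness, curvednessValues(cf))
  expect_equal(vertexData(back)$shape_index, shapeIndexValues(cf))
})
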
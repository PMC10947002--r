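test_that("NIfTI label volumes round-trip data, spacing and origin", {
  set.seed(1)
  dat <- array(sample(0:3, 32^3, replace = TRUE), c(32, 32, 32))
  vol <- labelVolume(dat, spacing = 0.8, origin = c(-10, 2, 3.5))
  f <- tempfile(fileext = ".nii.gz")
  writeLabelVolume(vol, f)
  back <- readLabelVolume(f)
  expect_identical(labelArray(back), labelArray(vol))
  expect_equal(spacing(back), 0.8, tolerance = 1e-6)
  expect_equal(origin(back), origin(vol), tolerance = 1e-5)
})

test_that("anisotropic volumes are rejected", {
  arr <- array(0L, c(8, 8, 8))
  attr(arr, "pixdim") <- c(0.8, 0.8, 1.0)
  img <- RNifti::asNifti(arr)
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  expect_error(readLabelVolume(f), "anisotropic")
})

test_that("empty-background volume loads but extraction errors", {
  vol <- labelVolume(array(0L, c(16, 16, 16)), spacing = 0.8)
  expect_s4_class(vol, "LabelVolume")
  expect_error(extractMesh(vol, 1), "absent")
  expect_error(computeVolume(vol, 1), "absent")
})

test_that("digitized ball mesh volume is within 2% of the analytic sphere", {
  vol <- ballVolume(10, 0.8)
  mesh <- extractMesh(vol, 1)
  expect_true(isTRUE(isClosedManifold(mesh)))
  expect_equal(meshVolume(mesh), 4 / 3 * pi * 1000, tolerance = 0.02)
})

test_that("ball mesh volume error decreases monotonically with spacing", {
  errs <- vapply(c(1.2, 0.8, 0.5), function(sp) {
    m <- extractMesh(ballVolume(10, sp), 1)
    abs(meshVolume(m) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("largest connected component is retained for single-body structures", {
  vol <- ballVolume(6, 0.8)
  dat <- labelArray(vol)
  dat[2, 2, 2] <- 1L  # stray voxel far from the ball (not on the border)
  vol2 <- labelVolume(dat, spacing = spacing(vol), origin = origin(vol))
  mesh <- extractMesh(vol2, 1)
  expect_equal(max(fetalmorpho:::.meshComponents(mesh)), 1L)
})

test_that("masks touching the volume border are refused", {
  dat <- array(0L, c(12, 12, 12))
  dat[1:6, 4:8, 4:8] <- 1L
  vol <- labelVolume(dat, spacing = 0.8)
  expect_error(extractMesh(vol, 1), "border")
})

test_that("ventricle label keeps all bodies above the size threshold", {
  dat <- array(0L, c(40, 28, 24))
  dat[5:14, 5:14, 5:14] <- 2L    # body 1: 1000 voxels
  dat[25:34, 12:21, 8:17] <- 2L  # body 2: 1000 voxels
  dat[20, 24, 20] <- 2L          # stray voxel below threshold
  vol <- labelVolume(dat, spacing = 0.8)
  mesh <- extractMesh(vol, 2)
  expect_true(isTRUE(isClosedManifold(mesh)))
  expect_equal(max(fetalmorpho:::.meshComponents(mesh)), 2L)
})

test_that("voxelization labels voxel centres inside the surface", {
  cube <- cubeMesh(1)
  vol <- voxelizeMesh(cube, spacing = 0.25)
  v <- sum(labelArray(vol) > 0) * 0.25^3
  expect_lt(abs(v - 1), 6 * 0.25)  # within one voxel-layer of 1 mm^3
  # padding invariant: at least 2 background voxels on all sides
  d <- dim(vol)
  arr <- labelArray(vol)
  expect_true(all(arr[1:2, , ] == 0) && all(arr[, , (d[3] - 1):d[3]] == 0))
})

test_that("voxelize matches a brute-force point-in-mesh oracle", {
  mesh <- icosphere(5, 2)
  sp <- 0.8
  vol <- voxelizeMesh(mesh, spacing = sp)
  d <- dim(vol)
  o <- origin(vol)
  centres <- as.matrix(expand.grid(x = o[1] + (seq_len(d[1]) - 1) * sp,
                                   y = o[2] + (seq_len(d[2]) - 1) * sp,
                                   z = o[3] + (seq_len(d[3]) - 1) * sp))
  # independent parity test: ray along +x, counting crossings face by face
  v <- vertices(mesh)
  f <- faces(mesh)
  inside <- rep(0L, nrow(centres))
  for (k in seq_len(nrow(f))) {
    a <- v[f[k, 1], ]; b <- v[f[k, 2], ]; c_ <- v[f[k, 3], ]
    d0 <- (b[2] - a[2]) * (centres[, 3] - a[3]) -
      (b[3] - a[3]) * (centres[, 2] - a[2])
    d1 <- (c_[2] - b[2]) * (centres[, 3] - b[3]) -
      (c_[3] - b[3]) * (centres[, 2] - b[2])
    d2 <- (a[2] - c_[2]) * (centres[, 3] - c_[3]) -
      (a[3] - c_[3]) * (centres[, 2] - c_[2])
    hit <- (d0 > 0 & d1 > 0 & d2 > 0) | (d0 < 0 & d1 < 0 & d2 < 0)
    if (!any(hit)) next
    s <- d0 + d1 + d2
    xhit <- (d1 * a[1] + d2 * b[1] + d0 * c_[1]) / s
    inside[hit & xhit > centres[, 1]] <-
      inside[hit & xhit > centres[, 1]] + 1L
    }
  expect_equal(sum(labelArray(vol) > 0), sum(inside %% 2L == 1L))
})

test_that("voxelize-extract round trip preserves the mask (Dice >= 0.95)", {
  vol <- ballVolume(8, 0.8)
  mesh <- extractMesh(vol, 1)
  back <- voxelizeMesh(mesh, spacing = 0.8,
                       grid = list(dims = dim(vol), origin = origin(vol)))
  a <- labelArray(vol) > 0
  b <- labelArray(back) > 0
  dice <- 2 * sum(a & b) / (sum(a) + sum(b))
  expect_gte(dice, 0.95)
})

test_that("open meshes cannot be voxelized", {
  cube <- cubeMesh(1)
  open <- surfaceMesh(vertices(cube), faces(cube)[-1, , drop = FALSE])
  expect_error(voxelizeMesh(open, 0.25), "open mesh")
})

test_that("PLY and OFF round-trip vertices and faces losslessly", {
  mesh <- icosphere(3.7, 1)
  ply <- tempfile(fileext = ".ply")
  off <- tempfile(fileext = ".off")
  writeMesh(mesh, ply)
  writeMesh(mesh, off)
  mply <- readMesh(ply)
  moff <- readMesh(off)
  expect_identical(faces(mply), faces(mesh))
  expect_identical(faces(moff), faces(mesh))
  expect_equal(vertices(mply), vertices(mesh), tolerance = 0)
  expect_equal(vertices(moff), vertices(mesh), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(writeMesh(surfaceMesh(vertices(mesh),
                                     matrix(integer(), 0, 3)), ply),
               "0 faces")
})

test_that("PLY vertex scalar properties survive a round trip", {
  mesh <- icosphere(2, 1)
  f <- tempfile(fileext = ".ply")
  writeMesh(mesh, f, vertexScalars = list(val = seq_len(nVertices(mesh)) / 7))
  back <- readMesh(f)
  expect_equal(vertexData(back)$val, seq_len(nVertices(mesh)) / 7)
})
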
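# geometry fixtures built in code

# digitized ball as a LabelVolume (voxel centres inside the sphere)
ballVolume <- function(radius, spacing, label = 1L, pad = 5) {
  n <- ceiling(2 * (radius + pad * spacing) / spacing)
  ax <- (seq_len(n) - 1) * spacing - (n - 1) * spacing / 2
  g <- expand.grid(x = ax, y = ax, z = ax)
  inside <- g$x^2 + g$y^2 + g$z^2 < radius^2
  labelVolume(array(as.integer(inside) * label, c(n, n, n)),
              spacing = spacing, origin = rep(ax[1], 3))
}

# analytic torus mesh on a (u, v) grid with outward normals
torusMesh <- function(R = 10, r = 3, nu = 160, nv = 64) {
  u <- (seq_len(nu) - 1) * 2 * pi / nu
  v <- (seq_len(nv) - 1) * 2 * pi / nv
  g <- expand.grid(v = v, u = u)
  x <- (R + r * cos(g$v)) * cos(g$u)
  y <- (R + r * cos(g$v)) * sin(g$u)
  z <- r * sin(g$v)
  idx <- function(i, j) ((i - 1) %% nu) * nv + ((j - 1) %% nv) + 1
  f <- do.call(rbind, lapply(seq_len(nu), function(i) {
    j <- seq_len(nv)
    rbind(cbind(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
          cbind(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }))
  fetalmorpho:::.orientOutward(surfaceMesh(cbind(x, y, z), f))
}

# closed-form torus principal curvatures at the mesh vertices (outward
# normals): tube curvature 1/r everywhere, ring curvature cos(v)/(R+r cos v)
torusAnalytic <- function(mesh, R = 10, r = 3) {
  v <- vertices(mesh)
  cosv <- (sqrt(v[, 1]^2 + v[, 2]^2) - R) / r
  ks <- cosv / (R + r * cosv)
  list(kappa1 = pmax(1 / r, ks), kappa2 = pmin(1 / r, ks))
}

# axis-aligned cube [0, side]^3 triangulated into 12 faces, outward normals
cubeMesh <- function(side = 1) {
  v <- as.matrix(expand.grid(x = c(0, side), y = c(0, side),
                             z = c(0, side)))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = side
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = side
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = side
  fetalmorpho:::.orientOutward(surfaceMesh(v, f))
}

randomRotation <- function(seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

rigidCopy <- function(mesh, rotation, translation = c(5, -3, 2)) {
  mesh@vertices <- vertices(mesh) %*% t(rotation) +
    matrix(translation, nVertices(mesh), 3, byrow = TRUE)
  mesh
}

# a small gyrified surface pair from the generator's radial model
gyriPair <- function(seed = 42, nTheta = 24L, nPhi = 48L) {
  basis <- fetalmorpho:::.foldBasis(cohortConfig()@folding)
  set.seed(seed)
  ph <- runif(length(basis$omega), 0, 2 * pi)
  list(
    a = generateSurface(24, axesMM = c(33, 28, 24), amplitude = 0.06,
                        basis = basis, phases = ph, nTheta = nTheta,
                        nPhi = nPhi),
    b = generateSurface(30, axesMM = c(38, 32, 28), amplitude = 0.12,
                        basis = basis, phases = ph, nTheta = nTheta,
                        nPhi = nPhi))
}
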
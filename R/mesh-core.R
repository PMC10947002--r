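#' Construct a SurfaceMesh
#'
#' @param vertices numeric n x 3 matrix of coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices with
#'   counter-clockwise winding seen from outside.
#' @param structureLabel optional label code of the bounded structure.
#' @param vertexData optional data.frame of per-vertex annotations.
#' @return A [SurfaceMesh-class] object.
#' @export
surfaceMesh <- function(vertices, faces, structureLabel = NA_integer_,
                        vertexData = NULL) {
  storage.mode(faces) <- "integer"
  if (is.null(vertexData)) vertexData <- data.frame()
  new("SurfaceMesh", vertices = as.matrix(vertices), faces = faces,
      structureLabel = as.integer(structureLabel), vertexData = vertexData)
}

#' Construct a LabelVolume
#'
#' @param data 3D integer array of label codes (0 background, 1 white matter,
#'   2 ventricles, 3 cerebellum).
#' @param spacing isotropic voxel edge length, mm.
#' @param origin world coordinate (mm) of the centre of voxel (0,0,0).
#' @return A [LabelVolume-class] object.
#' @export
labelVolume <- function(data, spacing = 0.8, origin = c(0, 0, 0)) {
  storage.mode(data) <- "integer"
  new("LabelVolume", data = data, spacing = spacing, origin = origin)
}

# directed half-edges of a triangulation, one row per face corner
.halfEdges <- function(faces) {
  rbind(faces[, c(1, 2), drop = FALSE],
        faces[, c(2, 3), drop = FALSE],
        faces[, c(3, 1), drop = FALSE])
}

#' Check that a mesh is closed and 2-manifold
#'
#' A triangulation bounds a solid iff every undirected edge is shared by
#' exactly two faces and the two incidences have opposite direction
#' (consistent winding). Multi-shell meshes (e.g. two lateral ventricle
#' bodies) pass as long as every shell is closed.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return TRUE/FALSE, with attribute `"why"` describing the first failure.
#' @export
isClosedManifold <- function(mesh) {
  he <- .halfEdges(faces(mesh))
  n <- nVertices(mesh)
  dirKey <- (he[, 1] - 1) * as.double(n) + he[, 2]
  undKey <- (pmin(he[, 1], he[, 2]) - 1) * as.double(n) + pmax(he[, 1], he[, 2])
  fail <- function(why) structure(FALSE, why = why)
  if (anyDuplicated(dirKey))
    return(fail("a directed edge is used twice (inconsistent winding or non-manifold)"))
  if (length(undKey) %% 2L)
    return(fail("an edge is not shared by exactly two faces (mesh not closed)"))
  s <- sort(undKey)
  a <- s[c(TRUE, FALSE)]
  if (any(a != s[c(FALSE, TRUE)]) || anyDuplicated(a))
    return(fail("an edge is not shared by exactly two faces (mesh not closed)"))
  TRUE
}

#' Signed enclosed volume of a closed mesh
#'
#' Divergence-theorem volume: positive when faces wind counter-clockwise seen
#' from outside (outward normals).
#'
#' @param mesh a closed [SurfaceMesh-class].
#' @return signed volume in mm^3.
#' @export
meshVolume <- function(mesh) {
  v <- vertices(mesh)
  f <- faces(mesh)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# flip face winding so the signed volume is positive (outward normals)
.orientOutward <- function(mesh) {
  if (meshVolume(mesh) < 0) mesh@faces <- mesh@faces[, c(1, 3, 2)]
  mesh
}

# connected components of the vertex graph; returns membership vector
.meshComponents <- function(mesh) {
  he <- .halfEdges(faces(mesh))
  g <- igraph::graph_from_edgelist(he, directed = FALSE)
  if (igraph::vcount(g) < nVertices(mesh))
    g <- igraph::add_vertices(g, nVertices(mesh) - igraph::vcount(g))
  igraph::components(g)$membership
}

#' Taubin lambda/mu mesh smoothing
#'
#' Two-step pass-band smoother: a shrinking Laplacian step with factor
#' `lambda` followed by an inflating step with factor `mu` (mu < -lambda),
#' which attenuates voxelization staircase frequencies while approximately
#' preserving enclosed volume, unlike plain Laplacian smoothing.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param iterations number of lambda/mu passes.
#' @param lambda,mu Taubin factors (defaults 0.5 / -0.53).
#' @return the smoothed mesh.
#' @export
taubinSmooth <- function(mesh, iterations = 10L, lambda = 0.5, mu = -0.53) {
  if (iterations <= 0L) return(mesh)
  n <- nVertices(mesh)
  he <- .halfEdges(faces(mesh))
  A <- Matrix::sparseMatrix(i = he[, 1], j = he[, 2], x = 1, dims = c(n, n))
  A <- (A + Matrix::t(A) > 0) * 1
  W <- A / Matrix::rowSums(A)  # row-stochastic umbrella operator
  x <- vertices(mesh)
  for (it in seq_len(iterations)) {
    x <- x + lambda * (as.matrix(W %*% x) - x)
    x <- x + mu * (as.matrix(W %*% x) - x)
  }
  mesh@vertices <- x
  mesh
}

#' Total triangle area and per-face areas
#' @noRd
.faceAreas <- function(mesh) {
  v <- vertices(mesh)
  f <- faces(mesh)
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# area-weighted outward vertex normals
.vertexNormals <- function(mesh) {
  v <- vertices(mesh)
  f <- faces(mesh)
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # 2*area-weighted
  n <- matrix(0, nrow(v), 3)
  for (c_ in 1:3) {
    idx <- f[, c_]
    n[, 1] <- n[, 1] + .tapplySum(fn[, 1], idx, nrow(v))
    n[, 2] <- n[, 2] + .tapplySum(fn[, 2], idx, nrow(v))
    n[, 3] <- n[, 3] + .tapplySum(fn[, 3], idx, nrow(v))
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# sum `x` into `nbins` groups given by `idx` (1-based); dense result
.tapplySum <- function(x, idx, nbins) {
  out <- numeric(nbins)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Geodesic icosphere
#'
#' Icosahedron subdivided `subdivisions` times with vertices projected to the
#' sphere; the standard near-uniform sphere triangulation used as analytic
#' test geometry.
#'
#' @param radius sphere radius, mm.
#' @param subdivisions subdivision level (0 = icosahedron).
#' @param center sphere centre.
#' @return a closed [SurfaceMesh-class] with outward normals.
#' @export
icosphere <- function(radius = 1, subdivisions = 3L, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    key2idx <- new.env(hash = TRUE)
    newV <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- key2idx[[key]]
      if (!is.null(hit)) return(hit)
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      newV[[length(newV) + 1L]] <<- m
      idx <- nv + length(newV)
      key2idx[[key]] <- idx
      idx
    }
    fl <- vector("list", nrow(f))
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      fl[[i]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    f <- do.call(rbind, fl)
    v <- rbind(v, do.call(rbind, newV))
  }
  surfaceMesh(sweep(v * radius, 2, center, "+"), f)
}
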
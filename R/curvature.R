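#' Per-vertex principal curvatures by local quadric fitting
#'
#' For each vertex a quadric height patch
#' \eqn{h(u,v) = a u^2 + b uv + c v^2 + d u + e v}
#' is fitted by least squares over the `rings`-ring neighbourhood, expressed
#' in the tangent frame of the area-weighted vertex normal. Principal
#' curvatures are the eigenvalues of the Weingarten map (shape operator)
#' \eqn{I^{-1} II} of the fitted patch, with the sign convention that convex
#' regions (surface bending away from the outward normal) are positive.
#'
#' @param mesh a closed, outward-oriented [SurfaceMesh-class].
#' @param rings neighbourhood ring count (default 2).
#' @return list with numeric vectors `kappa1`, `kappa2` (mm^-1),
#'   `kappa1 >= kappa2` per vertex.
#' @export
principalCurvatures <- function(mesh, rings = 2L) {
  v <- vertices(mesh)
  f <- faces(mesh)
  n <- nrow(v)
  if (n < 10L) stop("mesh too small for curvature estimation")
  nrm <- .vertexNormals(mesh)
  # ring-neighbourhood pair list (i, j) via boolean sparse adjacency powers
  he <- .halfEdges(f)
  A <- Matrix::sparseMatrix(i = c(he[, 1], seq_len(n)),
                            j = c(he[, 2], seq_len(n)), x = 1,
                            dims = c(n, n))
  A <- (A + Matrix::t(A)) > 0
  Ar <- A
  if (rings >= 2L) for (r in seq_len(rings - 1L)) Ar <- (Ar %*% A) > 0
  At <- methods::as(Ar, "TsparseMatrix")
  keep <- At@i != At@j
  i <- At@i[keep] + 1L
  j <- At@j[keep] + 1L
  deg <- tabulate(i, n)
  if (any(deg < 5L))
    stop("a vertex has a neighbourhood smaller than the quadric basis")
  # per-vertex tangent frames orthogonal to the (outward) vertex normal
  useX <- abs(nrm[, 1]) < 0.9
  ref <- cbind(ifelse(useX, 1, 0), ifelse(useX, 0, 1), 0)
  t1 <- ref - nrm * rowSums(ref * nrm)
  t1 <- t1 / sqrt(rowSums(t1^2))
  t2 <- cbind(nrm[, 2] * t1[, 3] - nrm[, 3] * t1[, 2],
              nrm[, 3] * t1[, 1] - nrm[, 1] * t1[, 3],
              nrm[, 1] * t1[, 2] - nrm[, 2] * t1[, 1])
  p <- v[j, , drop = FALSE] - v[i, , drop = FALSE]
  u <- rowSums(p * t1[i, , drop = FALSE])
  w <- rowSums(p * t2[i, , drop = FALSE])
  h <- -rowSums(p * nrm[i, , drop = FALSE])  # inward height: convex positive
  # normal equations of h ~ a u^2 + b uw + c w^2 + d u + e w, accumulated
  # per centre vertex
  X <- cbind(u^2, u * w, w^2, u, w)
  G <- matrix(0, n, 15L)
  cc <- 1L
  for (a_ in 1:5) for (b_ in a_:5) {
    G[, cc] <- .tapplySum(X[, a_] * X[, b_], i, n)
    cc <- cc + 1L
  }
  Xh <- vapply(1:5, function(c_) .tapplySum(X[, c_] * h, i, n),
               numeric(n))
  ut <- rbind(c(1, 2, 3, 4, 5), c(2, 6, 7, 8, 9), c(3, 7, 10, 11, 12),
              c(4, 8, 11, 13, 14), c(5, 9, 12, 14, 15))
  k1 <- numeric(n)
  k2 <- numeric(n)
  beta <- matrix(0, n, 5)
  for (ii in seq_len(n)) {
    M5 <- matrix(G[ii, ut], 5, 5)
    ridge <- 1e-12 * max(diag(M5))
    beta[ii, ] <- tryCatch(solve(M5 + diag(ridge, 5), Xh[ii, ]),
                           error = function(e) rep(0, 5))
  }
  a <- beta[, 1]; b <- beta[, 2]; c_ <- beta[, 3]
  d <- beta[, 4]; e <- beta[, 5]
  # shape operator I^-1 II of the fitted graph at the origin
  den <- sqrt(1 + d^2 + e^2)
  E <- 1 + d^2; Fuv <- d * e; Gg <- 1 + e^2
  L <- 2 * a / den; M <- b / den; N <- 2 * c_ / den
  detI <- E * Gg - Fuv^2
  s11 <- (Gg * L - Fuv * M) / detI
  s12 <- (Gg * M - Fuv * N) / detI
  s21 <- (E * M - Fuv * L) / detI
  s22 <- (E * N - Fuv * M) / detI
  tr <- s11 + s22
  disc <- pmax(tr^2 - 4 * (s11 * s22 - s12 * s21), 0)
  k1 <- (tr + sqrt(disc)) / 2
  k2 <- (tr - sqrt(disc)) / 2
  list(kappa1 = k1, kappa2 = k2)
}

#' Curvedness
#'
#' \eqn{C = \sqrt{(\kappa_1^2 + \kappa_2^2)/2}} (mm^-1): the magnitude of
#' surface bending, zero on a plane, 1/r on a sphere of radius r.
#'
#' @param kappa1,kappa2 principal curvatures.
#' @return non-negative curvedness values.
#' @export
curvedness <- function(kappa1, kappa2) sqrt((kappa1^2 + kappa2^2) / 2)

#' Shape index
#'
#' \eqn{SI = (2/\pi)\,\arctan((\kappa_1+\kappa_2)/(\kappa_1-\kappa_2))} with
#' `kappa1 >= kappa2`, ranging over [-1, 1]: +1 on a convex dome (gyrus),
#' +0.5 on a convex ridge, 0 on a perfect saddle, -1 in a concave cup
#' (sulcus). At umbilic points (`kappa1 == kappa2`) the limit
#' `sign(kappa1)` is returned (0 for a plane) so that summaries remain
#' computable on near-spherical surfaces.
#'
#' @param kappa1,kappa2 principal curvatures with `kappa1 >= kappa2`.
#' @return shape index values in [-1, 1].
#' @export
shapeIndex <- function(kappa1, kappa2) {
  if (any(kappa1 + 1e-12 < kappa2)) stop("kappa1 must be >= kappa2")
  num <- kappa1 + kappa2
  den <- kappa1 - kappa2
  umb <- den <= 1e-12 * pmax(abs(kappa1) + abs(kappa2), 1e-300)
  si <- numeric(length(kappa1))
  si[!umb] <- (2 / pi) * atan(num[!umb] / den[!umb])
  si[umb] <- sign(kappa1[umb])
  si
}

#' Full curvature field of a mesh
#'
#' Runs [principalCurvatures()] and derives curvedness and shape index
#' vertex-wise.
#'
#' @inheritParams principalCurvatures
#' @return a [CurvatureField-class].
#' @export
curvatureField <- function(mesh, rings = 2L) {
  pc <- principalCurvatures(mesh, rings = rings)
  new("CurvatureField", kappa1 = pc$kappa1, kappa2 = pc$kappa2,
      curvedness = curvedness(pc$kappa1, pc$kappa2),
      shapeIndex = shapeIndex(pc$kappa1, pc$kappa2))
}

#' Export a curvature field as PLY vertex scalars
#'
#' Writes the mesh with `kappa1`, `kappa2`, `curvedness` and `shape_index`
#' vertex properties for external visualization.
#'
#' @param mesh the [SurfaceMesh-class] the field was computed on.
#' @param field the matching [CurvatureField-class].
#' @param path output PLY path.
#' @export
writeCurvaturePLY <- function(mesh, field, path) {
  stopifnot(length(field) == nVertices(mesh))
  writeMesh(mesh, path, format = "ply",
            vertexScalars = list(kappa1 = kappa1(field),
                                 kappa2 = kappa2(field),
                                 curvedness = curvednessValues(field),
                                 shape_index = shapeIndexValues(field)))
}
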
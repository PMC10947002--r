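#' @importFrom Matrix sparseMatrix Diagonal forceSymmetric rowSums t diag
NULL

# cotangent edge weights and lumped (barycentric) vertex areas
.cotanWeights <- function(mesh) {
  v <- vertices(mesh)
  f <- faces(mesh)
  n <- nrow(v)
  i1 <- f[, 1]; i2 <- f[, 2]; i3 <- f[, 3]
  cotAt <- function(a, b, c_) {
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[c_, , drop = FALSE] - v[a, , drop = FALSE]
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    rowSums(u * w) / pmax(sqrt(rowSums(cr^2)), 1e-300)
  }
  c1 <- cotAt(i1, i2, i3)  # angle at corner 1, opposite edge (2,3)
  c2 <- cotAt(i2, i3, i1)
  c3 <- cotAt(i3, i1, i2)
  W <- Matrix::sparseMatrix(
    i = c(i2, i3, i1), j = c(i3, i1, i2),
    x = 0.5 * c(c1, c2, c3), dims = c(n, n))
  W <- W + Matrix::t(W)
  areas <- .faceAreas(mesh)
  mass <- (.tapplySum(areas, i1, n) + .tapplySum(areas, i2, n) +
           .tapplySum(areas, i3, n)) / 3
  list(W = W, mass = mass)
}

# m smallest eigenpairs of a sparse symmetric PSD matrix; dense LAPACK for
# small problems, shift-inverted ARPACK (via a sparse Cholesky solve) above
.smallestEigs <- function(A, m, denseLimit = 1200L) {
  n <- nrow(A)
  if (n <= denseLimit) {
    e <- eigen(as.matrix(A), symmetric = TRUE)
    idx <- seq(n, n - m + 1L)
    return(list(values = e$values[idx], vectors = e$vectors[, idx,
                                                            drop = FALSE]))
  }
  sigma <- 1e-8 * mean(Matrix::diag(A)) + 1e-12
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A + sigma * Matrix::Diagonal(n)),
                         LDL = FALSE)
  fn <- function(x, extra) as.numeric(Matrix::solve(ch, x))
  res <- igraph::arpack(fn, sym = TRUE,
                        options = list(n = n, nev = m,
                                       ncv = min(n, max(4L * m + 1L, 25L)),
                                       which = "LA", maxiter = 5000L))
  lam <- 1 / res$values - sigma
  ord <- order(lam)
  vec <- res$vectors
  if (is.null(dim(vec))) vec <- matrix(vec, ncol = 1L)
  list(values = lam[ord], vectors = vec[, ord, drop = FALSE])
}

#' Laplacian eigenmodes of a surface mesh
#'
#' First `k` non-trivial eigenpairs of the cotangent-weighted mesh Laplacian
#' with lumped vertex areas (the symmetrized generalized problem
#' \eqn{L\phi = \lambda M \phi}), ascending, each retained mode normalized to
#' unit magnitude with a deterministic sign convention (the entry of largest
#' absolute value is positive). Low modes encode low spatial frequencies of
#' the surface (primary folds), higher modes increasingly fine ones.
#'
#' @param mesh a connected, closed [SurfaceMesh-class].
#' @param k number of non-trivial modes (default 5).
#' @param weighting `"cotangent"` (geometric, default) or `"graph"`
#'   (unweighted combinatorial Laplacian fallback for degenerate
#'   triangulations).
#' @return a [SpectralEmbedding-class].
#' @export
laplacianEigenmodes <- function(mesh, k = 5L, weighting = c("cotangent",
                                                            "graph")) {
  weighting <- match.arg(weighting)
  if (k < 1L) stop("k must be >= 1")
  comp <- .meshComponents(mesh)
  if (max(comp) > 1L)
    stop("mesh is disconnected (", max(comp),
         " components): eigenvalue 0 would have multiplicity > 1")
  n <- nVertices(mesh)
  if (weighting == "cotangent") {
    cw <- .cotanWeights(mesh)
    W <- cw$W
    mass <- cw$mass
  } else {
    he <- .halfEdges(faces(mesh))
    W <- Matrix::sparseMatrix(i = he[, 1], j = he[, 2], x = 1, dims = c(n, n))
    W <- (W + Matrix::t(W) > 0) * 1
    mass <- rep(1, n)
  }
  L <- Matrix::Diagonal(n, Matrix::rowSums(W)) - W
  s <- 1 / sqrt(mass)
  A <- Matrix::forceSymmetric(Matrix::Diagonal(n, s) %*% L %*%
                                Matrix::Diagonal(n, s))
  eg <- .smallestEigs(A, m = k + 1L)
  vals <- pmax(eg$values, 0)
  phi <- eg$vectors * s  # back-transform of the mass scaling
  phi <- apply(phi, 2, function(x) {
    x <- x / sqrt(sum(x^2))
    if (x[which.max(abs(x))] < 0) -x else x
  })
  new("SpectralEmbedding", eigenvalues = vals,
      modes = phi[, -1L, drop = FALSE])
}

# nearest-row index in Y for every row of X (squared Euclidean, chunked)
.nnIndex <- function(X, Y, chunk = 1024L) {
  ny2 <- rowSums(Y^2)
  out <- integer(nrow(X))
  for (s in seq(1L, nrow(X), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(X))
    Xc <- X[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Xc^2), ny2, "+") - 2 * Xc %*% t(Y)
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

# Coarse rigid pairing of two vertex clouds: centre and scale to unit RMS,
# then ICP (nearest neighbours + Kabsch) from several proper-rotation starts
# (identity and principal-axes combinations restricted to det = +1, so that
# a near-symmetric shape cannot be matched to its mirror image); the start
# with the lowest residual wins.
.coarsePairing <- function(vA, vB, iters = 5L, maxIcp = 2000L) {
  pa <- sweep(vA, 2, colMeans(vA))
  pa <- pa / sqrt(mean(rowSums(pa^2)))
  pb <- sweep(vB, 2, colMeans(vB))
  pb <- pb / sqrt(mean(rowSums(pb^2)))
  # ICP iterations run on an evenly spaced subsample; only the final
  # pairing uses every vertex
  sa <- if (nrow(pa) > maxIcp)
    pa[round(seq(1, nrow(pa), length.out = maxIcp)), , drop = FALSE]
  else pa
  fixdet <- function(E) {
    if (det(E) < 0) E[, 3] <- -E[, 3]
    E
  }
  Ea <- fixdet(eigen(stats::cov(pa), symmetric = TRUE)$vectors)
  Eb <- fixdet(eigen(stats::cov(pb), symmetric = TRUE)$vectors)
  cands <- c(list(diag(3)),
             lapply(list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                         c(-1, -1, 1)),
                    function(s) Eb %*% diag(s) %*% t(Ea)))
  best <- NULL
  bestRes <- Inf
  bestQ <- diag(3)
  for (Q in cands) {
    for (it in seq_len(iters)) {
      pbt <- pb %*% Q
      j <- .nnIndex(sa, pbt)
      sv <- svd(crossprod(pb[j, , drop = FALSE], sa))
      if (det(sv$u %*% t(sv$v)) < 0) sv$u[, 3] <- -sv$u[, 3]
      Q <- sv$u %*% t(sv$v)
    }
    pbt <- pb %*% Q
    j <- .nnIndex(sa, pbt)
    res <- mean(rowSums((sa - pbt[j, , drop = FALSE])^2))
    if (res < bestRes) {
      bestRes <- res
      bestQ <- Q
    }
  }
  best <- .nnIndex(pa, pb %*% bestQ)
  structure(best, residual = bestRes)
}

#' Align two spectral embeddings
#'
#' Resolves the eigen-sign ambiguity and mode permutation of embedding B
#' relative to embedding A, using an initial coarse vertex pairing. Modes are
#' greedily paired by absolute correlation; within near-degenerate eigenvalue
#' groups an orthogonal (Procrustes) rotation is applied, since eigenvectors
#' of nearly equal eigenvalues are only determined up to rotation.
#'
#' @param embA,embB [SpectralEmbedding-class] objects with the same `k`.
#' @param pairing integer vector: for each A-vertex, a coarsely matched
#'   B-vertex. Defaults to the identity when vertex counts agree.
#' @param degenerateGap relative eigenvalue gap below which consecutive modes
#'   are treated as one degenerate group.
#' @return list with `modesB` (aligned B modes), `perm`, `signs`, and
#'   `quality` (mean absolute mode-wise correlation after alignment).
#' @export
alignSpectra <- function(embA, embB, pairing = NULL, degenerateGap = 0.05) {
  Ma <- modes(embA)
  Mb <- modes(embB)
  if (ncol(Ma) != ncol(Mb)) stop("embeddings must retain the same k")
  if (is.null(pairing)) {
    if (nrow(Ma) != nrow(Mb))
      stop("pairing required when vertex counts differ")
    pairing <- seq_len(nrow(Ma))
  }
  k <- ncol(Ma)
  Mbp <- Mb[pairing, , drop = FALSE]
  C <- suppressWarnings(stats::cor(Ma, Mbp))
  C[!is.finite(C)] <- 0
  perm <- integer(k)
  sgn <- numeric(k)
  Cw <- abs(C)
  for (step in seq_len(k)) {
    pick <- which(Cw == max(Cw), arr.ind = TRUE)[1, ]
    i <- pick[1]; j <- pick[2]
    perm[i] <- j
    sgn[i] <- if (C[i, j] < 0) -1 else 1
    Cw[i, ] <- -Inf
    Cw[, j] <- -Inf
  }
  aligned <- Mb[, perm, drop = FALSE] %*% diag(sgn, k)
  # rotate within near-degenerate eigenvalue groups of A
  ev <- eigenvalues(embA)[-1L]
  grp <- cumsum(c(TRUE, diff(ev) > degenerateGap * pmax(ev[-1], 1e-12)))
  for (g in unique(grp)) {
    cols <- which(grp == g)
    if (length(cols) < 2L) next
    Bg <- aligned[pairing, cols, drop = FALSE]
    sv <- svd(crossprod(Bg, Ma[, cols, drop = FALSE]))
    R <- sv$u %*% t(sv$v)
    aligned[, cols] <- aligned[, cols, drop = FALSE] %*% R
  }
  q <- suppressWarnings(
    mean(abs(diag(stats::cor(Ma, aligned[pairing, , drop = FALSE]))),
         na.rm = TRUE))
  list(modesB = aligned, perm = perm, signs = sgn, quality = q)
}

#' Joint spectral matching of two meshes
#'
#' Longitudinal vertex correspondence between two surfaces of the same
#' subject via a dual-layered graph: each mesh is one layer with its
#' cotangent weights; inter-layer links come from an initial correspondence
#' (nearest neighbours in the sign/order-aligned per-mesh spectral
#' embeddings, both directions), with link weight a fixed fraction of the
#' mean intra-layer edge weight. The first `k` non-trivial eigenmodes of the
#' combined graph are shared by both layers; each A-vertex is assigned its
#' nearest B-vertex in the eigenvalue-scaled joint spectral coordinates
#' (nearest-neighbour ties broken by lowest vertex index).
#'
#' @param meshA,meshB connected, closed [SurfaceMesh-class] objects.
#' @param k number of non-trivial modes for both the per-mesh and the joint
#'   embedding (default 5).
#' @param coupling inter-layer link weight as a fraction of the mean
#'   intra-layer edge weight (default 0.1).
#' @param weighting Laplacian weighting, see [laplacianEigenmodes()].
#' @return a [Correspondence-class] mapping A-vertices to B-vertices, with
#'   attribute `"alignmentQuality"` from the initial spectral alignment.
#' @export
jointSpectralMatch <- function(meshA, meshB, k = 5L, coupling = 0.1,
                               weighting = "cotangent") {
  embA <- laplacianEigenmodes(meshA, k = k, weighting = weighting)
  embB <- laplacianEigenmodes(meshB, k = k, weighting = weighting)
  pairing <- .coarsePairing(vertices(meshA), vertices(meshB))
  al <- alignSpectra(embA, embB, pairing = pairing)
  evA <- pmax(eigenvalues(embA)[-1L], 1e-12)
  SA <- modes(embA) %*% diag(1 / sqrt(evA), k)
  SB <- al$modesB %*% diag(1 / sqrt(evA), k)
  ab <- .nnIndex(SA, SB)
  ba <- .nnIndex(SB, SA)
  nA <- nVertices(meshA)
  nB <- nVertices(meshB)
  cwA <- .cotanWeights(meshA)
  cwB <- .cotanWeights(meshB)
  wbar <- mean(abs(c(cwA$W@x, cwB$W@x)))
  linkI <- c(seq_len(nA), ba + 0L)
  linkJ <- c(nA + ab, nA + seq_len(nB))
  keyOrd <- !duplicated(linkI * as.double(nA + nB) + linkJ)
  Wlink <- Matrix::sparseMatrix(i = linkI[keyOrd], j = linkJ[keyOrd],
                                x = coupling * wbar, dims = c(nA + nB, nA + nB))
  W <- rbind(cbind(cwA$W, Matrix::sparseMatrix(i = integer(), j = integer(),
                                               dims = c(nA, nB))),
             cbind(Matrix::sparseMatrix(i = integer(), j = integer(),
                                        dims = c(nB, nA)), cwB$W))
  W <- W + Wlink + Matrix::t(Wlink)
  mass <- c(cwA$mass, cwB$mass)
  L <- Matrix::Diagonal(nA + nB, Matrix::rowSums(W)) - W
  s <- 1 / sqrt(mass)
  A <- Matrix::forceSymmetric(Matrix::Diagonal(nA + nB, s) %*% L %*%
                                Matrix::Diagonal(nA + nB, s))
  eg <- .smallestEigs(A, m = k + 1L)
  vals <- pmax(eg$values, 1e-12)
  phi <- eg$vectors * s
  phi <- apply(phi, 2, function(x) x / sqrt(sum(x^2)))
  J <- phi[, -1L, drop = FALSE] %*% diag(1 / sqrt(vals[-1L]), k)
  JA <- J[seq_len(nA), , drop = FALSE]
  JB <- J[nA + seq_len(nB), , drop = FALSE]
  map <- .nnIndex(JA, JB)
  resid <- sqrt(rowSums((JA - JB[map, , drop = FALSE])^2))
  out <- new("Correspondence", map = as.integer(map), residual = resid,
             nTarget = as.integer(nB))
  attr(out, "alignmentQuality") <- al$quality
  out
}

#' Per-vertex weekly rate of change
#'
#' For each A-vertex v: `(fieldB[corr(v)] - fieldA[v]) / deltaWeeks`.
#'
#' @param fieldA,fieldB per-vertex numeric values on meshes A and B.
#' @param corr a [Correspondence-class] from A to B.
#' @param deltaWeeks positive gestational-age difference in weeks.
#' @return per-A-vertex rates (units of the field per week).
#' @export
vertexwiseRate <- function(fieldA, fieldB, corr, deltaWeeks) {
  if (deltaWeeks <= 0) stop("deltaWeeks must be positive")
  if (length(fieldA) != length(corr))
    stop("fieldA length must match the correspondence source")
  if (length(fieldB) < corr@nTarget)
    stop("fieldB shorter than the correspondence target")
  (fieldB[matchMap(corr)] - fieldA) / deltaWeeks
}
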
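#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib fetalmorpho, .registration = TRUE
NULL

.LABEL_CODES <- c(background = 0L, wm = 1L, ventricles = 2L, cerebellum = 3L)

#' Segmentation label volume
#'
#' A 3D integer segmentation grid on an isotropic voxel lattice. Label codes:
#' 0 background, 1 unmyelinated white matter, 2 ventricles, 3 cerebellum.
#' World coordinates follow the voxel-centre convention: the centre of voxel
#' (i,j,k) (zero-based) lies at `origin + c(i,j,k) * spacing`.
#'
#' @slot data 3D integer array of label codes.
#' @slot spacing voxel edge length in mm (isotropic, single positive number).
#' @slot origin world coordinate (mm) of the centre of voxel (0,0,0).
#' @export
setClass("LabelVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = 0.8, origin = c(0, 0, 0)))

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
      object@spacing <= 0)
    msg <- c(msg, "spacing must be a single positive number")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be a numeric vector of length 3")
  vals <- unique(as.vector(object@data))
  if (any(vals != round(vals)))
    msg <- c(msg, "label data must be integer-valued")
  if (!all(vals %in% .LABEL_CODES))
    msg <- c(msg, sprintf("unknown label codes: %s",
                          paste(setdiff(vals, .LABEL_CODES), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Closed triangulated surface mesh
#'
#' Triangle mesh in world (mm) coordinates with counter-clockwise winding and
#' outward-pointing normals. `vertexData` carries optional per-vertex
#' annotations (e.g. lobe labels or parameter-grid tags from the synthetic
#' generator).
#'
#' @slot vertices numeric matrix (n x 3), mm.
#' @slot faces integer matrix (m x 3) of 1-based vertex indices.
#' @slot structureLabel integer label code of the structure the mesh bounds.
#' @slot vertexData data.frame with n rows (possibly zero columns).
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix",
                 structureLabel = "integer", vertexData = "data.frame"),
  prototype(structureLabel = NA_integer_, vertexData = data.frame()))

setValidity("SurfaceMesh", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3L || !is.numeric(object@vertices))
    msg <- c(msg, "vertices must be a numeric n x 3 matrix")
  if (ncol(object@faces) != 3L)
    msg <- c(msg, "faces must be an m x 3 index matrix")
  f <- object@faces
  if (length(f) && (any(f < 1L) || any(f > nrow(object@vertices))))
    msg <- c(msg, "face indices out of range")
  if (length(f) && any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    msg <- c(msg, "degenerate face (repeated vertex index)")
  if (nrow(object@vertexData) && nrow(object@vertexData) != nrow(object@vertices))
    msg <- c(msg, "vertexData rows must match vertex count")
  if (length(msg)) msg else TRUE
})

#' Per-vertex curvature field
#'
#' Principal curvatures and the two derived gyrification markers for one
#' mesh: curvedness C = sqrt((k1^2 + k2^2)/2) (mm^-1) and shape index
#' SI = (2/pi) atan((k1 + k2)/(k1 - k2)) in [-1, 1], with k1 >= k2 and the
#' convention that convex regions have positive curvature (SI = +1 on a
#' convex dome/gyrus, -1 in a concave cup/sulcus).
#'
#' @slot kappa1,kappa2 principal curvatures, mm^-1, `kappa1 >= kappa2`.
#' @slot curvedness non-negative, mm^-1.
#' @slot shapeIndex in [-1, 1]; +/-1 at umbilic points by sign convention.
#' @export
setClass("CurvatureField",
  representation(kappa1 = "numeric", kappa2 = "numeric",
                 curvedness = "numeric", shapeIndex = "numeric"))

setValidity("CurvatureField", function(object) {
  n <- length(object@kappa1)
  msg <- character()
  if (length(object@kappa2) != n || length(object@curvedness) != n ||
      length(object@shapeIndex) != n)
    msg <- c(msg, "all fields must have equal length")
  if (any(object@kappa1 + 1e-9 < object@kappa2))
    msg <- c(msg, "kappa1 must be >= kappa2 at every vertex")
  if (any(object@curvedness < 0))
    msg <- c(msg, "curvedness must be non-negative")
  if (any(abs(object@shapeIndex) > 1 + 1e-9))
    msg <- c(msg, "shape index must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Laplacian spectral embedding of a mesh
#'
#' Eigenvalues are the k+1 smallest of the (cotangent-weighted, mass-
#' normalized) mesh Laplacian, ascending, the first ~0 with constant mode.
#' `modes` holds the k non-trivial eigenvectors, each normalized to unit
#' magnitude, with a deterministic sign convention.
#'
#' @slot eigenvalues numeric vector of length k+1, non-negative, ascending.
#' @slot modes numeric matrix (n x k).
#' @export
setClass("SpectralEmbedding",
  representation(eigenvalues = "numeric", modes = "matrix"))

setValidity("SpectralEmbedding", function(object) {
  msg <- character()
  ev <- object@eigenvalues
  if (length(ev) != ncol(object@modes) + 1L)
    msg <- c(msg, "need k+1 eigenvalues for k retained modes")
  if (any(ev < -1e-8)) msg <- c(msg, "eigenvalues must be non-negative")
  if (is.unsorted(ev + 1e-12)) msg <- c(msg, "eigenvalues must be ascending")
  if (length(msg)) msg else TRUE
})

#' Vertex correspondence between two meshes
#'
#' For each vertex of mesh A, the index of its matched vertex on mesh B, with
#' the per-vertex residual distance in joint spectral coordinates.
#'
#' @slot map integer vector, length = vertices of A, values in 1..nB.
#' @slot residual numeric vector of spectral-distance residuals.
#' @slot nTarget vertex count of mesh B.
#' @export
setClass("Correspondence",
  representation(map = "integer", residual = "numeric", nTarget = "integer"))

setValidity("Correspondence", function(object) {
  msg <- character()
  if (any(is.na(object@map)))
    msg <- c(msg, "map must be total (no unmatched vertices)")
  if (length(object@map) &&
      (min(object@map) < 1L || max(object@map) > object@nTarget))
    msg <- c(msg, "map indices out of range")
  if (length(object@residual) != length(object@map))
    msg <- c(msg, "residual length must match map length")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort configuration
#'
#' Bundles every knob of the synthetic longitudinal cohort generator: group
#' sizes, gestational-age schedules, per-structure growth models, the
#' cortical folding model and voxel spacing. See [cohortConfig()] for the
#' documented defaults.
#'
#' @slot nOSB,nControl subject counts.
#' @slot seed integer master seed.
#' @slot spacing voxel edge length, mm.
#' @slot gaSchedule,growth,folding,effects,mesh parameter lists.
#' @export
setClass("CohortConfig",
  representation(nOSB = "integer", nControl = "integer", seed = "integer",
                 spacing = "numeric", gaSchedule = "list", growth = "list",
                 folding = "list", effects = "list", mesh = "list"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nOSB < 1L || object@nControl < 1L)
    msg <- c(msg, "group counts must be >= 1")
  if (object@spacing <= 0) msg <- c(msg, "spacing must be positive")
  sds <- unlist(lapply(object@gaSchedule, `[[`, "sd"))
  if (any(sds < 0)) msg <- c(msg, "GA schedule SDs must be >= 0")
  if (any(unlist(object@folding[c("ampBase", "ampSlope")]) < 0))
    msg <- c(msg, "folding amplitudes must be >= 0")
  if (length(msg)) msg else TRUE
})
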
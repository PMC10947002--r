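#' @describeIn LabelVolume-class voxel edge length (mm)
#' @param object,x an object
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))

#' @describeIn LabelVolume-class world coordinate of voxel (0,0,0) centre
#' @export
setGeneric("origin", function(object) standardGeneric("origin"))

#' @describeIn LabelVolume-class the raw 3D label array
#' @export
setGeneric("labelArray", function(object) standardGeneric("labelArray"))

#' @describeIn SurfaceMesh-class n x 3 vertex coordinate matrix (mm)
#' @export
setGeneric("vertices", function(object) standardGeneric("vertices"))

#' @describeIn SurfaceMesh-class m x 3 face index matrix (1-based)
#' @export
setGeneric("faces", function(object) standardGeneric("faces"))

#' @describeIn SurfaceMesh-class label code of the bounded structure
#' @export
setGeneric("structureLabel", function(object) standardGeneric("structureLabel"))

#' @describeIn SurfaceMesh-class per-vertex annotation data.frame
#' @export
setGeneric("vertexData", function(object) standardGeneric("vertexData"))

#' @describeIn SurfaceMesh-class number of vertices
#' @export
setGeneric("nVertices", function(object) standardGeneric("nVertices"))

#' @describeIn SurfaceMesh-class number of faces
#' @export
setGeneric("nFaces", function(object) standardGeneric("nFaces"))

#' @describeIn CurvatureField-class larger principal curvature (mm^-1)
#' @export
setGeneric("kappa1", function(object) standardGeneric("kappa1"))

#' @describeIn CurvatureField-class smaller principal curvature (mm^-1)
#' @export
setGeneric("kappa2", function(object) standardGeneric("kappa2"))

#' @describeIn CurvatureField-class per-vertex curvedness (mm^-1)
#' @export
setGeneric("curvednessValues", function(object) standardGeneric("curvednessValues"))

#' @describeIn CurvatureField-class per-vertex shape index in [-1, 1]
#' @export
setGeneric("shapeIndexValues", function(object) standardGeneric("shapeIndexValues"))

#' @describeIn SpectralEmbedding-class ascending Laplacian eigenvalues
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))

#' @describeIn SpectralEmbedding-class n x k matrix of retained eigenmodes
#' @export
setGeneric("modes", function(object) standardGeneric("modes"))

#' @describeIn Correspondence-class matched B-vertex index per A-vertex
#' @export
setGeneric("matchMap", function(object) standardGeneric("matchMap"))

#' @describeIn Correspondence-class per-vertex spectral residual
#' @export
setGeneric("matchResidual", function(object) standardGeneric("matchResidual"))
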
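#' @rdname LabelVolume-class
#' @aliases spacing,LabelVolume-method
setMethod("spacing", "LabelVolume", function(object) object@spacing)

#' @rdname LabelVolume-class
setMethod("origin", "LabelVolume", function(object) object@origin)

#' @rdname LabelVolume-class
setMethod("labelArray", "LabelVolume", function(object) object@data)

#' @rdname LabelVolume-class
setMethod("dim", "LabelVolume", function(x) dim(x@data))

#' @rdname SurfaceMesh-class
setMethod("vertices", "SurfaceMesh", function(object) object@vertices)

#' @rdname SurfaceMesh-class
setMethod("faces", "SurfaceMesh", function(object) object@faces)

#' @rdname SurfaceMesh-class
setMethod("structureLabel", "SurfaceMesh", function(object) object@structureLabel)

#' @rdname SurfaceMesh-class
setMethod("vertexData", "SurfaceMesh", function(object) object@vertexData)

#' @rdname SurfaceMesh-class
setMethod("nVertices", "SurfaceMesh", function(object) nrow(object@vertices))

#' @rdname SurfaceMesh-class
setMethod("nFaces", "SurfaceMesh", function(object) nrow(object@faces))

#' @rdname CurvatureField-class
setMethod("kappa1", "CurvatureField", function(object) object@kappa1)

#' @rdname CurvatureField-class
setMethod("kappa2", "CurvatureField", function(object) object@kappa2)

#' @rdname CurvatureField-class
setMethod("curvednessValues", "CurvatureField", function(object) object@curvedness)

#' @rdname CurvatureField-class
setMethod("shapeIndexValues", "CurvatureField", function(object) object@shapeIndex)

#' @rdname CurvatureField-class
setMethod("length", "CurvatureField", function(x) length(x@kappa1))

#' @rdname SpectralEmbedding-class
setMethod("eigenvalues", "SpectralEmbedding", function(object) object@eigenvalues)

#' @rdname SpectralEmbedding-class
setMethod("modes", "SpectralEmbedding", function(object) object@modes)

#' @rdname Correspondence-class
setMethod("matchMap", "Correspondence", function(object) object@map)

#' @rdname Correspondence-class
setMethod("matchResidual", "Correspondence", function(object) object@residual)

#' @rdname Correspondence-class
setMethod("length", "Correspondence", function(x) length(x@map))

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@data)
  tab <- table(factor(object@data, levels = .LABEL_CODES))
  cat(sprintf("LabelVolume %d x %d x %d @ %.3g mm\n", d[1], d[2], d[3],
              object@spacing))
  cat(sprintf("  origin: (%.2f, %.2f, %.2f) mm\n", object@origin[1],
              object@origin[2], object@origin[3]))
  cat(sprintf("  voxels: background %d, wm %d, ventricles %d, cerebellum %d\n",
              tab[1], tab[2], tab[3], tab[4]))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d faces (structure label %s)\n",
              nrow(object@vertices), nrow(object@faces),
              ifelse(is.na(object@structureLabel), "NA",
                     object@structureLabel)))
  if (ncol(object@vertexData))
    cat("  vertexData:", paste(names(object@vertexData), collapse = ", "), "\n")
})

setMethod("show", "CurvatureField", function(object) {
  cat(sprintf("CurvatureField over %d vertices\n", length(object@kappa1)))
  cat(sprintf("  curvedness median %.4g mm^-1, shape index median %.3f\n",
              stats::median(object@curvedness), stats::median(object@shapeIndex)))
})

setMethod("show", "SpectralEmbedding", function(object) {
  cat(sprintf("SpectralEmbedding: %d modes over %d vertices\n",
              ncol(object@modes), nrow(object@modes)))
  cat("  eigenvalues:", paste(signif(object@eigenvalues, 4), collapse = ", "),
      "\n")
})

setMethod("show", "Correspondence", function(object) {
  cat(sprintf("Correspondence: %d -> %d vertices, median residual %.4g\n",
              length(object@map), object@nTarget,
              stats::median(object@residual)))
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: %d OSB + %d control subjects, seed %d, %.2g mm voxels\n",
              object@nOSB, object@nControl, object@seed, object@spacing))
})
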
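# S4 classes for the imaging pipeline. Coordinate convention throughout:
# origin at the top-left image corner, x = column, y = row, in continuous
# pixel units, so the centre of the pixel in (1-based) matrix cell [r, c]
# is (x, y) = (c - 0.5, r - 0.5).

# shoelace area of a polygon given as an n x 2 (x, y) matrix
polygonArea <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

#' Polygonal region of interest
#'
#' A single labelled region marked on a specimen image as a closed polygonal
#' line with an arbitrary number of vertices.
#'
#' @slot label character; region name, normalized to lower_snake_case.
#'   Typically one of [canonicalRegions()], but free text is allowed.
#' @slot vertices numeric matrix with columns (x, y), one row per vertex,
#'   in continuous pixel coordinates (origin top-left).
#'
#' @export
setClass("PolygonRoI",
  representation(label = "character", vertices = "matrix"),
  validity = function(object) {
    v <- object@vertices
    if (length(object@label) != 1L || !nzchar(object@label))
      return("'label' must be a single non-empty string")
    if (!is.numeric(v) || ncol(v) != 2L)
      return("'vertices' must be a numeric matrix with columns (x, y)")
    if (nrow(v) < 3L)
      return(sprintf("region '%s': a polygon needs at least 3 vertices",
                     object@label))
    if (any(!is.finite(v)))
      return(sprintf("region '%s': non-finite vertex coordinates",
                     object@label))
    d <- v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE]
    if (any(rowSums(abs(d)) == 0))
      return(sprintf("region '%s': two consecutive vertices are identical",
                     object@label))
    if (polygonArea(v) <= 0)
      return(sprintf("region '%s': polygon area must be > 0", object@label))
    TRUE
  }
)

#' @param label region name (normalized to lower_snake_case).
#' @param vertices n x 2 numeric matrix (or coercible) of (x, y) vertices.
#' @rdname PolygonRoI-class
#' @examples
#' tri <- PolygonRoI("Face", rbind(c(0, 0), c(4, 0), c(0, 4)))
#' roiLabel(tri)
#' @export
PolygonRoI <- function(label, vertices) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  new("PolygonRoI", label = normalizeLabel(label), vertices = vertices)
}

#' @describeIn PolygonRoI-class region label accessor.
#' @param x,object a `PolygonRoI`.
#' @export
roiLabel <- function(x) x@label

#' @describeIn PolygonRoI-class vertex matrix accessor.
#' @export
roiVertices <- function(x) x@vertices

setMethod("show", "PolygonRoI", function(object) {
  cat(sprintf("PolygonRoI '%s': %d vertices, area %.1f px^2\n",
              object@label, nrow(object@vertices),
              polygonArea(object@vertices)))
})

#' Set of regions of interest for one image
#'
#' All regions marked on one specimen photograph, together with the image
#' identity and pixel dimensions. Persisted as a JSON sidecar file (see
#' [saveRoiSet()]).
#'
#' @slot imageId character; the image file stem.
#' @slot imageWidth,imageHeight integer pixel dimensions of the image.
#' @slot regions list of [PolygonRoI-class] objects.
#'
#' @export
setClass("RoISet",
  representation(imageId = "character", imageWidth = "integer",
                 imageHeight = "integer", regions = "list"),
  validity = function(object) {
    if (length(object@imageId) != 1L || !nzchar(object@imageId))
      return("'imageId' must be a single non-empty string")
    if (object@imageWidth < 1L || object@imageHeight < 1L)
      return("image dimensions must be positive")
    ok <- vapply(object@regions, is, logical(1), class2 = "PolygonRoI")
    if (!all(ok))
      return("'regions' must be a list of PolygonRoI objects")
    TRUE
  }
)

#' @param imageId image file stem.
#' @param imageWidth,imageHeight image dimensions in pixels.
#' @param regions list of [PolygonRoI-class] objects.
#' @param quiet suppress validation warnings (out-of-bounds vertices,
#'   more than four regions, duplicate labels).
#' @rdname RoISet-class
#' @examples
#' rs <- RoISet("bee_001", 64, 48,
#'              list(PolygonRoI("face", rbind(c(2, 2), c(20, 2), c(2, 20)))))
#' roiLabels(rs)
#' @export
RoISet <- function(imageId, imageWidth, imageHeight, regions = list(),
                   quiet = FALSE) {
  rs <- new("RoISet", imageId = as.character(imageId),
            imageWidth = as.integer(imageWidth),
            imageHeight = as.integer(imageHeight), regions = regions)
  if (!quiet) {
    w <- validateRoiSet(rs)
    for (msg in w) warning(msg, call. = FALSE)
  }
  rs
}

#' @describeIn RoISet-class list of regions.
#' @param x,object a `RoISet`.
#' @export
regions <- function(x) x@regions

#' @describeIn RoISet-class labels of all regions, in order.
#' @export
roiLabels <- function(x) vapply(x@regions, roiLabel, character(1))

#' @describeIn RoISet-class image file stem.
#' @export
imageId <- function(x) x@imageId

#' @describeIn RoISet-class image (width, height) in pixels.
#' @export
imageSize <- function(x) c(width = x@imageWidth, height = x@imageHeight)

setMethod("show", "RoISet", function(object) {
  cat(sprintf("RoISet '%s' (%d x %d px), %d region(s)\n", object@imageId,
              object@imageWidth, object@imageHeight, length(object@regions)))
  for (r in object@regions)
    cat(sprintf("  - %s (%d vertices)\n", r@label, nrow(r@vertices)))
})

#' Disk structuring element (radius of influence)
#'
#' The neighbourhood over which each pixel's gray-value histogram is
#' collected by the entropy filter: the exact Euclidean disk of lattice
#' offsets \eqn{\{(di, dj): di^2 + dj^2 \le r^2\}}.
#'
#' @slot radius integer radius of influence in pixels.
#' @slot offsets integer matrix of (di, dj) displacements, one per row.
#'
#' @seealso [diskOffsets()]
#' @export
setClass("StructuringElement",
  representation(radius = "integer", offsets = "matrix"),
  validity = function(object) {
    o <- object@offsets
    if (object@radius < 0L) return("'radius' must be >= 0")
    if (!any(o[, 1] == 0L & o[, 2] == 0L))
      return("structuring element must contain the origin (0, 0)")
    if (any(o[, 1]^2 + o[, 2]^2 > object@radius^2))
      return("all offsets must satisfy di^2 + dj^2 <= r^2")
    key <- function(m) sort(paste(m[, 1], m[, 2]))
    if (!identical(key(o), key(cbind(-o[, 1], -o[, 2]))) ||
        !identical(key(o), key(o[, 2:1, drop = FALSE])))
      return("offset set must be symmetric under negation and axis swap")
    TRUE
  }
)

#' @describeIn StructuringElement-class offset matrix accessor.
#' @param x,object a `StructuringElement`.
#' @export
seOffsets <- function(x) x@offsets

#' @describeIn StructuringElement-class radius accessor.
#' @export
seRadius <- function(x) x@radius

setMethod("show", "StructuringElement", function(object) {
  cat(sprintf("StructuringElement: disk, r = %d px, %d offsets\n",
              object@radius, nrow(object@offsets)))
})

#' Pre-processing configuration
#'
#' Parameters of the artifact-removal stage: local-mean adaptive
#' thresholding followed by deletion of small and near-circular objects
#' (pollen grains and debris).
#'
#' @slot minArea minimum object area in pixels; smaller objects are deleted
#'   (default 8).
#' @slot circTol circularity tolerance; objects with \eqn{S \ge 1 -}
#'   `circTol` are deleted as near-circular (default 0.05). The bound is
#'   one-sided because the centre-to-centre boundary walk of a digitized
#'   disk is shorter than its continuum circumference, placing S of round
#'   blobs at and slightly above 1; elongated objects sit far below.
#' @slot thresholdWindow odd side length (px) of the square local-mean
#'   window (default 15).
#' @slot thresholdSensitivity multiplier of the local mean defining the
#'   segmentation threshold (default 1.45): with `polarity = "bright"` a
#'   pixel is a foreground candidate iff its value exceeds
#'   `thresholdSensitivity` times its local mean. The default targets
#'   compact artifacts that are strongly brighter than their surround
#'   (pollen is typically ~1.8x its local mean) while leaving textured
#'   cuticle, which stays within ~1.3x, unsegmented.
#' @slot polarity `"bright"`, `"dark"` or `"both"`: whether artifacts are
#'   sought as locally bright objects, locally dark objects, or both.
#' @slot enabled logical; when `FALSE` the whole pre-processing stage is a
#'   no-op (nothing is excluded).
#'
#' @export
setClass("PreprocessConfig",
  representation(minArea = "numeric", circTol = "numeric",
                 thresholdWindow = "integer", thresholdSensitivity = "numeric",
                 polarity = "character", enabled = "logical"),
  validity = function(object) {
    if (object@minArea < 1) return("'minArea' must be >= 1")
    if (object@circTol <= 0 || object@circTol >= 1)
      return("'circTol' must lie strictly between 0 and 1")
    if (object@thresholdWindow < 3L || object@thresholdWindow %% 2L == 0L)
      return("'thresholdWindow' must be an odd integer >= 3")
    if (object@thresholdSensitivity <= 0)
      return("'thresholdSensitivity' must be > 0")
    if (!object@polarity %in% c("bright", "dark", "both"))
      return("'polarity' must be one of 'bright', 'dark', 'both'")
    TRUE
  }
)

#' @param minArea,circTol,thresholdWindow,thresholdSensitivity,polarity,enabled
#'   see the slot documentation.
#' @rdname PreprocessConfig-class
#' @examples
#' preprocessConfig()
#' preprocessConfig(enabled = FALSE)
#' @export
preprocessConfig <- function(minArea = 8, circTol = 0.05,
                             thresholdWindow = 15L,
                             thresholdSensitivity = 1.45,
                             polarity = "bright", enabled = TRUE) {
  new("PreprocessConfig", minArea = as.numeric(minArea),
      circTol = as.numeric(circTol),
      thresholdWindow = as.integer(thresholdWindow),
      thresholdSensitivity = as.numeric(thresholdSensitivity),
      polarity = polarity, enabled = isTRUE(enabled))
}

setMethod("show", "PreprocessConfig", function(object) {
  cat(sprintf(paste0("PreprocessConfig: %s; minArea = %g px, circTol = %g, ",
                     "window = %d px, sensitivity = %g, polarity = %s\n"),
              if (object@enabled) "enabled" else "disabled",
              object@minArea, object@circTol, object@thresholdWindow,
              object@thresholdSensitivity, object@polarity))
})

#' Labelled segmented objects
#'
#' Result of 8-connected component labelling of the thresholded artifact
#' candidates, with per-object area, boundary-trace perimeter and
#' circularity \eqn{S = 4\pi \cdot Area / Perimeter^2}.
#'
#' @slot labelImage integer matrix; 0 = background, k = pixels of object k.
#' @slot objects data.frame with one row per object: `object`, `area`
#'   (pixel count), `perimeter` (px; accumulated centre-to-centre boundary
#'   distance, 0 for a single pixel), `circularity` (NA when perimeter 0).
#'
#' @export
setClass("LabeledObjects",
  representation(labelImage = "matrix", objects = "data.frame"),
  validity = function(object) {
    k <- nrow(object@objects)
    lab <- object@labelImage
    if (k > 0 && !identical(sort(unique(as.integer(object@objects$object))),
                            seq_len(k)))
      return("object ids must be contiguous 1..K")
    if (max(lab, 0L) != k)
      return("label image and object table disagree on object count")
    if (k > 0 && any(object@objects$area < 1))
      return("object areas must be >= 1")
    TRUE
  }
)

#' @describeIn LabeledObjects-class per-object measurement table.
#' @param x,object a `LabeledObjects`.
#' @export
objectTable <- function(x) x@objects

#' @describeIn LabeledObjects-class integer label image.
#' @export
labelImage <- function(x) x@labelImage

#' @describeIn LabeledObjects-class number of objects.
#' @export
nObjects <- function(x) nrow(x@objects)

setMethod("show", "LabeledObjects", function(object) {
  cat(sprintf("LabeledObjects: %d object(s) on a %d x %d image\n",
              nrow(object@objects), nrow(object@labelImage),
              ncol(object@labelImage)))
})

#' Combined entropy image
#'
#' Per-pixel combined entropy \eqn{E_S = E_R \cdot E_G \cdot E_B} (product
#' of the three channel entropy layers, each in bits) together with a
#' validity mask: pixels deleted by pre-processing are invalid, carry
#' \eqn{E_S = 0}, and are omitted from region statistics.
#'
#' @slot es numeric matrix of combined entropy values (>= 0).
#' @slot valid logical matrix, `FALSE` where the pixel was excluded.
#'
#' @export
setClass("EntropyImage",
  representation(es = "matrix", valid = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@es), dim(object@valid)))
      return("'es' and 'valid' dimensions differ")
    if (any(object@es < 0)) return("combined entropy must be >= 0")
    if (any(object@es[!object@valid] != 0))
      return("excluded pixels must carry E_S = 0")
    TRUE
  }
)

#' @describeIn EntropyImage-class combined entropy matrix.
#' @param x,object an `EntropyImage`.
#' @export
entropyValues <- function(x) x@es

#' @describeIn EntropyImage-class validity mask.
#' @export
validMask <- function(x) x@valid

setMethod("show", "EntropyImage", function(object) {
  v <- object@es[object@valid]
  cat(sprintf("EntropyImage %d x %d px; %d valid px; E_S range [%.3g, %.3g]\n",
              nrow(object@es), ncol(object@es), length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})
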
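#' @useDynLib contourQC, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

## Central S4 containers. All three carry an explicit physical geometry:
## voxel spacing (dx, dy, dz) in mm and a world-space origin in mm, with the
## fixed axis convention x = in-plane column, y = in-plane row, z = slice.

#' ImageVolume: a 3D scalar volume with physical voxel spacing
#'
#' A minimal container for an MRI-like 3D scalar grid. Intensities are
#' stored as a numeric (double) array; \code{spacing} is the physical voxel
#' size in mm along (x, y, z) and \code{origin} the world coordinate of the
#' centre of the first voxel.
#'
#' @slot data 3D numeric array of intensities (arbitrary units).
#' @slot spacing Numeric length-3, voxel size in mm; all strictly positive.
#' @slot origin Numeric length-3, world position (mm) of voxel (1,1,1).
#' @slot metadata List of free-form metadata (provenance, shifts, ...).
#'
#' @seealso [imageVolume()], [readVolume()], [BinaryMask-class]
#' @export
setClass("ImageVolume",
    representation(data = "array", spacing = "numeric", origin = "numeric",
                   metadata = "list"),
    prototype(data = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
              origin = c(0, 0, 0), metadata = list()))

.validGeometry <- function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 3L)
        msg <- c(msg, "data must have exactly 3 dimensions")
    if (any(d < 1L))
        msg <- c(msg, "every dimension must have extent >= 1")
    sp <- object@spacing
    if (length(sp) != 3L || !all(is.finite(sp)) || any(sp <= 0))
        msg <- c(msg, "spacing must be 3 strictly positive finite values (mm)")
    if (length(object@origin) != 3L || !all(is.finite(object@origin)))
        msg <- c(msg, "origin must be 3 finite values (mm)")
    msg
}

setValidity("ImageVolume", function(object) {
    msg <- .validGeometry(object)
    if (!is.numeric(object@data))
        msg <- c(msg, "data must be numeric")
    if (length(msg)) msg else TRUE
})

#' BinaryMask: a 3D organ mask with physical voxel spacing
#'
#' A logical 3D array marking the voxels inside one structure (organ),
#' sharing the geometry conventions of [ImageVolume-class].
#'
#' @slot data 3D logical array.
#' @slot spacing,origin As in [ImageVolume-class].
#' @slot metadata List of free-form metadata (flags such as \code{empty}).
#'
#' @seealso [binaryMask()], [StructureSet-class], [volumeCC()]
#' @export
setClass("BinaryMask",
    representation(data = "array", spacing = "numeric", origin = "numeric",
                   metadata = "list"),
    prototype(data = array(FALSE, c(1, 1, 1)), spacing = c(1, 1, 1),
              origin = c(0, 0, 0), metadata = list()))

setValidity("BinaryMask", function(object) {
    msg <- .validGeometry(object)
    if (!is.logical(object@data))
        msg <- c(msg, "mask data must be logical")
    if (length(msg)) msg else TRUE
})

#' StructureSet: named organ masks on one shared grid
#'
#' An ordered collection of [BinaryMask-class] objects (one per organ) that
#' all share the same grid shape, spacing, and origin — the in-memory
#' analogue of a radiotherapy structure set restricted to voxelised masks.
#'
#' @slot organs Named list of \code{BinaryMask}; names are organ names.
#' @slot metadata List (e.g. \code{empty_organs} flagged at load time).
#'
#' @seealso [structureSet()], [readStructures()], [evaluatePair()]
#' @export
setClass("StructureSet",
    representation(organs = "list", metadata = "list"),
    prototype(organs = list(), metadata = list()))

setValidity("StructureSet", function(object) {
    msg <- character()
    org <- object@organs
    if (length(org)) {
        if (is.null(names(org)) || any(!nzchar(names(org))))
            msg <- c(msg, "all organs must be named")
        if (anyDuplicated(names(org)))
            msg <- c(msg, "organ names must be unique")
        if (!all(vapply(org, is, logical(1), "BinaryMask")))
            msg <- c(msg, "all organs must be BinaryMask objects")
        else {
            ref <- org[[1]]
            same <- vapply(org, function(m)
                identical(dim(m@data), dim(ref@data)) &&
                isTRUE(all.equal(m@spacing, ref@spacing, tolerance = 1e-9)),
                logical(1))
            if (!all(same))
                msg <- c(msg, "all organs must share shape and spacing")
        }
    }
    if (length(msg)) msg else TRUE
})

#' SurfaceSample: boundary elements of a voxel mask
#'
#' Boundary of a [BinaryMask-class] represented as exposed voxel faces:
#' physical face-centre positions (mm) and per-face areas (mm^2), or, in
#' slice-contour mode, in-plane edge midpoints with lengths (mm).
#'
#' @slot points Numeric matrix, one row per element, columns x/y/z in mm.
#' @slot areas Numeric vector of per-element areas (mm^2) or lengths (mm).
#' @slot lattice Integer matrix of half-integer-lattice indices (internal,
#'   used by the exact distance transform).
#' @slot latticeDims Integer length-3, extents of the half-integer lattice.
#' @slot spacing Voxel spacing of the parent mask (mm).
#'
#' @seealso [extractSurface()], [surfaceDistances()]
#' @export
setClass("SurfaceSample",
    representation(points = "matrix", areas = "numeric", lattice = "matrix",
                   latticeDims = "integer", spacing = "numeric"),
    prototype(points = matrix(numeric(0), 0, 3), areas = numeric(0),
              lattice = matrix(integer(0), 0, 3), latticeDims = c(1L, 1L, 1L),
              spacing = c(1, 1, 1)))

setValidity("SurfaceSample", function(object) {
    msg <- character()
    if (ncol(object@points) != 3L)
        msg <- c(msg, "points must have 3 columns")
    if (nrow(object@points) != length(object@areas))
        msg <- c(msg, "points and areas must have equal length")
    if (any(object@areas <= 0))
        msg <- c(msg, "all element areas/lengths must be positive")
    if (length(msg)) msg else TRUE
})

## ---- constructors -----------------------------------------------------

#' Construct an ImageVolume
#'
#' @param data 3D numeric array.
#' @param spacing Voxel size (dx, dy, dz) in mm.
#' @param origin World position of the first voxel centre, mm.
#' @param metadata Optional list of metadata.
#' @return An [ImageVolume-class].
#' @examples
#' v <- imageVolume(array(rnorm(64), c(4, 4, 4)), spacing = c(1.1875, 1.1875, 3))
#' spacing(v)
#' @export
imageVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        metadata = list()) {
    data <- array(as.numeric(data), dim(data))
    new("ImageVolume", data = data, spacing = as.numeric(spacing),
        origin = as.numeric(origin), metadata = metadata)
}

#' Construct a BinaryMask
#'
#' @param data 3D array coercible to logical (nonzero = inside).
#' @inheritParams imageVolume
#' @return A [BinaryMask-class].
#' @examples
#' m <- binaryMask(array(c(rep(0, 32), rep(1, 32)), c(4, 4, 4)))
#' volumeCC(m)
#' @export
binaryMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       metadata = list()) {
    d <- array(as.logical(data), dim(data))
    new("BinaryMask", data = d, spacing = as.numeric(spacing),
        origin = as.numeric(origin), metadata = metadata)
}

#' Construct a StructureSet from named masks
#'
#' @param organs Named list of [BinaryMask-class] objects sharing geometry.
#' @param metadata Optional list.
#' @return A [StructureSet-class].
#' @export
structureSet <- function(organs, metadata = list()) {
    new("StructureSet", organs = organs, metadata = metadata)
}

## ---- accessors --------------------------------------------------------

#' @rdname accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname accessors
#' @export
setGeneric("organNames", function(x) standardGeneric("organNames"))
#' @rdname accessors
#' @export
setGeneric("volumeCC", function(x) standardGeneric("volumeCC"))

#' Accessors for volumes, masks and structure sets
#'
#' \code{imgData} returns the raw array; \code{spacing} and \code{origin}
#' the physical geometry (mm); \code{organNames} the organ names of a
#' structure set; \code{volumeCC} the physical volume of a mask in cubic
#' centimetres (voxel count times voxel volume / 1000).
#'
#' @param x An \code{ImageVolume}, \code{BinaryMask} or \code{StructureSet}.
#' @name accessors
#' @aliases imgData spacing origin organNames volumeCC
#' @examples
#' m <- binaryMask(array(TRUE, c(10, 10, 10)), spacing = c(1, 1, 1))
#' volumeCC(m)  # 1 cc
NULL

#' @rdname accessors
setMethod("imgData", "ImageVolume", function(x) x@data)
#' @rdname accessors
setMethod("imgData", "BinaryMask", function(x) x@data)
#' @rdname accessors
setMethod("spacing", "ImageVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "BinaryMask", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "StructureSet", function(x) {
    if (!length(x@organs)) stop("empty StructureSet has no geometry")
    x@organs[[1]]@spacing
})
#' @rdname accessors
setMethod("origin", "ImageVolume", function(x) x@origin)
#' @rdname accessors
setMethod("origin", "BinaryMask", function(x) x@origin)
#' @rdname accessors
setMethod("organNames", "StructureSet", function(x) names(x@organs))
#' @rdname accessors
setMethod("volumeCC", "BinaryMask", function(x)
    sum(x@data) * prod(x@spacing) / 1000)

#' @describeIn StructureSet-class extract one organ mask by name or index
#' @param x,i,j,... standard extraction arguments (only \code{i} is used).
#' @export
setMethod("[[", "StructureSet", function(x, i, j, ...) x@organs[[i]])

#' @describeIn StructureSet-class number of organs
#' @export
setMethod("length", "StructureSet", function(x) length(x@organs))

## ---- show methods -----------------------------------------------------

setMethod("show", "ImageVolume", function(object) {
    d <- dim(object@data)
    cat(sprintf("ImageVolume %d x %d x %d, spacing (%.6g, %.6g, %.6g) mm\n",
                d[1], d[2], d[3], object@spacing[1], object@spacing[2],
                object@spacing[3]))
    cat(sprintf("  intensity range [%.4g, %.4g]\n",
                min(object@data), max(object@data)))
})

setMethod("show", "BinaryMask", function(object) {
    d <- dim(object@data)
    cat(sprintf("BinaryMask %d x %d x %d, spacing (%.6g, %.6g, %.6g) mm\n",
                d[1], d[2], d[3], object@spacing[1], object@spacing[2],
                object@spacing[3]))
    cat(sprintf("  %d voxels inside (%.3g cc)\n", sum(object@data),
                volumeCC(object)))
})

setMethod("show", "StructureSet", function(object) {
    cat(sprintf("StructureSet with %d organ(s)\n", length(object@organs)))
    if (length(object@organs)) {
        d <- dim(object@organs[[1]]@data)
        cat(sprintf("  grid %d x %d x %d, spacing (%.6g, %.6g, %.6g) mm\n",
                    d[1], d[2], d[3], spacing(object)[1], spacing(object)[2],
                    spacing(object)[3]))
        cc <- vapply(object@organs, volumeCC, numeric(1))
        cat("  organs: ",
            paste(sprintf("%s (%.3g cc)", names(cc), cc), collapse = ", "),
            "\n", sep = "")
    }
})

setMethod("show", "SurfaceSample", function(object) {
    cat(sprintf("SurfaceSample with %d boundary elements, total %.4g mm^2|mm\n",
                nrow(object@points), sum(object@areas)))
})
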
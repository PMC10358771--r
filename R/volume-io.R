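#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file (.nii or .nii.gz) into an [ImageVolume-class].
#' Voxel spacing is taken from the file header (mm) and intensities are
#' widened to double precision. When the file carries a spatial transform,
#' the volume is first reoriented to the canonical RAS axis order (closest
#' to axial), so that slice-wise operations always iterate the z axis.
#'
#' @param path Path to a readable NIfTI-1 file.
#' @return An [ImageVolume-class] with header spacing and origin.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(imageVolume(array(rnorm(64), c(4, 4, 4)),
#'                         spacing = c(1.1875, 1.1875, 3)), f)
#' readVolume(f)
#' @seealso [writeVolume()], [readStructures()]
#' @export
readVolume <- function(path) {
    img <- .readNiftiCanonical(path)
    arr <- as.array(img)
    arr <- array(as.numeric(arr), dim(arr))   # strip NIfTI attributes
    arr <- .dropTrailingSingletons(arr)
    d <- dim(arr)
    if (length(d) < 3L) dim(arr) <- c(d, rep(1L, 3L - length(d)))
    if (length(dim(arr)) != 3L)
        stop(sprintf("'%s' is not a 3D image (dims: %s)", path,
                     paste(dim(arr), collapse = "x")))
    sp <- c(RNifti::pixdim(img), 1, 1, 1)[1:3]
    if (any(!is.finite(sp)) || any(sp <= 0))
        stop(sprintf("'%s' has non-positive voxel spacing in its header", path))
    storage.mode(arr) <- "double"
    imageVolume(arr, spacing = sp, origin = .niftiOrigin(img))
}

.readNiftiCanonical <- function(path) {
    if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
    img <- RNifti::readNifti(path)
    xf <- try(RNifti::xform(img), silent = TRUE)
    if (!inherits(xf, "try-error") && !all(xf[1:3, 1:3] == 0)) {
        ort <- try({ RNifti::orientation(img) <- "RAS"; img }, silent = TRUE)
        if (!inherits(ort, "try-error")) img <- ort
    }
    img
}

.dropTrailingSingletons <- function(arr) {
    d <- dim(arr)
    while (length(d) > 3L && d[length(d)] == 1L) {
        d <- d[-length(d)]
        dim(arr) <- d
    }
    arr
}

.niftiOrigin <- function(img) {
    xf <- try(RNifti::xform(img), silent = TRUE)
    if (inherits(xf, "try-error")) return(c(0, 0, 0))
    as.numeric(xf[1:3, 4])
}

#' Write a volume or label map to NIfTI
#'
#' Writes an [ImageVolume-class] (or an integer label array wrapped in one)
#' to a NIfTI-1 file with an RAS affine built from the object's spacing and
#' origin. Round-tripping through [readVolume()] preserves data, spacing,
#' and origin to floating-point precision.
#'
#' @param vol An [ImageVolume-class].
#' @param path Output path (.nii or .nii.gz).
#' @param datatype NIfTI storage type, \code{"double"} (default) or
#'   \code{"int16"}/\code{"uint8"} for label maps.
#' @return Invisibly, \code{path}.
#' @export
writeVolume <- function(vol, path, datatype = "double") {
    stopifnot(is(vol, "ImageVolume"))
    img <- RNifti::asNifti(vol@data)
    RNifti::pixdim(img) <- vol@spacing
    aff <- diag(c(vol@spacing, 1))
    aff[1:3, 4] <- vol@origin
    RNifti::qform(img) <- structure(aff, code = 2L)
    RNifti::sform(img) <- structure(aff, code = 2L)
    RNifti::writeNifti(img, path, datatype = datatype)
    invisible(path)
}

#' Read a structure set from an integer label map
#'
#' Splits an integer label map into one binary mask per named label. Label 0
#' is background. Labels listed in the table but absent from the volume
#' yield empty masks; these are flagged in the returned object's metadata
#' (\code{empty_organs}) and reported with a warning.
#'
#' @param labelMapPath Path to a NIfTI integer label map, or an
#'   [ImageVolume-class] holding one.
#' @param labelTable Mapping label -> organ name: a named character vector
#'   whose names are the integer labels (e.g. \code{c("1" = "liver")}), or
#'   the path to a JSON file of the form \code{{"1": "liver", ...}}.
#' @return A [StructureSet-class] with one mask per table entry, in table
#'   order.
#' @examples
#' lab <- array(0L, c(4, 4, 2)); lab[1:2, , ] <- 1L; lab[4, , ] <- 2L
#' ss <- readStructures(imageVolume(lab), c("1" = "liver", "2" = "spleen"))
#' organNames(ss)
#' @export
readStructures <- function(labelMapPath, labelTable) {
    vol <- if (is(labelMapPath, "ImageVolume")) labelMapPath
           else readVolume(labelMapPath)
    tab <- .parseLabelTable(labelTable)
    arr <- vol@data
    if (max(abs(arr - round(arr))) > 1e-6)
        stop("label map contains non-integer values")
    arr <- round(arr)
    masks <- lapply(as.integer(names(tab)), function(lb)
        binaryMask(arr == lb, spacing = vol@spacing, origin = vol@origin))
    names(masks) <- unname(tab)
    empty <- names(masks)[vapply(masks, function(m) !any(m@data), logical(1))]
    if (length(empty))
        warning(sprintf("organ(s) absent from label map: %s",
                        paste(empty, collapse = ", ")))
    structureSet(masks, metadata = list(empty_organs = empty))
}

.parseLabelTable <- function(labelTable) {
    if (is.character(labelTable) && length(labelTable) == 1L &&
        file.exists(labelTable))
        labelTable <- unlist(jsonlite::read_json(labelTable))
    tab <- vapply(labelTable, as.character, character(1))
    if (is.null(names(tab)) || any(!nzchar(names(tab))))
        stop("labelTable must be named by integer labels")
    labs <- suppressWarnings(as.integer(names(tab)))
    if (any(is.na(labs)) || any(labs == 0L))
        stop("labelTable names must be nonzero integers")
    if (anyDuplicated(tab)) stop("duplicate organ names in labelTable")
    if (anyDuplicated(labs)) stop("duplicate labels in labelTable")
    tab
}

#' Write a structure set as an integer label map
#'
#' Organs are written in set order; where masks overlap, the later organ
#' wins (label maps cannot represent overlap — keep per-organ files for
#' abutting structures).
#'
#' @param ss A [StructureSet-class].
#' @param path Output NIfTI path.
#' @param labels Integer labels to assign, default \code{seq_along(organs)}.
#' @return Invisibly, the label table used (named character vector).
#' @export
writeStructures <- function(ss, path, labels = seq_along(ss@organs)) {
    stopifnot(is(ss, "StructureSet"), length(ss@organs) > 0,
              length(labels) == length(ss@organs))
    m1 <- ss@organs[[1]]
    lab <- array(0, dim(m1@data))
    for (k in seq_along(ss@organs)) lab[ss@organs[[k]]@data] <- labels[k]
    writeVolume(imageVolume(lab, spacing = m1@spacing, origin = m1@origin),
                path, datatype = "int16")
    tab <- stats::setNames(names(ss@organs), as.character(labels))
    invisible(tab)
}

# Fixed report column schema shared by writers/readers.
.reportColumns <- c("case_id", "organ", "dsc", "mda_mm", "hd95_mm",
                    "pvd_pct", "sdsc", "apl_mm", "rapl_mm_per_cc",
                    "ref_volume_cc", "auto_volume_cc")

#' Write a metrics/grades report
#'
#' Serialises per-(case, organ) metric records — the output of
#' [evaluatePair()], optionally augmented with category and score columns —
#' to CSV or JSON with locale-independent formatting.
#'
#' @param results Non-empty data.frame with at least columns \code{case_id},
#'   \code{organ} and the six metric columns (\code{dsc}, \code{mda_mm},
#'   \code{hd95_mm}, \code{pvd_pct}, \code{sdsc}, \code{apl_mm},
#'   \code{rapl_mm_per_cc}).
#' @param path Output path.
#' @param format \code{"csv"} or \code{"json"}.
#' @param digits Decimal digits written (default 6).
#' @return Invisibly, \code{path}.
#' @seealso [readReport()]
#' @export
writeReport <- function(results, path, format = c("csv", "json"),
                        digits = 6) {
    format <- match.arg(format)
    if (!is.data.frame(results) || nrow(results) == 0)
        stop("results must be a non-empty data.frame")
    need <- c("case_id", "organ", "dsc", "mda_mm", "hd95_mm", "pvd_pct",
              "sdsc", "apl_mm", "rapl_mm_per_cc")
    miss <- setdiff(need, names(results))
    if (length(miss))
        stop(sprintf("results lacks required column(s): %s",
                     paste(miss, collapse = ", ")))
    out <- results
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(x) round(x, digits))
    if (format == "csv") {
        utils::write.csv(out, path, row.names = FALSE, na = "")
    } else {
        jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                             auto_unbox = TRUE, digits = NA)
    }
    invisible(path)
}

#' Read a report written by [writeReport()]
#'
#' @param path Path to the CSV or JSON report.
#' @param format \code{"csv"} or \code{"json"}; guessed from the extension
#'   by default.
#' @return A data.frame of records.
#' @export
readReport <- function(path, format = NULL) {
    if (is.null(format))
        format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
                  else "csv"
    if (format == "csv")
        utils::read.csv(path, stringsAsFactors = FALSE)
    else
        as.data.frame(jsonlite::fromJSON(path))
}

#' The twelve canonical abdominal organs-at-risk
#'
#' Organ names used throughout: aorta, large bowel, small bowel, duodenum,
#' esophagus, left/right kidney, liver, pancreas, spinal cord, spleen,
#' stomach.
#'
#' @return Character vector of length 12.
#' @export
canonicalOrgans <- function() {
    c("aorta", "large_bowel", "small_bowel", "duodenum", "esophagus",
      "kidney_l", "kidney_r", "liver", "pancreas", "spinal_cord",
      "spleen", "stomach")
}
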
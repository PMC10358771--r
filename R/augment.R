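# Training-time augmentation transforms applied consistently to image and
# label volumes: stochastic gamma intensity transformation and smooth 3D
# elastic deformation driven by a cubic-B-spline displacement field.

#' Augmentation configuration
#'
#' @param gamma_p Probability of applying the gamma transform per call
#'   (default 0.3).
#' @param gamma_range Range of the uniform gamma exponent, default
#'   \code{c(0.7, 1.3)}.
#' @param elastic_grid_spacing_mm Control-grid spacing of the elastic
#'   displacement field (default 50 mm — coarse relative to organ size, so
#'   deformations stay smooth).
#' @param elastic_max_disp_mm Maximum displacement amplitude per axis
#'   (default 4 mm, a "minor" deformation relative to abdominal organs).
#' @param seed Default seed used when a call does not pass one.
#' @return A list of class \code{AugmentConfig}.
#' @export
augmentConfig <- function(gamma_p = 0.3, gamma_range = c(0.7, 1.3),
                          elastic_grid_spacing_mm = 50,
                          elastic_max_disp_mm = 4, seed = NULL) {
    stopifnot(gamma_p >= 0, gamma_p <= 1, length(gamma_range) == 2,
              gamma_range[1] > 0, gamma_range[1] <= gamma_range[2],
              elastic_grid_spacing_mm > 0, elastic_max_disp_mm >= 0)
    structure(list(gamma_p = gamma_p, gamma_range = gamma_range,
                   elastic_grid_spacing_mm = elastic_grid_spacing_mm,
                   elastic_max_disp_mm = elastic_max_disp_mm, seed = seed),
              class = "AugmentConfig")
}

#' Stochastic gamma intensity transform
#'
#' With probability \code{gamma_p}: intensities are mapped to [0, 1] via
#' \eqn{(v - min)/(max - min)}, raised to a power \eqn{\gamma \sim
#' U(lo, hi)}, and mapped back to the original range — well-defined for
#' Z-scored (negative-valued) input and preserving both the intensity
#' extremes and the rank order. Otherwise the input is returned unchanged.
#' Constant volumes are a documented no-op.
#'
#' @param vol An [ImageVolume-class].
#' @param config An [augmentConfig()].
#' @param seed Seed for this call (overrides \code{config$seed}); the same
#'   seed always reproduces the same decision and exponent.
#' @param gamma Optional fixed exponent: bypasses the random draw and the
#'   application probability (useful for testing; \code{gamma = 1} is an
#'   exact identity).
#' @return The transformed [ImageVolume-class];
#'   \code{metadata$gamma_applied} and \code{metadata$gamma} record what
#'   happened.
#' @export
gammaTransform <- function(vol, config = augmentConfig(),
                           seed = config$seed, gamma = NULL) {
    stopifnot(is(vol, "ImageVolume"))
    a <- vol@data
    lo <- min(a); hi <- max(a)
    if (hi == lo) {
        vol@metadata$gamma_applied <- FALSE
        return(vol)
    }
    if (is.null(gamma)) {
        draw <- .withSeed(seed, stats::runif(2))
        if (draw[1] >= config$gamma_p) {
            vol@metadata$gamma_applied <- FALSE
            return(vol)
        }
        gamma <- config$gamma_range[1] +
            draw[2] * (config$gamma_range[2] - config$gamma_range[1])
    }
    u <- (a - lo) / (hi - lo)
    out <- lo + (hi - lo) * u^gamma
    imageVolume(out, spacing = vol@spacing, origin = vol@origin,
                metadata = c(vol@metadata,
                             list(gamma_applied = TRUE, gamma = gamma)))
}

#' 3D elastic deformation of an image and its labels
#'
#' Draws independent per-axis displacements on a coarse control grid
#' (spacing \code{elastic_grid_spacing_mm}, uniform in
#' \code{[-elastic_max_disp_mm, elastic_max_disp_mm]}), interpolates them
#' to voxel resolution with cubic B-splines (whose partition of unity
#' bounds the field by the control amplitude), and warps the image (linear
#' interpolation, edge-clamped) and every mask (nearest-neighbour) with the
#' \emph{same} field. Geometry is unchanged; a zero amplitude returns the
#' inputs bitwise-identical; identical seeds reproduce identical outputs.
#'
#' @param vol An [ImageVolume-class].
#' @param structures A [StructureSet-class] sharing the volume's geometry
#'   (may be empty).
#' @param config An [augmentConfig()].
#' @param seed Seed for this call (overrides \code{config$seed}).
#' @return List with \code{volume} (warped image) and \code{structures}
#'   (warped masks).
#' @export
elasticDeform <- function(vol, structures = structureSet(list()),
                          config = augmentConfig(), seed = config$seed) {
    stopifnot(is(vol, "ImageVolume"), is(structures, "StructureSet"))
    for (org in organNames(structures))
        .checkSameGeometry(vol, structures[[org]],
                           sprintf("volume and mask '%s'", org))
    if (config$elastic_max_disp_mm == 0)
        return(list(volume = vol, structures = structures))
    d <- dim(vol@data)
    sp <- vol@spacing
    g <- pmax(config$elastic_grid_spacing_mm / sp, 1.5)
    Bx <- .bsplineBasis1d(d[1], g[1])
    By <- .bsplineBasis1d(d[2], g[2])
    Bz <- .bsplineBasis1d(d[3], g[3])
    nco <- c(ncol(Bx), ncol(By), ncol(Bz))
    coefs <- .withSeed(seed,
        lapply(1:3, function(ax)
            array(stats::runif(prod(nco), -config$elastic_max_disp_mm,
                               config$elastic_max_disp_mm), nco)))
    disp <- lapply(coefs, .tensorField3d, Bx = Bx, By = By, Bz = Bz)
    if (all(vapply(disp, function(x) all(x == 0), logical(1))))
        return(list(volume = vol, structures = structures))
    # backward mapping: sample input at x - d(x), in fractional voxel coords
    grid <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                        z = seq_len(d[3]))
    qx <- grid$x - as.vector(disp[[1]]) / sp[1]
    qy <- grid$y - as.vector(disp[[2]]) / sp[2]
    qz <- grid$z - as.vector(disp[[3]]) / sp[3]
    warped <- array(.interpTrilinear(vol@data, qx, qy, qz), d)
    outVol <- imageVolume(warped, spacing = sp, origin = vol@origin,
                          metadata = vol@metadata)
    outOrgans <- lapply(structures@organs, function(m)
        binaryMask(array(.interpNearest(m@data, qx, qy, qz), d),
                   spacing = sp, origin = m@origin, metadata = m@metadata))
    list(volume = outVol,
         structures = structureSet(outOrgans,
                                   metadata = structures@metadata))
}
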
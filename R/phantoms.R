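# Synthetic multi-organ abdominal phantoms: caricature organ shapes
# (ellipsoids, tubes, a C-loop) at realistic sizes and the study's voxel
# spacings, MRI-like intensities with a known smooth multiplicative bias
# field and additive noise, controlled mask perturbations, and a benchmark
# suite whose expected metric values are closed-form or derived from an
# independent brute-force oracle.

#' Phantom specification
#'
#' @param grid_shape Grid extents (voxels), default \code{c(96, 96, 40)}.
#' @param spacing Voxel spacing in mm; default the T1-like
#'   \code{c(1.640625, 1.640625, 3)}; a T2-like alternative is
#'   \code{c(1.1875, 1.1875, 3)}.
#' @param organs Named list of organ recipes (see
#'   [defaultOrganRecipes()]).
#' @param bias_amplitude Relative amplitude of the multiplicative bias
#'   field, in [0, 0.5] (field spans \code{1 +/- amplitude}); default 0.3.
#' @param bias_smoothness_mm Correlation length of the bias field
#'   (default 80 mm — bias is a low-frequency artefact).
#' @param noise_sd SD of additive Gaussian noise (intensity units).
#' @param allow_overlap If \code{FALSE} (default), overlapping organ
#'   recipes are an error.
#' @param seed Seed making volume and field reproducible.
#' @return A list of class \code{PhantomSpec}.
#' @export
phantomSpec <- function(grid_shape = c(96, 96, 40),
                        spacing = c(1.640625, 1.640625, 3),
                        organs = defaultOrganRecipes(),
                        bias_amplitude = 0.3, bias_smoothness_mm = 80,
                        noise_sd = 5, allow_overlap = FALSE, seed = NULL) {
    stopifnot(length(grid_shape) == 3, all(grid_shape >= 4),
              all(spacing > 0), bias_amplitude >= 0, bias_amplitude <= 0.5,
              bias_smoothness_mm > 0, noise_sd >= 0)
    structure(list(grid_shape = as.integer(grid_shape),
                   spacing = as.numeric(spacing), organs = organs,
                   bias_amplitude = bias_amplitude,
                   bias_smoothness_mm = bias_smoothness_mm,
                   noise_sd = noise_sd, allow_overlap = allow_overlap,
                   seed = seed),
              class = "PhantomSpec")
}

#' Default 12-organ abdominal recipe set
#'
#' Caricatures of the twelve abdominal organs-at-risk: ellipsoids (liver,
#' spleen, stomach, kidneys, pancreas, small bowel), straight tubes
#' (aorta, spinal cord, esophagus, large bowel), and a C-loop tube
#' (duodenum), sized so organ volumes span about two orders of magnitude
#' (esophagus a few cc, liver over 100 cc) — the volume spread that drives
#' metric differences between organs. Positions are in mm within the
#' default ~157 x 157 x 120 mm field of view.
#'
#' @return Named list of organ recipes.
#' @export
defaultOrganRecipes <- function() {
    list(
        liver = list(shape = "ellipsoid", center_mm = c(45, 55, 62),
                     semiaxes_mm = c(33, 27, 27), intensity_mean = 300),
        spleen = list(shape = "ellipsoid", center_mm = c(126, 62, 75),
                      semiaxes_mm = c(14, 12, 14), intensity_mean = 280),
        stomach = list(shape = "ellipsoid", center_mm = c(98, 42, 82),
                       semiaxes_mm = c(18, 13, 15), intensity_mean = 150),
        kidney_l = list(shape = "ellipsoid", center_mm = c(120, 106, 42),
                        semiaxes_mm = c(12, 10, 15), intensity_mean = 260),
        kidney_r = list(shape = "ellipsoid", center_mm = c(38, 106, 42),
                        semiaxes_mm = c(12, 10, 15), intensity_mean = 260),
        pancreas = list(shape = "ellipsoid", center_mm = c(88, 82, 55),
                        semiaxes_mm = c(26, 8, 7), intensity_mean = 220),
        small_bowel = list(shape = "ellipsoid", center_mm = c(75, 46, 22),
                           semiaxes_mm = c(20, 11, 10), intensity_mean = 170),
        aorta = list(shape = "tube", axis = "z", center_mm = c(79, 100, 58),
                     radius_mm = 7, length_mm = 104, intensity_mean = 350),
        spinal_cord = list(shape = "tube", axis = "z",
                           center_mm = c(79, 132, 58), radius_mm = 5,
                           length_mm = 104, intensity_mean = 200),
        esophagus = list(shape = "tube", axis = "z",
                         center_mm = c(79, 76, 98), radius_mm = 4,
                         length_mm = 34, intensity_mean = 180),
        large_bowel = list(shape = "tube", axis = "x",
                           center_mm = c(79, 30, 104), radius_mm = 8,
                           length_mm = 116, intensity_mean = 140),
        duodenum = list(shape = "c_loop", center_mm = c(62, 82, 32),
                        major_radius_mm = 16, tube_radius_mm = 6,
                        arc_deg = 270, start_deg = 90,
                        intensity_mean = 160)
    )
}

.recipeMask <- function(recipe, dims, sp) {
    xs <- (seq_len(dims[1]) - 1) * sp[1]
    ys <- (seq_len(dims[2]) - 1) * sp[2]
    zs <- (seq_len(dims[3]) - 1) * sp[3]
    cm <- recipe$center_mm
    if (recipe$shape == "ellipsoid") {
        se <- recipe$semiaxes_mm
        ex <- ((xs - cm[1]) / se[1])^2
        ey <- ((ys - cm[2]) / se[2])^2
        ez <- ((zs - cm[3]) / se[3])^2
        return(outer(outer(ex, ey, `+`), ez, `+`) <= 1)
    }
    if (recipe$shape == "tube") {
        r2 <- recipe$radius_mm^2
        half <- recipe$length_mm / 2
        if (recipe$axis == "z") {
            inpl <- outer((xs - cm[1])^2, (ys - cm[2])^2, `+`) <= r2
            along <- abs(zs - cm[3]) <= half
            return(outer(inpl, along, `&`))
        }
        if (recipe$axis == "x") {
            inpl <- outer((ys - cm[2])^2, (zs - cm[3])^2, `+`) <= r2
            along <- abs(xs - cm[1]) <= half
            out <- outer(along, inpl, `&`)
            return(out)
        }
        # axis == "y"
        inpl <- outer((xs - cm[1])^2, (zs - cm[3])^2, `+`) <= r2
        along <- abs(ys - cm[2]) <= half
        return(aperm(outer(inpl, along, `&`), c(1, 3, 2)))
    }
    if (recipe$shape == "c_loop") {
        DX <- outer(xs - cm[1], rep(1, dims[2]))
        DY <- outer(rep(1, dims[1]), ys - cm[2])
        rad <- sqrt(DX^2 + DY^2)
        ang <- atan2(DY, DX) * 180 / pi
        a0 <- recipe$start_deg %% 360
        rel <- (ang - a0) %% 360
        angOK <- rel <= recipe$arc_deg
        ring <- (rad - recipe$major_radius_mm)^2
        m3 <- outer(ring, (zs - cm[3])^2, `+`) <= recipe$tube_radius_mm^2
        return(m3 & array(angOK, c(dims[1], dims[2], dims[3])))
    }
    stop(sprintf("unknown organ shape '%s'", recipe$shape))
}

#' Generate a phantom volume, structure set, and ground truth
#'
#' Builds the clean organ masks from the recipes, the noiseless intensity
#' volume (sum of organ indicators times their intensity means), the
#' smooth multiplicative bias field (\code{1 + amplitude * f} with
#' \code{f} a unit-normalised smooth random field), and the observed
#' volume = noiseless x bias + Gaussian noise. The generating field and
#' the noiseless volume are returned for oracle use.
#'
#' @param spec A [phantomSpec()].
#' @return List with \code{volume} ([ImageVolume-class]),
#'   \code{structures} ([StructureSet-class]), \code{bias_field} (array),
#'   \code{noiseless} (array), and \code{spec}.
#' @export
makePhantom <- function(spec = phantomSpec()) {
    stopifnot(inherits(spec, "PhantomSpec"))
    dims <- spec$grid_shape
    sp <- spec$spacing
    masks <- lapply(spec$organs, .recipeMask, dims = dims, sp = sp)
    for (nm in names(masks)) {
        m <- masks[[nm]]
        if (!any(m)) stop(sprintf("organ '%s' produced an empty mask", nm))
        if (any(m[c(1, dims[1]), , ]) || any(m[, c(1, dims[2]), ]) ||
            any(m[, , c(1, dims[3])]))
            stop(sprintf("organ '%s' reaches the grid boundary: recipe out of bounds",
                         nm))
    }
    if (!spec$allow_overlap && length(masks) > 1) {
        counts <- Reduce(`+`, lapply(masks, function(m) m * 1L))
        if (any(counts > 1L)) {
            ov <- names(masks)[vapply(masks, function(m)
                any(m & (counts > 1L)), logical(1))]
            stop(sprintf("overlapping organ recipes (%s); set allow_overlap",
                         paste(ov, collapse = ", ")))
        }
    }
    noiseless <- array(0, dims)
    for (nm in names(masks))
        noiseless[masks[[nm]]] <- spec$organs[[nm]]$intensity_mean
    .withSeed(spec$seed, {
        bias <- if (spec$bias_amplitude > 0)
            1 + spec$bias_amplitude *
                .smoothRandomField(dims, sp, spec$bias_smoothness_mm)
        else array(1, dims)
        obs <- noiseless * bias
        if (spec$noise_sd > 0)
            obs <- obs + stats::rnorm(length(obs), sd = spec$noise_sd)
    })
    organs <- lapply(masks, binaryMask, spacing = sp)
    list(volume = imageVolume(obs, spacing = sp),
         structures = structureSet(organs),
         bias_field = bias, noiseless = noiseless, spec = spec)
}

#' Perturb a mask with a controlled operator
#'
#' Provides ground-truth "auto" contours for metric testing. Operators:
#' \describe{
#'   \item{translate_mm}{Shift by whole voxels nearest to
#'     \code{magnitude / spacing} per axis (scalar magnitude = x only);
#'     the realised shift in mm is reported in the metadata so expected
#'     distances stay exact.}
#'   \item{dilate_voxels / erode_voxels}{6-connected structuring element
#'     applied \code{magnitude} times; voxels outside the grid count as
#'     background.}
#'   \item{drop_slices}{Empties the \code{magnitude} topmost axial slices
#'     that contain the structure.}
#'   \item{boundary_jitter}{Toggles each boundary voxel (either side of
#'     the interface) independently with probability \code{magnitude}.}
#' }
#' A perturbation that empties the mask is flagged
#' (\code{metadata$emptied}), not an error.
#'
#' @param mask A [BinaryMask-class].
#' @param op One of the operator names above.
#' @param magnitude Operator magnitude (mm, iterations, slices, or
#'   probability).
#' @param seed Seed (used by \code{boundary_jitter}).
#' @return The perturbed [BinaryMask-class].
#' @export
perturbMask <- function(mask, op = c("translate_mm", "dilate_voxels",
                                     "erode_voxels", "drop_slices",
                                     "boundary_jitter"),
                        magnitude, seed = NULL) {
    stopifnot(is(mask, "BinaryMask"))
    op <- match.arg(op)
    m <- mask@data
    sp <- mask@spacing
    md <- mask@metadata
    if (op == "translate_mm") {
        mag <- if (length(magnitude) == 1) c(magnitude, 0, 0)
               else as.numeric(magnitude)
        vox <- as.integer(round(mag / sp))
        m <- .shiftArray(m, vox, fill = FALSE)
        md$realized_shift_mm <- vox * sp
    } else if (op %in% c("dilate_voxels", "erode_voxels")) {
        k <- as.integer(magnitude)
        for (i in seq_len(k))
            m <- if (op == "dilate_voxels") .dilate6(m) else .erode6(m)
    } else if (op == "drop_slices") {
        k <- as.integer(magnitude)
        present <- which(apply(m, 3, any))
        drop <- utils::tail(present, k)
        m[, , drop] <- FALSE
        md$dropped_slices <- drop
    } else if (op == "boundary_jitter") {
        stopifnot(magnitude >= 0, magnitude <= 1)
        boundary <- (m & !.erode6(m)) | (!m & .dilate6(m))
        idx <- which(boundary)
        flip <- .withSeed(seed,
                          idx[stats::runif(length(idx)) < magnitude])
        m[flip] <- !m[flip]
    }
    if (!any(m)) md$emptied <- TRUE
    binaryMask(m, spacing = sp, origin = mask@origin, metadata = md)
}

.dilate6 <- function(m) {
    out <- m
    for (ax in 1:3) for (s in c(-1L, 1L)) {
        sh <- c(0L, 0L, 0L); sh[ax] <- s
        out <- out | .shiftArray(m, sh, fill = FALSE)
    }
    out
}

.erode6 <- function(m) !.dilate6(!m)

## ---- independent brute-force oracle (used only to derive expected
## ---- benchmark values; deliberately avoids the EDT code path) ---------

.bfFaces <- function(m, sp) {
    idx <- which(m, arr.ind = TRUE)
    d <- dim(m)
    pts <- NULL; ar <- NULL
    areas <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
    for (r in seq_len(nrow(idx))) {
        v <- idx[r, ]
        for (ax in 1:3) for (s in c(-1L, 1L)) {
            nb <- v; nb[ax] <- nb[ax] + s
            outside <- nb[ax] < 1 || nb[ax] > d[ax]
            if (outside || !m[nb[1], nb[2], nb[3]]) {
                p <- (v - 1) * sp
                p[ax] <- p[ax] + s * sp[ax] / 2
                pts <- rbind(pts, p)
                ar <- c(ar, areas[ax])
            }
        }
    }
    list(points = pts, areas = ar)
}

.bfNN <- function(P, Q) {
    apply(P, 1, function(p)
        sqrt(min(colSums((t(Q) - p)^2))))
}

.bfWQuant <- function(x, w, p) {
    o <- order(x); x <- x[o]; cw <- cumsum(w[o])
    x[which(cw >= p * cw[length(cw)] - 1e-12)[1]]
}

.bfSurfaceMetrics <- function(autoM, refM, tol = 2, pct = 0.95) {
    sp <- refM@spacing
    fa <- .bfFaces(autoM@data, sp)
    fr <- .bfFaces(refM@data, sp)
    dab <- .bfNN(fa$points, fr$points)
    dba <- .bfNN(fr$points, fa$points)
    list(
        mda = sum(c(dab * fa$areas, dba * fr$areas)) /
              sum(fa$areas, fr$areas),
        hd = max(.bfWQuant(dab, fa$areas, pct), .bfWQuant(dba, fr$areas, pct)),
        sdsc = (sum(fa$areas[dab <= tol]) + sum(fr$areas[dba <= tol])) /
               (sum(fa$areas) + sum(fr$areas)),
        apl = .bfAPL(autoM, refM, tol))
}

.bfAPL <- function(autoM, refM, tol = 2) {
    sp <- refM@spacing
    d <- dim(refM@data)
    tot <- 0
    for (k in seq_len(d[3])) {
        r2 <- refM@data[, , k]; dim(r2) <- d[1:2]
        if (!any(r2)) next
        re <- .bfEdges2d(r2, sp)
        a2 <- autoM@data[, , k]; dim(a2) <- d[1:2]
        if (!any(a2)) { tot <- tot + sum(re$lengths); next }
        ae <- .bfEdges2d(a2, sp)
        dd <- apply(re$points, 1, function(p)
            sqrt(min(colSums((t(ae$points) - p)^2))))
        tot <- tot + sum(re$lengths[dd > tol])
    }
    tot
}

.bfEdges2d <- function(m2, sp) {
    idx <- which(m2, arr.ind = TRUE)
    d <- dim(m2)
    pts <- NULL; len <- NULL
    lens <- c(sp[2], sp[1])
    for (r in seq_len(nrow(idx))) {
        v <- idx[r, ]
        for (ax in 1:2) for (s in c(-1L, 1L)) {
            nb <- v; nb[ax] <- nb[ax] + s
            outside <- nb[ax] < 1 || nb[ax] > d[ax]
            if (outside || !m2[nb[1], nb[2]]) {
                p <- (v - 1) * sp[1:2]
                p[ax] <- p[ax] + s * sp[ax] / 2
                pts <- rbind(pts, p)
                len <- c(len, lens[ax])
            }
        }
    }
    list(points = pts, lengths = len)
}

.cubeMask <- function(dims, lo, size, sp) {
    m <- array(FALSE, dims)
    m[lo[1]:(lo[1] + size[1] - 1), lo[2]:(lo[2] + size[2] - 1),
      lo[3]:(lo[3] + size[3] - 1)] <- TRUE
    binaryMask(m, spacing = sp)
}

#' Build the metric benchmark suite
#'
#' A fixed ensemble of (reference, auto) mask pairs spanning identical
#' pairs, sub- and supra-tolerance translations, erosions, dilations,
#' missing structures, dropped slices, and boundary jitter — each with
#' expected metric values that are either closed-form (\code{"analytic"})
#' or derived from an all-pairs brute-force computation that shares no
#' code with the production distance transform (\code{"oracle"}).
#'
#' @param seed Seed for the stochastic families (jitter).
#' @return List of entries; each has \code{name}, \code{family},
#'   \code{magnitude}, \code{ref}, \code{auto} (single-organ
#'   [StructureSet-class]s), \code{expected} (named list of metric
#'   values), and \code{tags} (provenance \code{"analytic"}/\code{"oracle"}
#'   per expected value).
#' @export
makeBenchmarkSuite <- function(seed = 1) {
    sp1 <- c(1, 1, 1)
    dims <- c(20L, 20L, 16L)
    cube <- .cubeMask(dims, c(4, 4, 4), c(10, 10, 10), sp1)
    entries <- list()
    add <- function(name, family, magnitude, ref, auto, expected, tags) {
        entries[[length(entries) + 1L]] <<- list(
            name = name, family = family, magnitude = magnitude,
            ref = structureSet(list(organ = ref)),
            auto = structureSet(list(organ = auto)),
            expected = expected, tags = tags)
    }
    # identical pairs (3 shapes)
    sph <- local({
        xs <- 0:19; g <- outer(outer((xs - 9.5)^2, (xs - 9.5)^2, `+`),
                               ((0:15) - 7.5)^2 * 4, `+`)
        binaryMask(g <= 36, spacing = sp1)
    })
    slab <- .cubeMask(dims, c(3, 3, 5), c(14, 14, 4), sp1)
    for (p in list(list("identical_cube", cube), list("identical_sphere", sph),
                   list("identical_slab", slab)))
        add(p[[1]], "identical", 0, p[[2]], p[[2]],
            list(dsc = 1, mda = 0, hd = 0, pvd = 0, sdsc = 1, apl = 0),
            c(dsc = "analytic", mda = "analytic", hd = "analytic",
              pvd = "analytic", sdsc = "analytic", apl = "analytic"))
    # translations (1 mm and 2 mm sub-tolerance, 5 mm supra-tolerance)
    for (k in c(1L, 2L, 5L)) {
        auto <- perturbMask(cube, "translate_mm", k)
        expected <- list(dsc = 2 * (10 - k) * 100 / 2000, hd = k, pvd = 0)
        tags <- c(dsc = "analytic", hd = "analytic", pvd = "analytic")
        if (k <= 2) {
            expected$sdsc <- 1; expected$apl <- 0
            tags <- c(tags, sdsc = "analytic", apl = "analytic")
        } else {
            bf <- .bfSurfaceMetrics(auto, cube)
            expected$sdsc <- bf$sdsc; expected$apl <- bf$apl
            expected$mda <- bf$mda
            tags <- c(tags, sdsc = "oracle", apl = "oracle", mda = "oracle")
        }
        add(sprintf("translate_%dmm", k), "translate", k, cube, auto,
            expected, tags)
    }
    # erosions (cube shrinks to (10-2k)^3)
    for (k in 1:3) {
        auto <- perturbMask(cube, "erode_voxels", k)
        s <- 10 - 2 * k
        bf <- .bfSurfaceMetrics(auto, cube)
        add(sprintf("erode_%d", k), "erode", k, cube, auto,
            list(dsc = 2 * s^3 / (s^3 + 1000),
                 pvd = 100 * (s^3 - 1000) / 1000,
                 mda = bf$mda, hd = bf$hd, sdsc = bf$sdsc, apl = bf$apl),
            c(dsc = "analytic", pvd = "analytic", mda = "oracle",
              hd = "oracle", sdsc = "oracle", apl = "oracle"))
    }
    # dilations (6-connected: cube plus face slabs, no edges/corners)
    for (k in 1:3) {
        auto <- perturbMask(cube, "dilate_voxels", k)
        nv <- sum(auto@data)
        bf <- .bfSurfaceMetrics(auto, cube)
        add(sprintf("dilate_%d", k), "dilate", k, cube, auto,
            list(dsc = 2 * 1000 / (nv + 1000),
                 pvd = 100 * (nv - 1000) / 1000,
                 mda = bf$mda, hd = bf$hd, sdsc = bf$sdsc, apl = bf$apl),
            c(dsc = "analytic", pvd = "analytic", mda = "oracle",
              hd = "oracle", sdsc = "oracle", apl = "oracle"))
    }
    # missing structure: auto empty
    add("missing_organ", "missing", 1, cube,
        binaryMask(array(FALSE, dims), spacing = sp1),
        list(dsc = 0, pvd = -100, apl = 10 * 40),
        c(dsc = "analytic", pvd = "analytic", apl = "analytic"))
    # dropped slices: APL gains exactly the dropped per-slice perimeters
    for (k in 1:3) {
        auto <- perturbMask(cube, "drop_slices", k)
        add(sprintf("drop_slices_%d", k), "drop_slices", k, cube, auto,
            list(dsc = 2 * (10 - k) * 100 / ((10 - k) * 100 + 1000),
                 pvd = 100 * ((10 - k) * 100 - 1000) / 1000,
                 apl = k * 40),
            c(dsc = "analytic", pvd = "analytic", apl = "analytic"))
    }
    # boundary jitter at increasing rates (anisotropic spacing)
    spA <- c(1.1875, 1.1875, 3)
    cubeA <- .cubeMask(c(14L, 14L, 10L), c(4, 4, 4), c(7, 7, 4), spA)
    for (i in seq_along(c(0.1, 0.25, 0.5))) {
        pj <- c(0.1, 0.25, 0.5)[i]
        auto <- perturbMask(cubeA, "boundary_jitter", pj,
                            seed = seed + i)
        bf <- .bfSurfaceMetrics(auto, cubeA)
        na <- sum(auto@data); nr <- sum(cubeA@data)
        add(sprintf("jitter_%g", pj), "jitter", pj, cubeA, auto,
            list(dsc = 2 * sum(auto@data & cubeA@data) / (na + nr),
                 pvd = 100 * (na - nr) / nr,
                 mda = bf$mda, hd = bf$hd, sdsc = bf$sdsc, apl = bf$apl),
            c(dsc = "analytic", pvd = "analytic", mda = "oracle",
              hd = "oracle", sdsc = "oracle", apl = "oracle"))
    }
    entries
}
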
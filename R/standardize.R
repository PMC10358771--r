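# MRI intensity standardisation chain: multiplicative bias-field
# correction, edge-preserving (Perona-Malik) denoising, normalisation of
# the foreground median to 1, and percentile-windowed Z-score
# normalisation for model input.

#' Standardisation configuration
#'
#' @param pct_lo,pct_hi Percentile window (of all voxel intensities) used
#'   to compute the Z-score statistics; defaults 0.25 and 99.75 exclude the
#'   extreme 0.5\% of voxels so outliers do not inflate the moments.
#' @param diffusion_iters Number of explicit diffusion steps (default 5);
#'   0 is the identity.
#' @param diffusion_kappa Conduction threshold in intensity units;
#'   \code{NA} (default) sets it per volume to the 90th percentile of the
#'   gradient magnitude, separating noise gradients (diffused) from edge
#'   gradients (preserved).
#' @param diffusion_dt Explicit time step; \code{NA} (default) uses 80\% of
#'   the 3D stability bound \eqn{1 / (2 (dx^{-2}+dy^{-2}+dz^{-2}))} (with
#'   conductance \eqn{\le 1}). Values above the bound are an error.
#' @param diffusion_conductance \code{"rational"} (default,
#'   \eqn{1/(1+(g/\kappa)^2)}) or \code{"exponential"}
#'   (\eqn{\exp(-(g/\kappa)^2)}).
#' @param bias_fit_degree Per-axis degree of the log-domain tensor
#'   polynomial bias model (default 3).
#' @param fg_pct Foreground threshold percentile on nonzero voxels used by
#'   the median normalisation and bias fit (default 5).
#' @return A list of class \code{NormalizationConfig}.
#' @export
normalizationConfig <- function(pct_lo = 0.25, pct_hi = 99.75,
                                diffusion_iters = 5, diffusion_kappa = NA,
                                diffusion_dt = NA,
                                diffusion_conductance = c("rational",
                                                          "exponential"),
                                bias_fit_degree = 3, fg_pct = 5) {
    stopifnot(pct_lo >= 0, pct_lo < pct_hi, pct_hi <= 100,
              diffusion_iters >= 0, bias_fit_degree >= 1)
    structure(list(pct_lo = pct_lo, pct_hi = pct_hi,
                   diffusion_iters = as.integer(diffusion_iters),
                   diffusion_kappa = diffusion_kappa,
                   diffusion_dt = diffusion_dt,
                   diffusion_conductance = match.arg(diffusion_conductance),
                   bias_fit_degree = as.integer(bias_fit_degree),
                   fg_pct = fg_pct),
              class = "NormalizationConfig")
}

.polyBasis1d <- function(n, degree) {
    x <- if (n > 1) seq(-1, 1, length.out = n) else 0
    outer(x, 0:degree, `^`)
}

# Build the gradient-matching least-squares system for the bias fit:
# rows are (polynomial basis at voxel q) - (basis at voxel p) for adjacent
# foreground voxel pairs (p, q); responses are the log-intensity
# differences, robustly trimmed (organ/tissue boundaries are sparse large
# spikes, bias gradients are small and dense). Deterministically
# subsampled to bound the system size.
.logGradientEquations <- function(u, fg, Bx, By, Bz, maxRows = 120000L) {
    d <- dim(u)
    P1 <- NULL; P2 <- NULL; y <- NULL
    for (ax in 1:3) {
        if (d[ax] < 2) next
        sh <- c(0L, 0L, 0L); sh[ax] <- -1L
        nxtFg <- .shiftArray(fg, sh, fill = FALSE)
        nxtU <- .shiftArray(u, sh, fill = NA_real_)
        pair <- fg & nxtFg
        # exclude wrap at the far boundary
        idxEnd <- vector("list", 3)
        for (k in 1:3) idxEnd[[k]] <- seq_len(d[k])
        idxEnd[[ax]] <- d[ax]
        pair[idxEnd[[1]], idxEnd[[2]], idxEnd[[3]]] <- FALSE
        if (!any(pair)) next
        ijk <- which(pair, arr.ind = TRUE)
        ijk2 <- ijk; ijk2[, ax] <- ijk2[, ax] + 1L
        P1 <- rbind(P1, ijk)
        P2 <- rbind(P2, ijk2)
        y <- c(y, nxtU[pair] - u[pair])
    }
    if (is.null(y))
        return(list(X = matrix(0, 0, ncol(Bx) * ncol(By) * ncol(Bz)),
                    y = numeric(0)))
    s <- stats::mad(y)
    keep <- abs(y - stats::median(y)) <= max(4 * s, 1e-12)
    P1 <- P1[keep, , drop = FALSE]; P2 <- P2[keep, , drop = FALSE]
    y <- y[keep]
    if (length(y) > maxRows) {
        pick <- round(seq(1, length(y), length.out = maxRows))
        P1 <- P1[pick, , drop = FALSE]; P2 <- P2[pick, , drop = FALSE]
        y <- y[pick]
    }
    X <- .polyRows(P2, Bx, By, Bz) - .polyRows(P1, Bx, By, Bz)
    list(X = X, y = y)
}

.polyRows <- function(ijk, Bx, By, Bz) {
    ncf <- ncol(Bx) * ncol(By) * ncol(Bz)
    X <- matrix(0, nrow(ijk), ncf)
    col <- 1L
    for (cz in seq_len(ncol(Bz))) for (cy in seq_len(ncol(By)))
        for (cx in seq_len(ncol(Bx))) {
            X[, col] <- Bx[ijk[, 1], cx] * By[ijk[, 2], cy] *
                        Bz[ijk[, 3], cz]
            col <- col + 1L
        }
    X
}

#' Correct a multiplicative bias field
#'
#' Estimates the smooth, strictly positive multiplicative intensity
#' inhomogeneity of an MRI volume with a gradient-domain log-polynomial
#' fit. In the log domain the image is (tissue term) + (smooth bias term);
#' between neighbouring foreground voxels of the same tissue, the
#' log-intensity difference equals the bias difference, while tissue
#' boundaries show up as sparse large spikes. The fit therefore
#' least-squares-matches the differences of a low-degree tensor-product
#' polynomial to the robustly trimmed adjacent-voxel log differences
#' (spikes beyond a MAD-based cut are discarded), then integrates back to
#' a field with unit geometric mean over the foreground. The corrected
#' volume is rescaled so its mean equals the input mean exactly.
#'
#' @param vol An [ImageVolume-class]; negative intensities are shifted up
#'   before the log fit and shifted back afterwards (shift recorded in the
#'   output metadata).
#' @param config A [normalizationConfig()].
#' @return The corrected [ImageVolume-class]; \code{metadata$bias_field}
#'   holds the estimated field (array) and \code{metadata$intensity_shift}
#'   any applied shift.
#' @export
correctBiasField <- function(vol, config = normalizationConfig()) {
    stopifnot(is(vol, "ImageVolume"))
    a <- vol@data
    if (all(a == 0)) stop("cannot bias-correct an all-zero volume")
    d <- dim(a)
    deg <- config$bias_fit_degree
    if (any(d < 2L) || sum(a != 0) < (deg + 1)^3)
        return(vol)  # too small to support a smooth-field fit; no-op
    shift <- 0
    if (min(a) < 0) {
        shift <- -min(a)
        a <- a + shift
    }
    nz <- a > 0
    thr <- stats::quantile(a[nz], config$fg_pct / 100, names = FALSE)
    fg <- a > thr
    if (sum(fg) < (deg + 1)^3) fg <- nz
    Bx <- .polyBasis1d(d[1], deg); By <- .polyBasis1d(d[2], deg)
    Bz <- .polyBasis1d(d[3], deg)
    u <- array(NA_real_, d)
    u[fg] <- log(a[fg])
    eq <- .logGradientEquations(u, fg, Bx, By, Bz)
    coef <- rep(0, (deg + 1)^3)
    if (nrow(eq$X) >= length(coef)) {
        cf <- qr.coef(qr(eq$X), eq$y)
        cf[is.na(cf)] <- 0
        coef <- cf
    }
    coef <- array(coef, c(deg + 1, deg + 1, deg + 1))
    logField <- .tensorField3d(coef, Bx, By, Bz)
    logField <- logField - mean(logField[fg])  # unit (geometric) mean field
    field <- exp(logField)
    out <- a / field
    s <- mean(a) / mean(out)   # exact mean preservation
    out <- out * s
    field <- field / s
    out <- out - shift
    imageVolume(out, spacing = vol@spacing, origin = vol@origin,
                metadata = c(vol@metadata,
                             list(bias_field = field,
                                  intensity_shift = shift)))
}

#' Edge-preserving anisotropic diffusion denoising
#'
#' Perona-Malik diffusion in 3D with an explicit conservative
#' (flux-difference) scheme: smoothing is strong where the local gradient
#' magnitude is small relative to \eqn{\kappa} (noise) and suppressed
#' across strong edges. Zero-flux boundaries make the scheme conserve the
#' global mean exactly; \code{diffusion_iters = 0} returns the input
#' unchanged.
#'
#' @inheritParams correctBiasField
#' @return The denoised [ImageVolume-class].
#' @export
denoiseAnisotropic <- function(vol, config = normalizationConfig()) {
    stopifnot(is(vol, "ImageVolume"))
    iters <- config$diffusion_iters
    if (iters == 0) return(vol)
    a <- vol@data
    sp <- vol@spacing
    bound <- 1 / (2 * sum(1 / sp^2))
    dt <- config$diffusion_dt
    if (is.na(dt)) dt <- 0.8 * bound
    if (dt > bound)
        stop(sprintf(paste0("diffusion_dt = %.4g exceeds the 3D explicit ",
                            "stability bound %.4g for spacing (%g, %g, %g)"),
                     dt, bound, sp[1], sp[2], sp[3]))
    kappa <- config$diffusion_kappa
    if (is.na(kappa)) {
        gm <- .gradientMagnitude(a, sp)
        gm <- gm[gm > 0]
        if (!length(gm)) return(vol)  # constant volume: nothing to diffuse
        kappa <- stats::quantile(gm, 0.9, names = FALSE)
        if (!is.finite(kappa) || kappa == 0) return(vol)
    }
    cond <- if (config$diffusion_conductance == "rational")
        function(g) 1 / (1 + (g / kappa)^2)
    else
        function(g) exp(-(g / kappa)^2)
    d <- dim(a)
    for (it in seq_len(iters)) {
        upd <- array(0, d)
        for (ax in 1:3) {
            if (d[ax] < 2) next
            h <- sp[ax]
            fwd <- .diffForward(a, ax)          # (v[i+1]-v[i])/h at faces
            flux <- cond(abs(fwd / h)) * fwd / h
            upd <- upd + (flux - .shiftFace(flux, ax)) / h
        }
        a <- a + dt * upd
    }
    imageVolume(a, spacing = vol@spacing, origin = vol@origin,
                metadata = c(vol@metadata,
                             list(diffusion = list(iters = iters, dt = dt,
                                                   kappa = kappa))))
}

# Forward difference along axis `ax` (zero at the far boundary: zero flux).
.diffForward <- function(a, ax) {
    d <- dim(a)
    sh <- c(0L, 0L, 0L); sh[ax] <- -1L
    nxt <- .shiftArray(a, sh, fill = 0)
    out <- nxt - a
    idx <- vector("list", 3); for (k in 1:3) idx[[k]] <- seq_len(d[k])
    idx[[ax]] <- d[ax]
    out[idx[[1]], idx[[2]], idx[[3]]] <- 0
    out
}

# Shift face-flux array one step along `ax` (flux entering each voxel);
# zero at the near boundary.
.shiftFace <- function(flux, ax) {
    sh <- c(0L, 0L, 0L); sh[ax] <- 1L
    .shiftArray(flux, sh, fill = 0)
}

.gradientMagnitude <- function(a, sp) {
    g2 <- array(0, dim(a))
    for (ax in 1:3) {
        if (dim(a)[ax] < 2) next
        g2 <- g2 + (.diffForward(a, ax) / sp[ax])^2
    }
    sqrt(g2)
}

#' Normalise intensities to a foreground median of one
#'
#' Divides the volume by the median intensity of foreground voxels.
#' Foreground is defined scale-invariantly as the voxels above the larger
#' of (a) the \code{fg_pct}-th intensity percentile of the nonzero voxels
#' and (b) 5\% of the 99.5th-percentile intensity — (a) excludes an
#' exactly-zero air background, (b) excludes low-level background noise on
#' volumes whose air region is noisy rather than zero. The operation is
#' invariant to positive global scaling and preserves the rank order of
#' intensities; the applied threshold and divisor are recorded in the
#' output metadata.
#'
#' @inheritParams correctBiasField
#' @return The rescaled [ImageVolume-class] (foreground median = 1).
#' @export
normalizeToMedian <- function(vol, config = normalizationConfig()) {
    stopifnot(is(vol, "ImageVolume"))
    a <- vol@data
    if (length(unique(as.vector(a))) < 2)
        stop("normalizeToMedian requires more than one distinct intensity")
    nz <- a != 0
    if (!any(nz)) stop("no nonzero voxels: foreground is empty")
    thr <- max(stats::quantile(a[nz], config$fg_pct / 100, names = FALSE),
               0.05 * stats::quantile(a, 0.995, names = FALSE))
    fg <- a > thr
    if (!any(fg)) stop("foreground is empty after thresholding")
    med <- stats::median(a[fg])
    if (med <= 0) stop("foreground median is not positive")
    imageVolume(a / med, spacing = vol@spacing, origin = vol@origin,
                metadata = c(vol@metadata,
                             list(median_divisor = med,
                                  fg_threshold = thr)))
}

#' Percentile-windowed Z-score normalisation
#'
#' Computes the mean and standard deviation of the voxels whose intensity
#' lies within the closed \code{[pct_lo, pct_hi]} intensity-percentile
#' window and applies \eqn{(v - \mu_w) / \sigma_w} to \emph{all} voxels.
#' Values outside the window are transformed but never clipped; the window
#' only keeps outlier voxels out of the statistics.
#'
#' @inheritParams correctBiasField
#' @param stats_from Optional list of [ImageVolume-class] objects (e.g.
#'   all acquisitions of one patient): the window and moments are then
#'   computed from their pooled voxels instead of from \code{vol} alone,
#'   giving one consistent normalisation across acquisitions.
#' @return The normalised [ImageVolume-class]; in-window voxels of the
#'   output have mean 0 and SD 1 (per-volume mode).
#' @export
zscorePercentile <- function(vol, config = normalizationConfig(),
                             stats_from = NULL) {
    stopifnot(is(vol, "ImageVolume"))
    a <- vol@data
    pool <- if (is.null(stats_from)) as.vector(a)
            else unlist(lapply(stats_from, function(v) {
                stopifnot(is(v, "ImageVolume"))
                as.vector(v@data)
            }))
    qb <- stats::quantile(pool, c(config$pct_lo, config$pct_hi) / 100,
                          names = FALSE)
    win <- pool >= qb[1] & pool <= qb[2]
    mu <- mean(pool[win])
    sg <- stats::sd(pool[win])
    if (!is.finite(sg) || sg == 0)
        stop("in-window standard deviation is zero (constant volume?)")
    imageVolume((a - mu) / sg, spacing = vol@spacing, origin = vol@origin,
                metadata = c(vol@metadata,
                             list(zscore = list(mu = mu, sigma = sg,
                                                window = qb))))
}

#' Full standardisation pipeline
#'
#' Applies, in order, bias-field correction, anisotropic-diffusion
#' denoising, and median normalisation, and records the parameters of each
#' stage as a provenance list in the result's metadata. (The Z-score step
#' is a separate, model-input transform: apply [zscorePercentile()]
#' afterwards when preparing training input.)
#'
#' @inheritParams correctBiasField
#' @return The standardised [ImageVolume-class] with
#'   \code{metadata$provenance}.
#' @export
standardizePipeline <- function(vol, config = normalizationConfig()) {
    out <- correctBiasField(vol, config)
    out <- denoiseAnisotropic(out, config)
    out <- normalizeToMedian(out, config)
    out@metadata$provenance <- list(
        stages = c("correctBiasField", "denoiseAnisotropic",
                   "normalizeToMedian"),
        config = unclass(config))
    out
}
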
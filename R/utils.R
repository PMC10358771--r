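# Internal helpers shared across modules.

# Fail before computing anything if two objects do not live on the same grid.
.checkSameGeometry <- function(a, b, what = "objects") {
    if (!identical(dim(a@data), dim(b@data)))
        stop(sprintf("%s have different grid shapes (%s vs %s)", what,
                     paste(dim(a@data), collapse = "x"),
                     paste(dim(b@data), collapse = "x")))
    if (!isTRUE(all.equal(a@spacing, b@spacing, tolerance = 1e-9)))
        stop(sprintf("%s have different voxel spacing", what))
    invisible(TRUE)
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards. Every stochastic operation routes through this
# so that (input, seed) fully determines the output.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(eval.parent(substitute(expr)))
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
        stop("seed must be a single finite number")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    eval.parent(substitute(expr))
}

# Weighted quantile, inverse-CDF convention: the smallest x whose cumulative
# weight reaches p * total weight. With unit weights this is type-1.
.weightedQuantile <- function(x, w, p) {
    stopifnot(length(x) == length(w), length(x) > 0, p >= 0, p <= 1)
    o <- order(x)
    x <- x[o]
    cw <- cumsum(w[o])
    x[which(cw >= p * cw[length(cw)] - 1e-12)[1]]
}

# Shift a 3D array by integer voxel offsets, padding with `fill`.
.shiftArray <- function(a, by, fill = FALSE) {
    d <- dim(a)
    out <- array(fill, d)
    src <- dst <- vector("list", 3)
    for (k in 1:3) {
        b <- by[k]
        if (abs(b) >= d[k]) return(out)
        if (b >= 0) { src[[k]] <- seq_len(d[k] - b); dst[[k]] <- src[[k]] + b }
        else       { src[[k]] <- seq_len(d[k] + b) - b; dst[[k]] <- seq_len(d[k] + b) }
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
}

# Cubic B-spline kernel (support [-2, 2], partition of unity).
.bspline3 <- function(u) {
    au <- abs(u)
    ifelse(au < 1, (4 - 6 * au^2 + 3 * au^3) / 6,
           ifelse(au < 2, (2 - au)^3 / 6, 0))
}

# Basis matrix mapping control-point coefficients (spacing `g` in voxel
# units, first control point at voxel coordinate -g) to the n voxel centres
# (voxel coordinates 0 .. n-1). Columns sum to 1 at every row.
.bsplineBasis1d <- function(n, g) {
    nctrl <- as.integer(ceiling((n - 1) / g)) + 4L
    x <- (seq_len(n) - 1) / g          # in control-grid units
    B <- matrix(0, n, nctrl)
    for (j in seq_len(nctrl)) {
        cj <- j - 2                      # control point position, grid units
        B[, j] <- .bspline3(x - cj)
    }
    B
}

# Contract a 3D coefficient array with per-axis basis matrices:
# field[i,j,k] = sum_abc Bx[i,a] By[j,b] Bz[k,c] coef[a,b,c]
.tensorField3d <- function(coef, Bx, By, Bz) {
    d <- dim(coef)
    t1 <- Bx %*% matrix(coef, d[1])                       # (nx, d2*d3)
    t1 <- array(t1, c(nrow(Bx), d[2], d[3]))
    t2 <- apply(t1, c(1, 3), function(v) By %*% v)        # (ny, nx, d3)
    t2 <- aperm(t2, c(2, 1, 3))
    t3 <- apply(t2, c(1, 2), function(v) Bz %*% v)        # (nz, nx, ny)
    aperm(t3, c(2, 3, 1))
}

# Smooth random field on a voxel grid: N(0,1) coefficients on a coarse
# control grid (spacing smooth_mm), cubic-B-spline interpolated, then scaled
# to max |field| = 1. Deterministic given the current RNG state.
.smoothRandomField <- function(dims, spacing, smooth_mm) {
    g <- pmax(smooth_mm / spacing, 1.5)  # control spacing in voxel units
    Bx <- .bsplineBasis1d(dims[1], g[1])
    By <- .bsplineBasis1d(dims[2], g[2])
    Bz <- .bsplineBasis1d(dims[3], g[3])
    coef <- array(stats::rnorm(ncol(Bx) * ncol(By) * ncol(Bz)),
                  c(ncol(Bx), ncol(By), ncol(Bz)))
    f <- .tensorField3d(coef, Bx, By, Bz)
    m <- max(abs(f))
    if (m == 0) f else f / m
}

# Trilinear interpolation of a 3D array at fractional voxel coordinates
# (1-based), edge-clamped. qx/qy/qz are equal-length vectors.
.interpTrilinear <- function(a, qx, qy, qz) {
    d <- dim(a)
    qx <- pmin(pmax(qx, 1), d[1]); qy <- pmin(pmax(qy, 1), d[2])
    qz <- pmin(pmax(qz, 1), d[3])
    x0 <- pmin(floor(qx), d[1] - 1L); x0 <- pmax(x0, 1L)
    y0 <- pmin(floor(qy), d[2] - 1L); y0 <- pmax(y0, 1L)
    z0 <- pmin(floor(qz), d[3] - 1L); z0 <- pmax(z0, 1L)
    if (d[1] == 1L) x0 <- rep(1L, length(qx))
    if (d[2] == 1L) y0 <- rep(1L, length(qy))
    if (d[3] == 1L) z0 <- rep(1L, length(qz))
    fx <- qx - x0; fy <- qy - y0; fz <- qz - z0
    x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
    idx <- function(i, j, k) ((k - 1) * d[2] + (j - 1)) * d[1] + i
    a <- as.vector(a)
    a[idx(x0, y0, z0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    a[idx(x1, y0, z0)] * fx       * (1 - fy) * (1 - fz) +
    a[idx(x0, y1, z0)] * (1 - fx) * fy       * (1 - fz) +
    a[idx(x1, y1, z0)] * fx       * fy       * (1 - fz) +
    a[idx(x0, y0, z1)] * (1 - fx) * (1 - fy) * fz +
    a[idx(x1, y0, z1)] * fx       * (1 - fy) * fz +
    a[idx(x0, y1, z1)] * (1 - fx) * fy       * fz +
    a[idx(x1, y1, z1)] * fx       * fy       * fz
}

# Nearest-neighbour sampling at fractional voxel coordinates, edge-clamped.
.interpNearest <- function(a, qx, qy, qz) {
    d <- dim(a)
    i <- pmin(pmax(round(qx), 1), d[1])
    j <- pmin(pmax(round(qy), 1), d[2])
    k <- pmin(pmax(round(qz), 1), d[3])
    a[((k - 1) * d[2] + (j - 1)) * d[1] + i]
}
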
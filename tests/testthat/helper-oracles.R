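# Independent brute-force oracles for the surface metrics, written as
# plain enumerations over voxels (no shared code with the package's
# distance-transform implementation). Only usable on small masks.

# Enumerate exposed voxel faces by checking each inside voxel's six
# neighbours directly.
oracleFaces <- function(m, sp) {
    idx <- which(m, arr.ind = TRUE)
    d <- dim(m)
    areas <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
    pts <- list(); ar <- list()
    for (r in seq_len(nrow(idx))) {
        v <- idx[r, ]
        for (ax in 1:3) for (s in c(-1L, 1L)) {
            nb <- v; nb[ax] <- nb[ax] + s
            if (nb[ax] < 1 || nb[ax] > d[ax] ||
                !m[nb[1], nb[2], nb[3]]) {
                p <- (v - 1) * sp
                p[ax] <- p[ax] + s * sp[ax] / 2
                pts[[length(pts) + 1L]] <- p
                ar[[length(ar) + 1L]] <- areas[ax]
            }
        }
    }
    list(points = do.call(rbind, pts), areas = unlist(ar))
}

# All-pairs nearest distance from each row of P to the rows of Q.
oracleNN <- function(P, Q) {
    apply(P, 1, function(p) sqrt(min(colSums((t(Q) - p)^2))))
}

# Weighted quantile, inverse-CDF convention (smallest x reaching p of the
# total weight).
oracleWQ <- function(x, w, p) {
    o <- order(x); x <- x[o]; cw <- cumsum(w[o])
    x[which(cw >= p * cw[length(cw)] - 1e-12)[1]]
}

# The four surface metrics from all-pairs distances.
oracleSurfaceMetrics <- function(autoArr, refArr, sp, tol = 2, pct = 0.95) {
    fa <- oracleFaces(autoArr, sp)
    fr <- oracleFaces(refArr, sp)
    dab <- oracleNN(fa$points, fr$points)
    dba <- oracleNN(fr$points, fa$points)
    list(mda = (sum(dab * fa$areas) + sum(dba * fr$areas)) /
               (sum(fa$areas) + sum(fr$areas)),
         hd = max(oracleWQ(dab, fa$areas, pct), oracleWQ(dba, fr$areas, pct)),
         hdmax = max(dab, dba),
         sdsc = (sum(fa$areas[dab <= tol]) + sum(fr$areas[dba <= tol])) /
                (sum(fa$areas) + sum(fr$areas)),
         apl = oracleAPL(autoArr, refArr, sp, tol))
}

# Slice-wise added path length by direct per-slice edge enumeration.
oracleAPL <- function(autoArr, refArr, sp, tol = 2) {
    d <- dim(refArr)
    total <- 0
    for (k in seq_len(d[3])) {
        r2 <- refArr[, , k]; dim(r2) <- d[1:2]
        if (!any(r2)) next
        re <- oracleEdges2d(r2, sp)
        a2 <- autoArr[, , k]; dim(a2) <- d[1:2]
        if (!any(a2)) { total <- total + sum(re$lengths); next }
        ae <- oracleEdges2d(a2, sp)
        dd <- apply(re$points, 1, function(p)
            sqrt(min(colSums((t(ae$points) - p)^2))))
        total <- total + sum(re$lengths[dd > tol])
    }
    total
}

oracleEdges2d <- function(m2, sp) {
    idx <- which(m2, arr.ind = TRUE)
    d <- dim(m2)
    lens <- c(sp[2], sp[1])
    pts <- list(); ln <- list()
    for (r in seq_len(nrow(idx))) {
        v <- idx[r, ]
        for (ax in 1:2) for (s in c(-1L, 1L)) {
            nb <- v; nb[ax] <- nb[ax] + s
            if (nb[ax] < 1 || nb[ax] > d[ax] || !m2[nb[1], nb[2]]) {
                p <- (v - 1) * sp[1:2]
                p[ax] <- p[ax] + s * sp[ax] / 2
                pts[[length(pts) + 1L]] <- p
                ln[[length(ln) + 1L]] <- lens[ax]
            }
        }
    }
    list(points = do.call(rbind, pts), lengths = unlist(ln))
}

# Convenience builders.
cubeMask <- function(dims, lo, size, sp = c(1, 1, 1)) {
    m <- array(FALSE, dims)
    m[lo[1]:(lo[1] + size[1] - 1), lo[2]:(lo[2] + size[2] - 1),
      lo[3]:(lo[3] + size[3] - 1)] <- TRUE
    binaryMask(m, spacing = sp)
}

randomMaskPair <- function(dims = c(12, 12, 8), sp = c(1.1875, 1.1875, 3),
                           p = 0.25) {
    repeat { a <- array(stats::runif(prod(dims)) < p, dims); if (any(a)) break }
    repeat { b <- array(stats::runif(prod(dims)) < p, dims); if (any(b)) break }
    list(a = binaryMask(a, spacing = sp), b = binaryMask(b, spacing = sp))
}
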
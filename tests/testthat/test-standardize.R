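test_that("bias correction leaves unbiased inputs essentially unchanged", {
    flat <- imageVolume(array(100, c(10, 10, 10)))
    out <- correctBiasField(flat)
    expect_lt(max(abs(imgData(out) - 100)), 1e-9)
    one <- imageVolume(array(5, c(1, 1, 1)))
    expect_identical(imgData(correctBiasField(one)), imgData(one))
    expect_error(correctBiasField(imageVolume(array(0, c(8, 8, 8)))),
                 "all-zero")
})

test_that("bias correction recovers a known smooth field on phantoms", {
    ph <- makePhantom(phantomSpec(seed = 4, noise_sd = 0))
    fg <- ph$noiseless > 0
    ratioCV <- function(arr) {
        r <- arr[fg] / ph$noiseless[fg]
        stats::sd(r) / mean(r)
    }
    cvIn <- ratioCV(imgData(ph$volume))
    out <- correctBiasField(ph$volume)
    cvOut <- ratioCV(imgData(out))
    expect_lt(cvOut, 0.5 * cvIn)
    # mean preserved and the removed field smooth and positive
    expect_equal(mean(imgData(out)), mean(imgData(ph$volume)),
                 tolerance = 0.05)
    expect_true(all(out@metadata$bias_field > 0))
})

test_that("anisotropic diffusion denoises but keeps edges and the mean", {
    set.seed(9)
    sp <- c(1, 1, 2)
    a <- array(0, c(24, 24, 12)); a[13:24, , ] <- 100
    noisy <- a + rnorm(length(a), sd = 5)
    v <- imageVolume(noisy, spacing = sp)
    cfg <- normalizationConfig(diffusion_iters = 5)
    out <- imgData(denoiseAnisotropic(v, cfg))
    expect_gt(var(as.vector(noisy[1:10, , ])) /
              var(as.vector(out[1:10, , ])), 4)
    expect_gt(var(as.vector(noisy[15:24, , ])) /
              var(as.vector(out[15:24, , ])), 4)
    profIn <- apply(noisy, 1, mean); profOut <- apply(out, 1, mean)
    expect_identical(which.max(diff(profOut)), which.max(diff(profIn)))
    expect_equal(mean(out), mean(noisy), tolerance = 0.01 * abs(mean(noisy)))
    # identity and degenerate cases
    expect_identical(
        imgData(denoiseAnisotropic(v, normalizationConfig(diffusion_iters = 0))),
        noisy)
    flat <- imageVolume(array(7, c(6, 6, 6)))
    expect_lt(max(abs(imgData(denoiseAnisotropic(flat, cfg)) - 7)), 1e-6)
    # exceeding the explicit stability bound is an error, not a clamp
    bound <- 1 / (2 * sum(1 / sp^2))
    expect_error(denoiseAnisotropic(v, normalizationConfig(
        diffusion_iters = 2, diffusion_dt = bound * 1.5)), "stability")
})

test_that("median normalisation fixes the foreground median at one", {
    set.seed(21)
    a <- array(rgamma(4000, shape = 4, scale = 60), c(20, 20, 10))
    a[1:5, 1:5, ] <- 0   # background
    v <- imageVolume(a)
    out <- normalizeToMedian(v)
    thr <- out@metadata$fg_threshold            # in input intensity units
    expect_equal(stats::median(imgData(out)[a > thr]), 1, tolerance = 1e-9)
    # invariance to positive global scaling
    out7 <- normalizeToMedian(imageVolume(a * 7))
    expect_lt(max(abs(imgData(out7) - imgData(out))), 1e-12)
    # rank order preserved
    o1 <- order(as.vector(a)); o2 <- order(as.vector(imgData(out)))
    expect_identical(o1, o2)
    expect_error(normalizeToMedian(imageVolume(array(3, c(4, 4, 4)))),
                 "distinct")
    expect_error(normalizeToMedian(imageVolume(array(c(-9, -5, -1, 0),
                                                     c(4, 1, 1)))),
                 "not positive")
})

test_that("percentile-window z-score has exact in-window moments", {
    a <- array(as.numeric(1:1000), c(10, 10, 10))
    v <- imageVolume(a)
    out <- zscorePercentile(v)
    # brute-force recomputation of the window statistics
    qb <- stats::quantile(a, c(0.25, 99.75) / 100, names = FALSE)
    w <- a >= qb[1] & a <= qb[2]
    expect_lt(sum(w), length(a))       # extremes excluded
    muW <- mean(a[w]); sdW <- stats::sd(a[w])
    expect_equal(imgData(out), (a - muW) / sdW, tolerance = 1e-12)
    expect_equal(mean(imgData(out)[w]), 0, tolerance = 1e-9)
    expect_equal(stats::sd(imgData(out)[w]), 1, tolerance = 1e-9)
    # no clipping outside the window
    expect_equal(max(imgData(out)), (1000 - muW) / sdW)
    # idempotent up to re-derivation: applying again still gives (0, 1)
    out2 <- zscorePercentile(out)
    qb2 <- stats::quantile(imgData(out), c(0.25, 99.75) / 100, names = FALSE)
    w2 <- imgData(out) >= qb2[1] & imgData(out) <= qb2[2]
    expect_equal(mean(imgData(out2)[w2]), 0, tolerance = 1e-9)
    expect_equal(stats::sd(imgData(out2)[w2]), 1, tolerance = 1e-9)
    expect_error(zscorePercentile(imageVolume(array(4, c(5, 5, 5)))),
                 "zero")
    # pooled (per-patient) statistics: both acquisitions get one transform
    set.seed(61)
    v1 <- imageVolume(array(rnorm(512, 100, 10), c(8, 8, 8)))
    v2 <- imageVolume(array(rnorm(512, 140, 12), c(8, 8, 8)))
    z1 <- zscorePercentile(v1, stats_from = list(v1, v2))
    z2 <- zscorePercentile(v2, stats_from = list(v1, v2))
    expect_identical(z1@metadata$zscore$mu, z2@metadata$zscore$mu)
    expect_identical(z1@metadata$zscore$sigma, z2@metadata$zscore$sigma)
    expect_gt(mean(imgData(z2)), mean(imgData(z1)))  # contrast preserved
})

test_that("the full pipeline standardises phantoms deterministically", {
    spec <- phantomSpec(seed = 12, noise_sd = 4)
    ph <- makePhantom(spec)
    cfg <- normalizationConfig(diffusion_iters = 3)
    out <- standardizePipeline(ph$volume, cfg)
    expect_identical(dim(imgData(out)), dim(imgData(ph$volume)))
    expect_identical(spacing(out), spacing(ph$volume))
    # foreground median is 1 after the chain
    a <- imgData(out)
    fgm <- a > out@metadata$fg_threshold / out@metadata$median_divisor
    expect_equal(stats::median(a[fgm]), 1, tolerance = 1e-9)
    # within-organ variability reduced relative to the raw volume
    liver <- imgData(ph$structures[["liver"]])
    cv <- function(x) stats::sd(x) / mean(x)
    expect_lt(cv(a[liver]), cv(imgData(ph$volume)[liver]))
    # determinism
    out2 <- standardizePipeline(makePhantom(spec)$volume, cfg)
    expect_identical(imgData(out), imgData(out2))
    expect_identical(out@metadata$provenance$stages,
                     c("correctBiasField", "denoiseAnisotropic",
                       "normalizeToMedian"))
})

test_that("standardisation pulls differently scaled acquisitions together", {
    base <- phantomSpec(seed = 30, noise_sd = 3)
    ph1 <- makePhantom(base)
    ph2 <- makePhantom(phantomSpec(seed = 31, noise_sd = 3))
    # second "sequence": different global scale on the same anatomy
    v2 <- imageVolume(imgData(ph2$volume) * 2.6, spacing = spacing(ph2$volume))
    w1 <- function(x, y) {   # 1D Wasserstein distance between histograms
        qs <- seq(0.01, 0.99, by = 0.01)
        mean(abs(stats::quantile(x, qs) - stats::quantile(y, qs)))
    }
    cfg <- normalizationConfig(diffusion_iters = 2)
    dRaw <- w1(imgData(ph1$volume), imgData(v2))
    s1 <- imgData(standardizePipeline(ph1$volume, cfg))
    s2 <- imgData(standardizePipeline(v2, cfg))
    dStd <- w1(s1, s2)
    expect_lt(dStd, dRaw / 2)
})

test_that("pipeline with identity-like configuration returns input almost unchanged", {
    set.seed(40)
    a <- array(1 + 0.01 * rnorm(12^3), c(12, 12, 12))
    v <- imageVolume(a)
    out <- standardizePipeline(v, normalizationConfig(diffusion_iters = 0))
    expect_lt(max(abs(imgData(out) - a)), 0.02)
})
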
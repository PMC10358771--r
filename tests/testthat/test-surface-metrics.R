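dims <- c(20, 20, 16)
cube10 <- cubeMask(dims, c(4, 4, 4), c(10, 10, 10))

test_that("dsc matches analytic overlap values", {
    expect_equal(dsc(cube10, cube10), 1)
    other <- cubeMask(dims, c(16, 16, 2), c(3, 3, 3))
    expect_equal(dsc(other, cube10), 0)
    shifted <- perturbMask(cube10, "translate_mm", 2)
    expect_equal(dsc(shifted, cube10), 0.8)
    eA <- binaryMask(array(FALSE, dims)); eB <- binaryMask(array(FALSE, dims))
    expect_equal(dsc(eA, eB), 1)       # agreement on absence
    expect_equal(dsc(eA, cube10), 0)
})

test_that("surface extraction counts exposed faces with physical areas", {
    s1 <- extractSurface(binaryMask(array(TRUE, c(1, 1, 1))))
    expect_equal(nrow(s1@points), 6)
    expect_equal(sum(s1@areas), 6)
    s2 <- extractSurface(binaryMask(array(TRUE, c(2, 2, 2))))
    expect_equal(sum(s2@areas), 24)
    sp <- c(1.1875, 1.1875, 3)
    c10 <- cubeMask(c(14, 14, 14), c(2, 2, 2), c(10, 10, 10), sp)
    sA <- extractSurface(c10)
    expected <- 2 * (10 * sp[1] * 10 * sp[2]) + 4 * (10 * sp[1] * 10 * sp[3])
    expect_equal(sum(sA@areas), expected)
    bf <- oracleFaces(imgData(c10), sp)
    expect_equal(sum(sA@areas), sum(bf$areas))
    expect_equal(nrow(sA@points), nrow(bf$points))
    empty <- extractSurface(binaryMask(array(FALSE, c(3, 3, 3))))
    expect_equal(nrow(empty@points), 0)
})

test_that("surface distances equal brute-force nearest distances", {
    sp <- c(1, 1, 3)
    a <- binaryMask(array(FALSE, c(10, 10, 10)), sp)
    a@data[3, 3, 2] <- TRUE
    b <- binaryMask(array(FALSE, c(10, 10, 10)), sp)
    b@data[3, 3, 7] <- TRUE
    sd <- surfaceDistances(a, b)
    fa <- oracleFaces(imgData(a), sp); fb <- oracleFaces(imgData(b), sp)
    expect_equal(sort(sd$d_ab), sort(oracleNN(fa$points, fb$points)),
                 tolerance = 1e-9)
    expect_equal(min(sd$d_ab), 5 * 3 - 3)  # facing faces, 5 voxels at dz=3
    same <- surfaceDistances(a, a)
    expect_true(all(same$d_ab == 0) && all(same$d_ba == 0))
    expect_error(surfaceDistances(a, binaryMask(array(FALSE, c(10, 10, 10)),
                                                sp)), "empty")
})

test_that("distance metrics agree with the brute-force oracle on random pairs", {
    set.seed(202)
    cfg <- metricConfig()
    for (i in 1:40) {
        pr <- randomMaskPair()
        bf <- oracleSurfaceMetrics(imgData(pr$a), imgData(pr$b),
                                   spacing(pr$a))
        expect_equal(mda(pr$a, pr$b), bf$mda, tolerance = 1e-6)
        expect_equal(hd95(pr$a, pr$b), bf$hd, tolerance = 1e-6)
        expect_equal(hd95(pr$a, pr$b, metricConfig(hd_percentile = 100)),
                     bf$hdmax, tolerance = 1e-6)
        expect_equal(sdsc(pr$a, pr$b), bf$sdsc, tolerance = 1e-6)
        expect_equal(apl(pr$a, pr$b), bf$apl, tolerance = 1e-6)
    }
})

test_that("mda and hd95 are symmetric; hd95 dominates mda", {
    set.seed(77)
    for (i in 1:25) {
        pr <- randomMaskPair()
        expect_identical(mda(pr$a, pr$b), mda(pr$b, pr$a))
        expect_identical(hd95(pr$a, pr$b), hd95(pr$b, pr$a))
        expect_gte(hd95(pr$a, pr$b), mda(pr$a, pr$b) - 1e-12)
    }
})

test_that("pvd follows the signed volume convention", {
    expect_equal(pvd(cube10, cube10), 0)
    grown <- cubeMask(dims, c(3, 3, 3), c(12, 12, 12))  # full 12^3 box
    expect_equal(pvd(grown, cube10), 100 * (12^3 - 10^3) / 10^3)
    expect_equal(round(pvd(grown, cube10), 1), 72.8)
    small <- cubeMask(dims, c(4, 4, 4), c(10, 9, 10))  # 900 voxels
    expect_equal(pvd(small, cube10), -10)
    expect_error(pvd(cube10, binaryMask(array(FALSE, dims))), "empty")
})

test_that("sdsc responds to tolerance as designed", {
    cfg2 <- metricConfig(tolerance_mm = 2)
    sh1 <- perturbMask(cube10, "translate_mm", 1)
    expect_equal(sdsc(sh1, cube10, cfg2), 1)
    sh5 <- perturbMask(cube10, "translate_mm", 5)
    bf <- oracleSurfaceMetrics(imgData(sh5), imgData(cube10), c(1, 1, 1))
    expect_equal(sdsc(sh5, cube10, cfg2), bf$sdsc, tolerance = 1e-9)
    far <- cubeMask(dims, c(17, 17, 13), c(3, 3, 3))  # > 2 mm from cube10
    expect_equal(sdsc(far, cube10, cfg2), 0)
    expect_equal(sdsc(cube10, cube10, metricConfig(tolerance_mm = 0)), 1)
    expect_equal(sdsc(sh5, cube10, metricConfig(tolerance_mm = 1e6)), 1)
    # tolerance 0: fraction of exactly coincident surface
    bf0 <- oracleSurfaceMetrics(imgData(sh5), imgData(cube10), c(1, 1, 1),
                                tol = 0)
    expect_equal(sdsc(sh5, cube10, metricConfig(tolerance_mm = 0)),
                 bf0$sdsc, tolerance = 1e-9)
})

test_that("apl covers the analytic contour-editing cases", {
    expect_equal(apl(cube10, cube10), 0)
    none <- binaryMask(array(FALSE, dims))
    expect_equal(apl(none, cube10), 10 * 40)  # 10 slices x 40 mm perimeter
    sh1 <- perturbMask(cube10, "translate_mm", 1)
    expect_equal(apl(sh1, cube10), 0)
    sh5 <- perturbMask(cube10, "translate_mm", 5)
    expect_equal(apl(sh5, cube10),
                 oracleAPL(imgData(sh5), imgData(cube10), c(1, 1, 1)),
                 tolerance = 1e-9)
    expect_error(apl(cube10, none), "empty")
})

test_that("rapl divides apl by the reference volume", {
    sh5 <- perturbMask(cube10, "translate_mm", 5)
    expect_equal(rapl(sh5, cube10), apl(sh5, cube10) / volumeCC(cube10))
    expect_equal(rapl(cube10, cube10), 0)
    # doubling linear size: APL grows ~4x, volume 8x, so rAPL roughly halves
    big <- cubeMask(c(40, 40, 32), c(8, 8, 8), c(20, 20, 20))
    bigAuto <- perturbMask(big, "translate_mm", 5)
    r1 <- rapl(sh5, cube10); r2 <- rapl(bigAuto, big)
    expect_lt(r2, r1 * 0.75)
    expect_gt(r2, r1 * 0.25)
})

test_that("erosion of the auto contour degrades metrics monotonically", {
    prev <- list(dsc = 1, sdsc = 1, apl = 0)
    for (k in 1:3) {
        er <- perturbMask(cube10, "erode_voxels", k)
        d <- dsc(er, cube10); s <- sdsc(er, cube10); a <- apl(er, cube10)
        expect_lte(d, prev$dsc + 1e-12)
        expect_lte(s, prev$sdsc + 1e-12)
        expect_gte(a, prev$apl - 1e-12)
        prev <- list(dsc = d, sdsc = s, apl = a)
    }
})

test_that("distances scale linearly with spacing; overlap metrics are invariant", {
    set.seed(5)
    pr <- randomMaskPair(sp = c(1, 1, 2))
    a2 <- binaryMask(imgData(pr$a), spacing = c(3, 3, 6))
    b2 <- binaryMask(imgData(pr$b), spacing = c(3, 3, 6))
    expect_equal(mda(a2, b2), 3 * mda(pr$a, pr$b), tolerance = 1e-9)
    expect_equal(hd95(a2, b2), 3 * hd95(pr$a, pr$b), tolerance = 1e-9)
    expect_equal(dsc(a2, b2), dsc(pr$a, pr$b))
    expect_equal(sdsc(a2, b2, metricConfig(tolerance_mm = 6)),
                 sdsc(pr$a, pr$b, metricConfig(tolerance_mm = 2)),
                 tolerance = 1e-9)
})

test_that("evaluatePair reports all organs and isolates empty ones", {
    ph <- makePhantom(phantomSpec(seed = 3, noise_sd = 0,
                                  bias_amplitude = 0))
    res <- evaluatePair(ph$structures, ph$structures)
    expect_equal(nrow(res), 12)
    expect_true(all(res$dsc == 1))
    expect_true(all(res$sdsc == 1))
    expect_true(all(res$mda_mm == 0 & res$hd95_mm == 0 & res$apl_mm == 0))
    expect_true(all(res$pvd_pct == 0))
    # drop one organ from the auto set
    autoOrgans <- ph$structures@organs
    autoOrgans$liver <- binaryMask(
        array(FALSE, dim(imgData(autoOrgans$liver))),
        spacing = spacing(ph$structures))
    res2 <- evaluatePair(structureSet(autoOrgans), ph$structures)
    lv <- res2[res2$organ == "liver", ]
    expect_identical(lv$flag, "empty_auto")
    expect_equal(lv$dsc, 0)
    expect_equal(lv$pvd_pct, -100)
    expect_true(is.na(lv$mda_mm) && is.na(lv$sdsc))
    expect_gt(lv$apl_mm, 0)
    expect_true(all(res2$dsc[res2$organ != "liver"] == 1))
    # organ name mismatch is an error naming the difference
    expect_error(evaluatePair(structureSet(autoOrgans[1:3]),
                              ph$structures), "differ")
})
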
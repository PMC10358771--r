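test_that("metric categorisation honours inclusive thresholds", {
    expect_identical(gradeMetric("dsc", 0.96), "best")
    expect_identical(gradeMetric("dsc", 0.9), "best")     # boundary
    expect_identical(gradeMetric("dsc", 0.85), "good")
    expect_identical(gradeMetric("dsc", 0.8), "good")     # boundary
    expect_identical(gradeMetric("dsc", 0.79), "suboptimal")
    expect_identical(gradeMetric("pvd", -36.3), "suboptimal")
    expect_identical(gradeMetric("pvd", -2.9), "best")    # graded on |PVD|
    expect_identical(gradeMetric("mda", 1.5), "best")
    expect_identical(gradeMetric("hd95", 10), "good")
    expect_identical(gradeMetric("rapl", 10.01), "suboptimal")
    expect_error(gradeMetric("apl", 3), "ungradable")
    expect_error(gradeMetric("banana", 3), "unknown")
})

test_that("categories are monotone in the metric value", {
    lvl <- c(best = 1, good = 2, suboptimal = 3)
    for (m in c("dsc", "sdsc")) {
        vals <- seq(0, 1, by = 0.01)
        cats <- lvl[gradeMetric(m, vals)]
        expect_true(all(diff(cats) <= 0))   # higher value never worse
    }
    for (m in c("mda", "hd95", "rapl")) {
        vals <- seq(0, 20, by = 0.1)
        cats <- lvl[gradeMetric(m, vals)]
        expect_true(all(diff(cats) >= 0))   # higher value never better
    }
    cats <- lvl[gradeMetric("pvd", seq(0, 20, by = 0.1))]
    expect_true(all(diff(cats) >= 0))
})

test_that("custom grade tables must keep best at least as strict as good", {
    expect_error(gradeTables(best = c(dsc = 0.7, mda_mm = 1.5, hd95_mm = 5,
                                      pvd_pct = 3, sdsc = 0.85,
                                      rapl_mm_per_cc = 5)),
                 "strict")
    relaxed <- gradeTables(good = c(dsc = 0.7, mda_mm = 4, hd95_mm = 12,
                                    pvd_pct = 8, sdsc = 0.65,
                                    rapl_mm_per_cc = 12))
    expect_identical(gradeMetric("dsc", 0.75, relaxed), "good")
})

test_that("edit scorecard reproduces the boundary rules", {
    expect_identical(scoreEdits(0, 40), 1L)
    expect_identical(scoreEdits(60, 100), 5L)
    expect_identical(scoreEdits(85, 100), 6L)
    expect_identical(scoreEdits(3, 40, "delete_or_expand"), 2L)
    expect_identical(scoreEdits(7, 40, "fix_incomplete"), 3L)
    expect_identical(scoreEdits(15, 40, "junction_or_hilum"), 4L)
    expect_identical(scoreEdits(20, 100), 4L)   # ~20 slices, under half
    expect_identical(scoreEdits(1, 100, "full_redo"), 6L)
    expect_error(scoreEdits(12, 10), "inconsistent")
    expect_error(scoreEdits(-1, 10), "inconsistent")
})

test_that("edit score is monotone in the number of edited slices", {
    for (kind in c("none", "delete_or_expand", "fix_incomplete",
                   "junction_or_hilum")) {
        sc <- vapply(0:100, scoreEdits, integer(1), total_slices = 100,
                     edit_kind = kind)
        expect_true(all(diff(sc) >= 0))
    }
})

test_that("aggregation produces per-organ, overall, and radar tables", {
    tab <- examplePerOrganMetrics()
    ag <- aggregateMetrics(tab)
    expect_equal(nrow(ag$per_organ), 36)
    expect_equal(nrow(ag$overall), 3)
    # singleton collapse: one row in, all means equal that value
    one <- tab[1, ]
    one$model <- "solo"
    ag1 <- aggregateMetrics(one)
    expect_equal(ag1$overall$dsc, one$dsc)
    expect_equal(ag1$per_organ$mda_mm, one$mda_mm)
    # radar normalisation: the per-metric max magnitude maps to 1
    for (mc in c("dsc", "mda_mm", "hd95_mm", "pvd_pct", "sdsc",
                 "rapl_mm_per_cc"))
        expect_equal(max(abs(ag$radar[[mc]])), 1)
    expect_error(aggregateMetrics(tab[0, ]), "non-empty")
})

test_that("per-contour categories vote with ties toward the worse label", {
    best <- c(dsc = 0.95, mda_mm = 1, hd95_mm = 3, pvd_pct = 1,
              sdsc = 0.9, rapl_mm_per_cc = 2)
    worst <- c(dsc = 0.5, mda_mm = 8, hd95_mm = 30, pvd_pct = 40,
               sdsc = 0.4, rapl_mm_per_cc = 50)
    expect_identical(contourCategory(best), "best")
    expect_identical(contourCategory(worst), "suboptimal")
    tie <- c(dsc = 0.95, mda_mm = 1, hd95_mm = 3,        # 3 best
             pvd_pct = 40, sdsc = 0.4, rapl_mm_per_cc = 50)  # 3 suboptimal
    expect_identical(contourCategory(tie), "suboptimal")
    df <- data.frame(rbind(best, best, worst, worst))
    expect_equal(percentBestGood(df), 50)
    expect_equal(percentBestGood(data.frame(rbind(best))), 100)
    expect_equal(percentBestGood(data.frame(rbind(worst))), 0)
})

test_that("percent best/good matches construction on a labelled ensemble", {
    set.seed(13)
    mk <- function(cat) {
        if (cat == "good")
            c(dsc = runif(1, 0.8, 0.89), mda_mm = runif(1, 1.6, 2.9),
              hd95_mm = runif(1, 5.5, 9.9), pvd_pct = runif(1, 3.2, 5.9),
              sdsc = runif(1, 0.75, 0.84), rapl_mm_per_cc = runif(1, 5.2, 9.8))
        else if (cat == "best")
            c(dsc = runif(1, 0.91, 0.99), mda_mm = runif(1, 0.1, 1.4),
              hd95_mm = runif(1, 0.5, 4.9), pvd_pct = runif(1, 0, 2.9),
              sdsc = runif(1, 0.86, 0.99), rapl_mm_per_cc = runif(1, 0, 4.9))
        else
            c(dsc = runif(1, 0.3, 0.79), mda_mm = runif(1, 3.1, 9),
              hd95_mm = runif(1, 10.5, 30), pvd_pct = runif(1, 6.2, 40),
              sdsc = runif(1, 0.2, 0.74), rapl_mm_per_cc = runif(1, 10.5, 60))
    }
    labels <- sample(c("best", "good", "suboptimal"), 60, replace = TRUE)
    df <- as.data.frame(do.call(rbind, lapply(labels, mk)))
    expect_equal(percentBestGood(df),
                 100 * mean(labels %in% c("best", "good")))
})
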
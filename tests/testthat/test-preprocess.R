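test_that("log2 transform has the closed-form values and guards", {
    m <- matrix(c(8, 1, 0, 1024), 2, 2,
                dimnames = list(c("A", "B"), c("s1", "s2")))
    pqt <- ProteinQuantTable(m, scaleTag = "linear")
    lg <- log2Transform(pqt)
    expect_identical(scaleTag(lg), "log2")
    expect_equal(intensities(lg)["A", "s1"], 3)
    expect_equal(intensities(lg)["B", "s1"], 0)
    expect_true(is.na(intensities(lg)["A", "s2"]))   # missing stays missing
    expect_true(missingMask(lg)["A", "s2"])
    expect_error(log2Transform(lg), "already")
    # 2^x then log2 is the identity on observed cells
    expect_equal(intensities(lg)[!missingMask(lg)],
                 log2(m[m != 0]))
})

test_that("detection filtering keeps >=60% in the best condition, inclusively", {
    # rows: 4/6 bait + 0/6 ctrl (kept); 3/6 + 3/6 (removed); 6/6 + 6/6
    # (kept); exactly 60% in one condition with a 5-sample condition ->
    # kept (inclusive threshold)
    det <- rbind(c(rep(TRUE, 4), FALSE, FALSE, rep(FALSE, 6)),
                 c(rep(TRUE, 3), rep(FALSE, 3), rep(TRUE, 3), rep(FALSE, 3)),
                 rep(TRUE, 12))
    m <- matrix(25, 3, 12,
                dimnames = list(c("kept46", "gone33", "keptAll"),
                                c(paste0("b", 1:6), paste0("c", 1:6))))
    m[!det] <- 0
    pqt <- ProteinQuantTable(m, scaleTag = "linear")
    des <- makeTwoGroupDesign(colnames(m), 6)
    kept <- filterByDetection(pqt, des)
    expect_identical(proteinIds(kept), c("kept46", "keptAll"))

    # idempotence
    again <- filterByDetection(kept, des)
    expect_identical(intensities(again), intensities(kept))

    # inclusive boundary: 3/5 detected is exactly 60%
    m5 <- matrix(c(2, 4, 8, 0, 0), 1, 5,
                 dimnames = list("edge", paste0("s", 1:5)))
    d5 <- makeTwoGroupDesign(colnames(m5), 5, condA = "BAIT_INTACT")
    expect_identical(proteinIds(filterByDetection(
        ProteinQuantTable(m5, scaleTag = "linear"), d5)), "edge")

    expect_error(filterByDetection(pqt, des[0, ]), "empty")
})

test_that("MNAR imputation draws from the left-shifted Gaussian", {
    # one sample whose observed values have mean exactly 25 and SD exactly 2
    nMiss <- 20000
    m <- matrix(c(23, 25, 27, rep(NA_real_, nMiss)), ncol = 1,
                dimnames = list(sprintf("P%05d", seq_len(nMiss + 3)), "s1"))
    pqt <- ProteinQuantTable(m, scaleTag = "log2")
    imp <- imputeMNAR(pqt, seed = 421)
    draws <- intensities(imp)[missingMask(imp)]
    expect_length(draws, nMiss)
    expect_equal(mean(draws), 25 - 1.8 * 2, tolerance = 0.05 / 21.4)
    expect_equal(sd(draws), 0.3 * 2, tolerance = 0.03 / 0.6)
    # observed cells untouched
    expect_equal(intensities(imp)[1:3, 1], c(23, 25, 27),
                 ignore_attr = TRUE)
    # imputed values lie below the observed mean essentially always
    # (sanity bound: at least pnorm(1.8 / 1.3))
    expect_gte(mean(draws < 25), pnorm(1.8 / 1.3))
})

test_that("imputation is seed-reproducible and leaves observed cells alone", {
    set.seed(9)
    m <- matrix(rnorm(200, 25, 2), 20, 10,
                dimnames = list(sprintf("P%02d", 1:20), paste0("s", 1:10)))
    m[sample(length(m), 40)] <- NA
    pqt <- ProteinQuantTable(m, scaleTag = "log2")
    i1 <- imputeMNAR(pqt, seed = 7)
    i2 <- imputeMNAR(pqt, seed = 7)
    i3 <- imputeMNAR(pqt, seed = 8)
    expect_identical(intensities(i1), intensities(i2))
    obs <- !missingMask(pqt)
    expect_identical(intensities(i1)[obs], intensities(i3)[obs])
    expect_false(identical(intensities(i1)[!obs], intensities(i3)[!obs]))

    # degenerate width: every draw is exactly mu - 1.8 sigma of its sample
    i0 <- imputeMNAR(pqt, widthSd = 0, seed = 1)
    for (j in seq_len(ncol(m))) {
        miss <- is.na(m[, j])
        if (!any(miss)) next
        expected <- mean(m[!miss, j]) - 1.8 * sd(m[!miss, j])
        expect_equal(unname(intensities(i0)[miss, j]),
                     rep(expected, sum(miss)))
    }

    # no missing values: output identical to input
    full <- ProteinQuantTable(matrix(rnorm(20, 25), 4, 5,
        dimnames = list(paste0("P", 1:4), paste0("s", 1:5))),
        scaleTag = "log2")
    expect_identical(intensities(imputeMNAR(full, seed = 1))[, ],
                     intensities(full)[, ])

    # a sample entirely missing is named in the error
    bad <- m; bad[, 3] <- NA
    expect_error(imputeMNAR(ProteinQuantTable(bad, scaleTag = "log2"),
                            seed = 1), "s3")
})

test_that("normalization methods satisfy their defining properties", {
    set.seed(31)
    m <- matrix(rnorm(600, 25, 2), 100, 6,
                dimnames = list(sprintf("P%03d", 1:100), paste0("s", 1:6)))
    pqt <- makePQT(m)

    med <- normalizeIntensities(pqt, "median_center")
    expect_equal(unname(apply(intensities(med), 2, median)), rep(0, 6))

    idn <- normalizeIntensities(pqt, "none")
    expect_identical(intensities(idn)[, ], m)

    # two samples differing only by a constant offset become identical
    # columns under either method
    off <- cbind(m[, 1:4], s5 = m[, 1] + 1.7, s6 = m[, 1] - 2.4)
    colnames(off) <- paste0("s", 1:6)
    for (meth in c("vsn_like", "median_center")) {
        v <- intensities(normalizeIntensities(makePQT(off), meth))
        expect_equal(v[, "s5"], v[, "s1"], tolerance = 1e-10,
                     ignore_attr = TRUE)
        expect_equal(v[, "s6"], v[, "s1"], tolerance = 1e-10,
                     ignore_attr = TRUE)
    }

    # vsn_like is monotone within each sample (rank preservation)
    for (seed in 1:5) {
        set.seed(seed)
        r <- matrix(rnorm(300, 25, 3), 60, 5,
                    dimnames = list(sprintf("P%02d", 1:60), paste0("s", 1:5)))
        v <- intensities(normalizeIntensities(makePQT(r), "vsn_like"))
        for (j in 1:5)
            expect_identical(order(v[, j]), order(r[, j]))
    }

    expect_error(normalizeIntensities(
        makePQT(matrix(rnorm(10, 25), 10, 1), imputed = TRUE), "vsn_like"),
        "2 samples")
    withNA <- ProteinQuantTable(
        matrix(c(25, NA, 24, 26), 2, 2,
               dimnames = list(c("A", "B"), c("s1", "s2"))),
        scaleTag = "log2")
    expect_error(normalizeIntensities(withNA, "median_center"), "imputed")
})

test_that("row z-scoring follows the documented SD conventions", {
    m <- matrix(c(1, 2, 3), 1, 3, dimnames = list("A", paste0("s", 1:3)))
    expect_equal(unname(zscoreRows(m, "population")[1, ]),
                 c(-1, 0, 1) / sqrt(2 / 3))
    expect_equal(unname(zscoreRows(m, "sample")[1, ]), c(-1, 0, 1))
    # an already-standardized row is unchanged
    z <- zscoreRows(m, "population")
    expect_equal(zscoreRows(z, "population"), z)
    set.seed(4)
    r <- matrix(rnorm(50), 5, 10)
    expect_true(all(abs(rowMeans(zscoreRows(r))) < 1e-12))
    expect_equal(unname(apply(zscoreRows(r, "sample"), 1, sd)), rep(1, 5))
    cst <- rbind(A = c(1, 1, 1), B = c(1, 2, 3))
    expect_error(zscoreRows(cst), "A")
})
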
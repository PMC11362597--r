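test_that("PCA separates well-separated groups and reports ordered variance fractions", {
    set.seed(21)
    n <- 200
    m <- matrix(rnorm(n * 12, 25, 1), n, 12,
                dimnames = list(sprintf("P%03d", 1:n), paste0("s", 1:12)))
    shifted <- sample(n, n * 0.3)
    m[shifted, 7:12] <- m[shifted, 7:12] + 4   # 4 sigma on 30% of proteins
    pca <- runPCA(makePQT(m), nComponents = 3)
    pc1 <- pca$coords[, 1]
    expect_true(max(pc1[1:6]) < min(pc1[7:12]) ||
                min(pc1[1:6]) > max(pc1[7:12]))
    expect_lte(sum(pca$varianceExplained), 1)
    expect_true(all(diff(pca$varianceExplained) <= 1e-12))

    # duplicated sample -> identical coordinates
    dup <- cbind(m, s13 = m[, 1])
    pcaDup <- runPCA(makePQT(dup), nComponents = 2)
    expect_equal(pcaDup$coords["s13", ], pcaDup$coords["s1", ],
                 ignore_attr = TRUE)

    # invariance (up to sign) under protein reordering
    perm <- sample(n)
    pcaPerm <- runPCA(makePQT(m[perm, ]), nComponents = 2)
    for (k in 1:2)
        expect_equal(abs(pcaPerm$coords[, k]), abs(pca$coords[, k]),
                     tolerance = 1e-8)

    expect_error(runPCA(makePQT(m[, 1, drop = FALSE])), "2 samples")
})

test_that("Pearson matrix is symmetric with unit diagonal and group structure", {
    set.seed(22)
    base <- rnorm(100, 25, 2)
    grpA <- sapply(1:3, function(i) base + rnorm(100, 0, 0.5))
    grpB <- sapply(1:3, function(i) base + rnorm(100, 0, 0.5) +
                       c(rep(4, 30), rep(0, 70)))
    m <- cbind(grpA, grpB)
    dimnames(m) <- list(sprintf("P%03d", 1:100), paste0("s", 1:6))
    r <- pearsonMatrix(makePQT(m))
    expect_equal(r, t(r))
    expect_equal(unname(diag(r)), rep(1, 6))
    within <- c(r[1, 2], r[1, 3], r[2, 3], r[4, 5], r[4, 6], r[5, 6])
    between <- as.vector(r[1:3, 4:6])
    expect_gt(mean(within), mean(between))

    # exact anticorrelation by construction
    anti <- cbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1))
    rownames(anti) <- paste0("P", 1:4)
    expect_equal(pearsonMatrix(makePQT(anti))["a", "b"], -1)

    cst <- cbind(a = rep(5, 4), b = c(1, 2, 3, 4))
    rownames(cst) <- paste0("P", 1:4)
    expect_error(pearsonMatrix(makePQT(cst)), "constant")
})

test_that("detected-count comparison behaves on null, shifted and simulated data", {
    det <- matrix(TRUE, 50, 8, dimnames = list(sprintf("P%02d", 1:50),
                                               paste0("s", 1:8)))
    m <- matrix(25, 50, 8, dimnames = dimnames(det))
    des <- makeTwoGroupDesign(colnames(m), 4)
    same <- compareDetectedCounts(makePQT(m, imputed = FALSE), des,
                                  "BAIT_INTACT", "GST_CTRL")
    expect_equal(same$meanDiff, 0)
    expect_equal(same$p, 1)

    # counts (200,200,200) vs (100,100,100): difference 100, but identical
    # within groups -> construct with controlled masks
    m2 <- matrix(25, 300, 6, dimnames = list(sprintf("P%03d", 1:300),
                                             paste0("s", 1:6)))
    m2[201:300, 1:3] <- NA    # group A detects 200, group B detects 300
    d2 <- makeTwoGroupDesign(colnames(m2), 3)
    cc <- compareDetectedCounts(ProteinQuantTable(m2, scaleTag = "log2"),
                                d2, "BAIT_INTACT", "GST_CTRL")
    expect_equal(cc$meanDiff, -100)

    # power: 30% extra detections with n = 6 is nearly always significant
    set.seed(23)
    hits <- 0L
    for (rep in 1:200) {
        det <- cbind(matrix(runif(300 * 6) < 0.91, 300, 6),   # bait
                     matrix(runif(300 * 6) < 0.70, 300, 6))   # control
        mm <- matrix(25, 300, 12,
                     dimnames = list(sprintf("P%03d", 1:300),
                                     paste0("s", 1:12)))
        mm[!det] <- NA
        dd <- makeTwoGroupDesign(colnames(mm), 6)
        p <- compareDetectedCounts(ProteinQuantTable(mm, scaleTag = "log2"),
                                   dd, "BAIT_INTACT", "GST_CTRL")$p
        hits <- hits + (p < 0.05)
    }
    expect_gte(hits / 200, 0.95)
})

test_that("overlap partition percentages use largest-remainder rounding and sum to 100", {
    # union of 775 proteins split 71 control-only / 471 bait-only / 233 shared
    buildOverlap <- function(aOnly, bOnly, shared) {
        n <- aOnly + bOnly + shared
        m <- matrix(NA_real_, n, 2,
                    dimnames = list(sprintf("P%04d", 1:n), c("a1", "b1")))
        m[seq_len(aOnly), 1] <- 25
        m[aOnly + seq_len(bOnly), 2] <- 25
        m[aOnly + bOnly + seq_len(shared), ] <- 25
        des <- StudyDesign(c("a1", "b1"), c("GST_CTRL", "BAIT_INTACT"),
                           c(1, 1))
        list(pqt = ProteinQuantTable(m, scaleTag = "log2"), des = des)
    }
    ov <- with(buildOverlap(71, 471, 233),
               overlapPartition(pqt, des, "GST_CTRL", "BAIT_INTACT"))
    expect_equal(unname(ov$counts), c(71, 471, 233, 775))
    expect_equal(unname(ov$percentages), c(9.16, 60.77, 30.07))
    expect_equal(sum(ov$percentages), 100)

    disjoint <- with(buildOverlap(5, 7, 0),
                     overlapPartition(pqt, des, "GST_CTRL", "BAIT_INTACT"))
    expect_equal(unname(disjoint$counts["shared"]), 0)
    identical_ <- with(buildOverlap(0, 0, 9),
                       overlapPartition(pqt, des, "GST_CTRL", "BAIT_INTACT"))
    expect_equal(unname(identical_$counts[c("a_only", "b_only")]), c(0, 0))

    # percentages always sum to exactly 100 under the rounding scheme
    set.seed(24)
    for (i in 1:25) {
        k <- sample(1:500, 3)
        ov <- with(buildOverlap(k[1], k[2], k[3]),
                   overlapPartition(pqt, des, "GST_CTRL", "BAIT_INTACT"))
        expect_equal(sum(ov$percentages), 100)
        raw <- unname(ov$counts[1:3]) / unname(ov$counts["total"]) * 100
        expect_true(all(abs(ov$percentages - raw) <= 0.011))
    }
})

test_that("hierarchical clustering merges duplicates first and recovers archetypes", {
    m <- rbind(a = c(1, 2, 3, 4), a2 = c(1, 2, 3, 4), b = c(9, 1, 4, 2))
    hc <- hierarchicalCluster(m)
    expect_equal(hc$heights[1], 0)
    expect_identical(sort(hc$linkage$merge[1, ]), c(-2L, -1L))
    expect_true(all(diff(hc$heights) >= 0))
    expect_error(hierarchicalCluster(m, k = 5), "k must be")
    expect_identical(sort(hc$order), 1:3)

    # heights invariant under row permutation
    set.seed(25)
    r <- matrix(rnorm(120), 12, 10)
    rownames(r) <- paste0("P", 1:12)
    h1 <- hierarchicalCluster(r)
    h2 <- hierarchicalCluster(r[sample(12), ])
    expect_equal(sort(h1$heights), sort(h2$heights))

    # three archetypes (bait-up, control-up, mixed) on z-scored rows
    baitUp <- matrix(rep(c(1, 1, 1, -1, -1, -1), 30), 30, 6, byrow = TRUE)
    mixed <- matrix(rep(c(1, -1, 1, -1, 1, -1), 30), 30, 6, byrow = TRUE)
    noisy <- rbind(baitUp, -baitUp, mixed) + matrix(rnorm(540, 0, 0.2), 90, 6)
    rownames(noisy) <- sprintf("P%02d", 1:90)
    z <- zscoreRows(noisy)
    cl <- hierarchicalCluster(z, k = 3)$clusters
    truthCl <- rep(1:3, each = 30)
    agree <- max(sapply(1:6, function(i) {
        perm <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1),
                      c(3,1,2), c(3,2,1))[i, ]
        mean(perm[cl] == truthCl)
    }))
    expect_gte(agree, 0.95)
})

test_that("gaussian check flags non-normal samples and reports near-zero moments for normal ones", {
    set.seed(28)
    g <- gaussianCheck(rnorm(1e4))
    expect_lt(abs(g$skewness), 0.05)
    expect_lt(abs(g$excessKurtosis), 0.1)
    expect_gt(g$p, 0.001)

    e <- gaussianCheck(rexp(1e4))
    expect_lt(e$p, 0.01)
    expect_gt(e$skewness, 1.5)

    expect_error(gaussianCheck(rep(3, 20)), "constant")
    expect_error(gaussianCheck(rnorm(5)), "at least 8")
})
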
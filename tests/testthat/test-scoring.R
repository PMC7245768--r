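test_that("difference matrices hold pairwise metric values in the lower triangle", {
    conf <- colorConformation(c("A", "B"), rbind(c(50, 0, 0), c(50, 3, 4)))
    C <- differenceMatrix(conf, "euclidean")
    expect_equal(C[2, 1], 5)
    expect_equal(C[1, 2], 0)
    same <- colorConformation(LETTERS[1:4],
                              matrix(rep(c(60, 5, 5), each = 4), 4, 3))
    expect_true(all(differenceMatrix(same) == 0))
    # permutation equivariance
    set.seed(21)
    conf5 <- random_conformation(5)
    C5 <- differenceMatrix(conf5)
    p <- sample(5)
    Cp <- differenceMatrix(colorConformation(alphabet(conf5)[p],
                                             labColors(conf5)[p, ]))
    expect_equal(Cp + t(Cp), (C5 + t(C5))[p, p], ignore_attr = TRUE)
})

test_that("scale factor is the reciprocal mean difference", {
    C <- matrix(0, 3, 3); C[lower.tri(C)] <- 2
    expect_equal(scaleFactor(C), 0.5)
    C[lower.tri(C)] <- 1
    expect_equal(scaleFactor(C), 1)
    set.seed(22)
    C[lower.tri(C)] <- stats::runif(3, 0.1, 50)
    expect_equal(scaleFactor(C) * mean(C[lower.tri(C)]), 1, tolerance = 1e-12)
    C[lower.tri(C)] <- 0
    expect_error(scaleFactor(C), "degenerate")
})

test_that("harmonic score vanishes at equilibrium and matches hand values", {
    d <- distanceMatrix(identitySubstitutionMatrix(c("A", "B", "C")))
    # colors whose scaled differences exactly match D
    C <- matrix(0, 3, 3); C[lower.tri(C)] <- 7
    expect_equal(harmonicScore(C, d, scaleFactor(C)), 0)
    # any 2-symbol problem has zero harmonic score
    d2 <- distanceMatrix(substitutionMatrix(c("A", "B"),
                                            matrix(c(4, 1, 1, 5), 2, 2)))
    C2 <- matrix(0, 2, 2); C2[2, 1] <- 13.7
    expect_equal(harmonicScore(C2, d2, scaleFactor(C2)), 0)
    # N = 3, D = (1,1,1), collinear colors with C = (1,1,2):
    # fs = 3/4, SH = 2 (3/4-1)^2 + (3/2-1)^2 = 0.375
    C3 <- matrix(0, 3, 3)
    C3[2, 1] <- 1; C3[3, 1] <- 1; C3[3, 2] <- 2
    fs <- scaleFactor(C3)
    expect_equal(fs, 3 / 4)
    expect_equal(harmonicScore(C3, d, fs), 0.375)
    expect_error(harmonicScore(C2, d, 1), "dimensions")
})

test_that("contrast score is reciprocal in the mean difference", {
    C <- matrix(0, 3, 3); C[lower.tri(C)] <- 20
    expect_equal(contrastScore(C, 10), 0.5)
    expect_equal(contrastScore(C, 0), 0)
    expect_equal(contrastScore(2 * C, 10), 0.25) # doubling differences halves it
    expect_error(contrastScore(C, -1), "nonnegative")
})

test_that("total score composes the pieces and matches the worked example", {
    d <- distanceMatrix(identitySubstitutionMatrix(c("A", "B", "C")))
    # collinear colors on the L axis at 0, 1, 2 -> C = (1,1,2) euclidean
    conf <- colorConformation(c("A", "B", "C"),
                              rbind(c(10, 0, 0), c(11, 0, 0), c(12, 0, 0)))
    bd <- totalScore(conf, d, fc = 1, metric = "euclidean")
    expect_equal(bd@sHarmonic, 0.375)
    expect_equal(bd@sContrast, 1 / (4 / 3))
    expect_equal(bd@sTotal, 1.125)
    expect_equal(bd@sTotal, bd@sHarmonic + bd@sContrast)
    expect_equal(bd@scaleFactor * bd@meanDifference, 1, tolerance = 1e-12)
})

test_that("scores match a brute-force recomputation on random conformations", {
    set.seed(23)
    for (rep in 1:100) {
        N <- sample(3:4, 1)
        metric <- sample(c("euclidean", "ciede2000"), 1)
        fc <- stats::runif(1, 0, 800)
        m <- matrix(stats::rnorm(N * N), N, N); m <- m + t(m)
        diag(m) <- apply(abs(m), 1, max) + stats::runif(1, 0.5, 2)
        d <- distanceMatrix(substitutionMatrix(LETTERS[1:N], m))
        conf <- random_conformation(N)
        bd <- totalScore(conf, d, fc = fc, metric = metric)
        ora <- oracle_score(labColors(conf), distances(d), fc, metric)
        expect_equal(bd@scaleFactor, ora$fs, tolerance = 1e-10)
        expect_equal(bd@sHarmonic, ora$sh, tolerance = 1e-10)
        expect_equal(bd@sContrast, ora$sc, tolerance = 1e-10)
        expect_equal(bd@sTotal, ora$st, tolerance = 1e-10)
        expect_gte(bd@sTotal, 0)
    }
})

test_that("the harmonic score is invariant under dilation, rotation, translation", {
    set.seed(24)
    d <- distanceMatrix(identitySubstitutionMatrix(LETTERS[1:5], 3, -1))
    for (rep in 1:10) {
        lab <- matrix(stats::rnorm(15, 50, 15), 5, 3)
        lab[, 1] <- pmin(pmax(lab[, 1], 0), 100)
        conf <- colorConformation(LETTERS[1:5], lab)
        C <- differenceMatrix(conf, "euclidean")
        sh <- harmonicScore(C, d, scaleFactor(C))
        # dilation about the centroid (keep L in range)
        f <- stats::runif(1, 0.2, 0.9)
        ctr <- colMeans(lab)
        lab2 <- sweep(sweep(lab, 2, ctr), 1, rep(f, 5), "*")
        lab2 <- sweep(lab2, 2, ctr, "+")
        C2 <- differenceMatrix(colorConformation(LETTERS[1:5], lab2),
                               "euclidean")
        expect_equal(harmonicScore(C2, d, scaleFactor(C2)), sh,
                     tolerance = 1e-8)
        # rotation in the a*b* plane plus translation
        th <- stats::runif(1, 0, 2 * pi)
        R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
        lab3 <- lab
        lab3[, 2:3] <- lab[, 2:3] %*% R + 5
        C3 <- differenceMatrix(colorConformation(LETTERS[1:5], lab3),
                               "euclidean")
        expect_equal(harmonicScore(C3, d, scaleFactor(C3)), sh,
                     tolerance = 1e-8)
    }
})

test_that("degenerate conformations error in the public scoring API", {
    d <- distanceMatrix(identitySubstitutionMatrix(c("A", "B", "C")))
    same <- colorConformation(c("A", "B", "C"),
                              matrix(rep(c(60, 0, 0), each = 3), 3, 3))
    expect_error(totalScore(same, d), "degenerate")
})
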
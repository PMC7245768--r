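test_that("Lab/sRGB conversion hits the reference white and black exactly", {
    w <- labToRgb(c(100, 0, 0))
    expect_equal(unname(w[1, ]), c(1, 1, 1), tolerance = 1e-9)
    b <- labToRgb(c(0, 0, 0))
    expect_equal(unname(b[1, ]), c(0, 0, 0), tolerance = 1e-9)
    expect_equal(unname(rgbToLab(c(1, 1, 1))[1, ]), c(100, 0, 0),
                 tolerance = 1e-4)
    expect_equal(unname(rgbToLab(c(0, 0, 0))[1, ]), c(0, 0, 0),
                 tolerance = 1e-4)
})

test_that("round trips are the identity for in-gamut colors", {
    set.seed(3)
    rgb <- matrix(stats::runif(300), ncol = 3)
    lab <- rgbToLab(rgb)
    expect_true(all(inGamut(lab)))
    back <- labToRgb(lab)
    expect_equal(unname(back), unname(rgb), tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(unname(rgbToLab(back)), unname(lab), tolerance = 1e-6,
                 ignore_attr = TRUE)
})

test_that("conversion agrees with grDevices::convertColor", {
    set.seed(4)
    lab <- cbind(stats::runif(50, 10, 95), stats::runif(50, -30, 30),
                 stats::runif(50, -30, 30))
    lab <- lab[inGamut(lab), , drop = FALSE]
    mine <- labToRgb(lab)
    ref <- grDevices::convertColor(lab, from = "Lab", to = "sRGB",
                                   from.ref.white = "D65",
                                   to.ref.white = "D65")
    expect_equal(unname(mine), unname(ref), tolerance = 2e-3,
                 ignore_attr = TRUE)
})

test_that("out-of-gamut colors are signalled, not erred", {
    r <- labToRgb(c(60, -200, 0))
    expect_true(all(is.na(r[1, ])))
    expect_false(inGamut(c(60, -200, 0)))
    expect_error(labToRgb(c(60, -200, 0), outOfGamut = "error"), "gamut")
    clip <- labToRgb(c(60, -200, 0), outOfGamut = "clip")
    expect_true(all(clip >= 0 & clip <= 1))
    expect_error(rgbToLab(c(1.2, 0, 0)), "\\[0, 1\\]")
})

test_that("CIEDE2000 reproduces all 34 published reference pairs", {
    got <- ciede2000(ciede2000_reference[, 1:3], ciede2000_reference[, 4:6])
    expect_equal(round(got, 4), ciede2000_reference[, 7])
})

test_that("CIEDE2000 is symmetric, zero at identity, and matches the oracle", {
    set.seed(5)
    a <- cbind(stats::runif(40, 0, 100), stats::runif(40, -90, 90),
               stats::runif(40, -90, 90))
    b <- cbind(stats::runif(40, 0, 100), stats::runif(40, -90, 90),
               stats::runif(40, -90, 90))
    expect_equal(ciede2000(a, b), ciede2000(b, a))
    expect_equal(ciede2000(a, a), rep(0, 40))
    ora <- vapply(seq_len(40),
                  function(i) oracle_ciede2000(a[i, ], b[i, ]), numeric(1))
    expect_equal(ciede2000(a, b), ora, tolerance = 1e-12)
    # both metrics vanish together and stay comparable near identity
    eps <- a + matrix(stats::runif(120, -0.01, 0.01), ncol = 3)
    expect_true(all(ciede2000(a, eps) <= 100 * euclideanLab(a, eps)))
})

test_that("Euclidean Lab distance is the plain 3-space distance", {
    expect_equal(euclideanLab(c(50, 0, 0), c(50, 3, 4)), 5)
    expect_equal(euclideanLab(c(50, 0, 0), c(60, 0, 0)), 10)
    expect_equal(euclideanLab(c(12, 3, -4), c(12, 3, -4)), 0)
})

test_that("subspace membership applies inclusive bounds and gamut", {
    s <- colorSubspace(60, 75)
    expect_true(isMember(s, c(60, 0, 0)))   # inclusive boundary
    expect_true(isMember(s, c(75, 0, 0)))
    expect_false(isMember(s, c(59.999, 0, 0)))
    cvd <- colorSubspace(50, 80, aMin = 0)
    expect_false(isMember(cvd, c(65, -5, 10)))
    expect_true(isMember(cvd, c(65, 5, 10)))
    free <- colorSubspace(0, 100, gamutRequired = FALSE)
    expect_true(isMember(free, c(50, 500, -500)))
    # gamut consistency: membership with gamut <=> conversion succeeds
    set.seed(6)
    pts <- cbind(stats::runif(100, 0, 100), stats::runif(100, -128, 128),
                 stats::runif(100, -128, 128))
    s2 <- colorSubspace(0, 100)
    expect_equal(isMember(s2, pts), inGamut(pts))
})

test_that("uniform sampling respects constraints and is reproducible", {
    s <- colorSubspace(60, 60.5)
    set.seed(7)
    x <- sampleSubspace(s, 200)
    expect_true(all(x[, 1] >= 60 & x[, 1] <= 60.5))
    expect_true(all(isMember(s, x)))
    set.seed(7)
    expect_identical(sampleSubspace(s, 200), x)
    expect_error(sampleSubspace(colorSubspace(60, 75, aMin = 500, aMax = 600),
                                maxReject = 10000L),
                 "empty")
})

test_that("sampled marginals are uniform over an unconstrained box", {
    s <- colorSubspace(20, 80, -60, 60, -60, 60, gamutRequired = FALSE)
    set.seed(8)
    x <- sampleSubspace(s, 4000)
    ks <- stats::ks.test(x[, 2], "punif", -60, 60)
    expect_gt(ks$p.value, 0.01)
    ks3 <- stats::ks.test(x[, 3], "punif", -60, 60)
    expect_gt(ks3$p.value, 0.01)
})
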
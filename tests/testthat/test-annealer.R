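test_that("schedules start at their initial values and are monotone", {
    cfg <- annealingConfig(nSteps = 10000L, beta0 = 2, tau = 1000,
                           step0 = 8, stepTau = 2500)
    s0 <- schedule(cfg, 0)
    expect_equal(s0$beta, 2)
    expect_equal(s0$step, 8)
    t <- 0:9999
    s <- schedule(cfg, t)
    expect_true(all(diff(s$beta) > 0))
    expect_true(all(diff(s$step) < 0))
    expect_equal(schedule(cfg, 1000)$beta / s0$beta, exp(1),
                 tolerance = 1e-12)
    expect_error(schedule(cfg, 10000), "range")
})

test_that("Metropolis rule always takes downhill moves and freezes uphill ones", {
    expect_true(metropolisAccept(-1, 1))
    expect_true(metropolisAccept(0, 100))
    expect_false(metropolisAccept(1, 1e6))
    expect_false(metropolisAccept(Inf, 1))
    # empirical acceptance of delta = +1 at beta = 1 is exp(-1)
    set.seed(31)
    acc <- mean(replicate(1e5, metropolisAccept(1, 1)))
    se <- sqrt(exp(-1) * (1 - exp(-1)) / 1e5)
    expect_lt(abs(acc - exp(-1)), 3 * se)
})

test_that("proposals stay inside the subspace and follow U(-step, step)", {
    s <- colorSubspace(40, 90, -60, 60, -60, 60, gamutRequired = FALSE)
    conf <- colorConformation(LETTERS[1:3],
                              rbind(c(65, 0, 0), c(60, 10, -10), c(70, -20, 20)))
    expect_equal(labColors(proposeConformation(conf, 0, s)), labColors(conf))
    set.seed(32)
    p1 <- proposeConformation(conf, 2, s)
    set.seed(32)
    p2 <- proposeConformation(conf, 2, s)
    expect_identical(labColors(p1), labColors(p2))
    # displacement statistics from an interior point
    set.seed(33)
    disp <- t(replicate(5000, labColors(proposeConformation(conf, 0.5, s))[1, ] -
                               labColors(conf)[1, ]))
    expect_true(all(abs(disp) <= 0.5))
    expect_true(all(abs(colMeans(disp)) < 0.03))
    # colors that would leave the subspace keep their previous position
    edge <- colorConformation(c("A", "B"),
                              rbind(c(40, -60, -60), c(90, 60, 60)))
    set.seed(34)
    for (i in 1:20) {
        pe <- proposeConformation(edge, 5, s)
        expect_true(all(isMember(s, labColors(pe))))
    }
})

test_that("annealing runs are reproducible and honor the best-so-far contract", {
    d <- distanceMatrix(readSubstitutionMatrix("BLOSUM62"))
    s <- colorSubspace(60, 75)
    cfg <- annealingConfig(nSteps = 2000L)
    r1 <- runAnnealer(d, s, cfg, seed = 5L)
    r2 <- runAnnealer(d, s, cfg, seed = 5L)
    expect_identical(labColors(bestConformation(r1)),
                     labColors(bestConformation(r2)))
    expect_identical(trajectory(r1), trajectory(r2))
    expect_lte(bestScore(r1), min(trajectory(r1)))
    expect_gte(worstScore(r1), max(trajectory(r1)))
    # running minimum of the trajectory is non-increasing and ends at best
    expect_equal(min(cummin(trajectory(r1))), bestScore(r1))
    # best-so-far conformation scores what the run reports
    bd <- totalScore(bestConformation(r1), d, fc = cfg@fc)
    expect_equal(bd@sTotal, bestScore(r1), tolerance = 1e-10)
    # every color of the result lies in the subspace
    expect_true(all(isMember(s, labColors(bestConformation(r1)))))
})

test_that("acceptance rate declines as the temperature anneals", {
    d <- distanceMatrix(readSubstitutionMatrix("BLOSUM62"))
    r <- runAnnealer(d, colorSubspace(60, 75), annealingConfig(), seed = 2L)
    n <- length(r@accepted)
    head5 <- mean(r@accepted[seq_len(n * 0.05)])
    tail5 <- mean(r@accepted[seq(n * 0.95, n)])
    expect_lt(tail5, head5)
})

test_that("ensembles aggregate instances exactly", {
    d <- distanceMatrix(identitySubstitutionMatrix(LETTERS[1:5], 2, 0))
    s <- colorSubspace(60, 75)
    cfg1 <- annealingConfig(nSteps = 500L, ensembleSize = 1L)
    e1 <- runEnsemble(d, s, cfg1, seed = 9L)
    r1 <- runAnnealer(d, s, cfg1, seed = 9L)
    expect_equal(bestScore(e1), bestScore(r1))
    expect_equal(e1@meanTrajectory, trajectory(r1))

    cfg4 <- annealingConfig(nSteps = 500L, ensembleSize = 4L)
    e4 <- runEnsemble(d, s, cfg4, seed = 9L)
    bests <- vapply(e4@instances, bestScore, numeric(1))
    expect_equal(bestScore(e4), min(bests))
    expect_equal(worstScore(e4),
                 max(vapply(e4@instances, worstScore, numeric(1))))
    expect_true(all(e4@sdTrajectory >= 0))
    expect_length(e4@instances, 4L)
    # deterministic as a whole given the master seed
    e4b <- runEnsemble(d, s, cfg4, seed = 9L)
    expect_identical(labColors(bestConformation(e4)),
                     labColors(bestConformation(e4b)))
})

test_that("the annealer recovers the known optimum of the equidistant problem", {
    d <- distanceMatrix(identitySubstitutionMatrix(c("A", "B", "C")))
    box <- colorSubspace(0, 100, -128, 128, -128, 128, gamutRequired = FALSE)
    cfg <- annealingConfig(nSteps = 20000L, fc = 0, metric = "euclidean",
                           ensembleSize = 1L)
    sc <- vapply(1:10, function(s) bestScore(runAnnealer(d, box, cfg, s)),
                 numeric(1))
    expect_gte(sum(sc < 1e-3), 9)
})

test_that("configuration validation catches bad settings", {
    expect_error(annealingConfig(nSteps = 0L), "nSteps")
    expect_error(annealingConfig(beta0 = -1), "beta0")
    expect_error(annealingConfig(metric = "rgb"), "arg")
    expect_error(annealingConfig(ensembleSize = 3L, seeds = c(1L, 1L, 2L)),
                 "unique")
})
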
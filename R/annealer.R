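#' Simulated-annealing configuration
#'
#' Geometric schedules are used for both the inverse temperature and the
#' step size: \code{beta(t) = beta0 * exp(t / tau)} grows while
#' \code{step(t) = step0 * exp(-t / stepTau)} shrinks, so the search
#' anneals simultaneously in temperature and in move size — the standard
#' adaptation of simulated annealing to continuous spaces.
#'
#' @param nSteps iteration budget per instance.
#' @param beta0 initial inverse temperature.
#' @param tau time constant of the temperature schedule;
#'   \code{beta(tau) = e * beta0}.
#' @param step0 initial per-component step half-width, in L*a*b* units.
#' @param stepTau time constant of the step-size decay.
#' @param fc contrast factor. The default 500 puts the contrast score on
#'   the same order of magnitude as the harmonic score for random
#'   conformations of a 20-symbol alphabet in the default subspace.
#' @param metric \code{"ciede2000"} (default) or \code{"euclidean"}.
#' @param ensembleSize number of independent instances.
#' @param seeds integer vector of unique per-instance seeds; defaults to
#'   \code{seed + 0:(ensembleSize-1)} when built via [runEnsemble()]'s
#'   \code{seed} argument, or \code{1:ensembleSize} here.
#' @param globalMoves perturb all N colors each step (default) or a single
#'   randomly chosen color per step.
#' @return an [AnnealingConfig-class].
#' @examples
#' annealingConfig(nSteps = 1000L, ensembleSize = 2L)
#' @export
annealingConfig <- function(nSteps = 20000L, beta0 = 1, tau = nSteps / 4,
                            step0 = 10, stepTau = nSteps / 2, fc = 500,
                            metric = "ciede2000", ensembleSize = 8L,
                            seeds = NULL, globalMoves = TRUE) {
    nSteps <- as.integer(nSteps)
    ensembleSize <- as.integer(ensembleSize)
    if (is.null(seeds)) seeds <- seq_len(ensembleSize)
    metric <- match.arg(metric, c("ciede2000", "euclidean"))
    new("AnnealingConfig", nSteps = nSteps, beta0 = beta0, tau = tau,
        step0 = step0, stepTau = stepTau, fc = fc, metric = metric,
        ensembleSize = ensembleSize, seeds = as.integer(seeds),
        globalMoves = globalMoves)
}

#' Annealing schedule at a given step
#'
#' @param config an [AnnealingConfig-class].
#' @param t step index (0-based), \code{0 <= t < nSteps}; vectorized.
#' @return list with components \code{beta} (inverse temperature,
#'   increasing in t) and \code{step} (move half-width, decreasing in t).
#' @export
schedule <- function(config, t) {
    stopifnot(is(config, "AnnealingConfig"))
    if (any(t < 0) || any(t >= config@nSteps))
        stop("step index out of range")
    list(beta = config@beta0 * exp(t / config@tau),
         step = config@step0 * exp(-t / config@stepTau))
}

#' Metropolis acceptance rule
#'
#' Downhill moves (\code{deltaScore <= 0}) are always accepted; uphill
#' moves are accepted with probability \code{exp(-beta * deltaScore)}.
#' Uses R's RNG.
#'
#' @param deltaScore proposed score minus current score.
#' @param beta positive inverse temperature.
#' @return logical.
#' @export
metropolisAccept <- function(deltaScore, beta) {
    if (deltaScore <= 0) return(TRUE)
    if (!is.finite(deltaScore)) return(FALSE)
    stats::runif(1) < exp(-beta * deltaScore)
}

#' Propose a perturbed conformation
#'
#' Each color receives an independent uniform perturbation in
#' \code{[-step, step]} per component; a color whose perturbed position
#' leaves the subspace keeps its previous position (per-color rejection),
#' so the result is always fully within the subspace. Uses R's RNG.
#'
#' @param current a [ColorConformation-class] fully inside \code{subspace}.
#' @param step nonnegative step half-width.
#' @param subspace the active [ColorSubspace-class].
#' @return a [ColorConformation-class].
#' @export
proposeConformation <- function(current, step, subspace) {
    stopifnot(is(current, "ColorConformation"), step >= 0)
    lab <- current@colors
    N <- nrow(lab)
    pert <- matrix(stats::runif(3 * N, -step, step), N, 3, byrow = TRUE)
    cand <- lab + pert
    ok <- isMember(subspace, cand)
    cand[!ok, ] <- lab[!ok, ]
    colorConformation(current@alphabet, cand)
}

#' Run one simulated-annealing instance
#'
#' Initializes each symbol's color uniformly in the subspace, then
#' iterates propose / score / Metropolis-accept for \code{nSteps} steps
#' under the geometric schedules of \code{config}, tracking the
#' best-so-far conformation, the worst score visited and the per-step
#' score trajectory. Fully reproducible given \code{seed}. Degenerate
#' all-identical-color states score \code{+Inf} inside the loop so the
#' sampler can move away from them.
#'
#' @param d a [DistanceMatrix-class].
#' @param subspace a non-empty [ColorSubspace-class].
#' @param config an [AnnealingConfig-class].
#' @param seed integer RNG seed for this instance.
#' @return an [SAResult-class].
#' @examples
#' d <- distanceMatrix(identitySubstitutionMatrix(LETTERS[1:4]))
#' res <- runAnnealer(d, colorSubspace(60, 75),
#'                    annealingConfig(nSteps = 500L), seed = 1L)
#' bestScore(res)
#' @export
runAnnealer <- function(d, subspace, config, seed = 1L) {
    stopifnot(is(d, "DistanceMatrix"), is(subspace, "ColorSubspace"),
              is(config, "AnnealingConfig"))
    N <- length(d@alphabet)
    set.seed(as.integer(seed))
    res <- cpp_run_sa(.pairVector(d@values), N, .subspaceBounds(subspace),
                      subspace@gamutRequired, config@nSteps, config@beta0,
                      config@tau, config@step0, config@stepTau, config@fc,
                      .metricCode(config@metric), config@globalMoves, 100000L)
    new("SAResult",
        bestConformation = colorConformation(d@alphabet, res$best),
        bestScore = res$best_score, worstScore = res$worst_score,
        trajectory = as.numeric(res$trajectory),
        accepted = as.logical(res$accepted), seed = as.integer(seed))
}

#' Run an ensemble of independent annealing instances
#'
#' Runs \code{ensembleSize} instances with distinct seeds and aggregates
#' them: the ensemble optimum is the minimum of the per-instance
#' best-so-far scores, the ensemble worst is the maximum of the worst
#' scores seen, and the per-step ensemble mean and standard deviation of
#' the score trajectories are stored for diagnostics (see [zScore()]).
#'
#' @param d a [DistanceMatrix-class].
#' @param subspace a [ColorSubspace-class].
#' @param config an [AnnealingConfig-class]; its \code{seeds} slot gives
#'   one seed per instance unless \code{seed} is supplied.
#' @param seed optional master seed: instance i uses \code{seed + i - 1}.
#' @return an [EnsembleResult-class].
#' @export
runEnsemble <- function(d, subspace, config = annealingConfig(), seed = NULL) {
    stopifnot(is(config, "AnnealingConfig"))
    seeds <- if (is.null(seed)) config@seeds
             else as.integer(seed) + seq_len(config@ensembleSize) - 1L
    if (anyDuplicated(seeds))
        warning("duplicate seeds across ensemble instances; instances will coincide")
    instances <- lapply(seeds, function(s) runAnnealer(d, subspace, config, s))
    bests <- vapply(instances, function(x) x@bestScore, numeric(1))
    worsts <- vapply(instances, function(x) x@worstScore, numeric(1))
    traj <- vapply(instances, function(x) x@trajectory,
                   numeric(config@nSteps))
    traj <- matrix(traj, nrow = config@nSteps)
    mt <- rowMeans(traj)
    st <- if (ncol(traj) > 1) apply(traj, 1, stats::sd) else rep(0, nrow(traj))
    ibest <- which.min(bests)
    new("EnsembleResult", instances = instances,
        bestConformation = instances[[ibest]]@bestConformation,
        bestScore = bests[ibest], worstScore = max(worsts),
        meanTrajectory = mt, sdTrajectory = st)
}

#' @rdname accessors
#' @export
setMethod("bestScore", "SAResult", function(x) x@bestScore)
#' @rdname accessors
#' @export
setMethod("bestScore", "EnsembleResult", function(x) x@bestScore)
#' @rdname accessors
#' @export
setMethod("bestConformation", "SAResult", function(x) x@bestConformation)
#' @rdname accessors
#' @export
setMethod("bestConformation", "EnsembleResult", function(x) x@bestConformation)
#' @rdname accessors
#' @export
setMethod("worstScore", "SAResult", function(x) x@worstScore)
#' @rdname accessors
#' @export
setMethod("worstScore", "EnsembleResult", function(x) x@worstScore)
#' @rdname accessors
#' @export
setMethod("trajectory", "SAResult", function(x) x@trajectory)

setMethod("show", "SAResult", function(object) {
    cat("SAResult (seed", object@seed, "):",
        length(object@trajectory), "steps\n")
    cat("  best score:", format(object@bestScore),
        " worst seen:", format(object@worstScore), "\n")
})

setMethod("show", "EnsembleResult", function(object) {
    cat("EnsembleResult:", length(object@instances), "instances,",
        length(object@meanTrajectory), "steps each\n")
    cat("  ensemble best:", format(object@bestScore),
        " ensemble worst:", format(object@worstScore), "\n")
})
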
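#' Random-sampling baseline
#'
#' Draws \code{nSamples} independent color conformations uniformly from
#' the subspace (one sample per optimizer iteration, so baseline "time"
#' aligns with annealer "time"), scores each, and records the running
#' prefix mean and standard deviation — the statistics of the sampling
#' distribution "seen so far" after t samples, against which the steered
#' annealer is compared.
#'
#' @param d a [DistanceMatrix-class].
#' @param subspace a [ColorSubspace-class].
#' @param nSamples number of independent samples (>= 2).
#' @param fc contrast factor (must match the annealer's for comparison).
#' @param metric difference metric.
#' @param seed RNG seed.
#' @return a [BaselineTrace-class]. The running standard deviation uses
#'   the unbiased (n-1) estimator and is \code{NA} at t = 1.
#' @export
randomBaseline <- function(d, subspace, nSamples, fc = 500,
                           metric = "ciede2000", seed = 1L) {
    stopifnot(is(d, "DistanceMatrix"), is(subspace, "ColorSubspace"),
              nSamples >= 2)
    N <- length(d@alphabet)
    set.seed(as.integer(seed))
    sc <- cpp_random_baseline(.pairVector(d@values), N,
                              .subspaceBounds(subspace),
                              subspace@gamutRequired, as.integer(nSamples),
                              fc, .metricCode(metric), 100000L)
    t <- seq_along(sc)
    mu <- cumsum(sc) / t
    # prefix variance with n-1 denominator; guard tiny negative round-off
    ss <- cumsum(sc^2) - t * mu^2
    sd <- sqrt(pmax(ss, 0) / (t - 1))
    sd[1] <- NA_real_
    new("BaselineTrace", scores = as.numeric(sc), runningMean = mu,
        runningSd = sd, seed = as.integer(seed))
}

#' Z-score of the annealer ensemble against random sampling
#'
#' \code{Z(t) = -(meanSA(t) - mu(t)) / sigma(t)}: the number of baseline
#' standard deviations by which the ensemble mean score at step t beats
#' the running mean of pure random sampling. The sign is flipped because
#' lower scores are better, so Z is positive when the annealer
#' outperforms random sampling.
#'
#' @param ensembleMean numeric vector: per-step ensemble mean score
#'   (\code{meanTrajectory} of an [EnsembleResult-class]).
#' @param baseline a [BaselineTrace-class] aligned step-for-step with the
#'   annealer trajectory.
#' @return numeric vector of Z values; \code{NA} where the baseline
#'   standard deviation is undefined (t = 1). A zero standard deviation
#'   at any later step is an error.
#' @export
zScore <- function(ensembleMean, baseline) {
    stopifnot(is(baseline, "BaselineTrace"))
    n <- length(ensembleMean)
    if (length(baseline@scores) < n)
        stop("baseline trace is shorter than the ensemble trajectory")
    mu <- baseline@runningMean[seq_len(n)]
    sigma <- baseline@runningSd[seq_len(n)]
    if (any(sigma[-1] == 0, na.rm = TRUE))
        stop("baseline standard deviation is zero; Z is undefined")
    -(ensembleMean - mu) / sigma
}

#' Logarithmically strided step indices
#'
#' Convenience for compact diagnostic traces: approximately
#' \code{length.out} unique step indices spaced evenly on a log scale
#' from 1 to \code{nSteps}.
#'
#' @param nSteps total number of steps.
#' @param length.out target number of indices.
#' @return integer vector of unique, sorted 1-based indices.
#' @export
logStride <- function(nSteps, length.out = 200L) {
    unique(round(exp(seq(0, log(nSteps), length.out = length.out))))
}

#' @rdname accessors
#' @export
setMethod("trajectory", "BaselineTrace", function(x) x@scores)

setMethod("show", "BaselineTrace", function(object) {
    n <- length(object@scores)
    cat("BaselineTrace:", n, "random samples (seed", object@seed, ")\n")
    cat("  final mean:", format(object@runningMean[n]),
        " final sd:", format(object@runningSd[n]), "\n")
})
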
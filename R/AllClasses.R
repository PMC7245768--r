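#' @import methods
NULL

.validAlphabet <- function(alphabet) {
    if (length(alphabet) < 2)
        return("alphabet must contain at least 2 symbols")
    if (anyDuplicated(alphabet))
        return("alphabet contains duplicate symbols")
    if (any(is.na(alphabet)) || any(!nzchar(alphabet)))
        return("alphabet symbols must be non-empty strings")
    TRUE
}

#' SubstitutionMatrix class
#'
#' Holds an alphabet of N symbols together with an N x N table of
#' substitution scores, where \code{scores[i, j]} is the score of
#' substituting symbol i by symbol j. The \code{diagonalDominant} flag
#' records whether every diagonal entry is the maximum of its row and
#' column, a property expected (but not required) of well-formed
#' substitution matrices.
#'
#' @slot alphabet character vector of unique symbols, in matrix order.
#' @slot scores numeric N x N matrix of substitution scores.
#' @slot diagonalDominant logical flag set at construction.
#'
#' @seealso [readSubstitutionMatrix()], [identitySubstitutionMatrix()],
#'   [distanceMatrix()]
#' @export
setClass("SubstitutionMatrix",
    representation(alphabet = "character", scores = "matrix",
                   diagonalDominant = "logical"),
    validity = function(object) {
        msg <- .validAlphabet(object@alphabet)
        if (!isTRUE(msg)) return(msg)
        N <- length(object@alphabet)
        if (!is.numeric(object@scores) || any(dim(object@scores) != c(N, N)))
            return("scores must be a numeric N x N matrix matching the alphabet")
        if (anyNA(object@scores))
            return("scores must not contain missing values")
        TRUE
    })

#' DistanceMatrix class
#'
#' Pairwise symbol distances derived from a substitution matrix. Only the
#' strict lower triangle is meaningful (distances are commutative); the
#' diagonal and upper triangle are structurally zero. Entries are
#' normalized so that their mean over the n = N(N-1)/2 stored pairs is 1.
#'
#' @slot alphabet character vector of symbols.
#' @slot values numeric N x N matrix; strict lower triangle holds the
#'   normalized distances, all other entries are 0.
#'
#' @seealso [distanceMatrix()]
#' @export
setClass("DistanceMatrix",
    representation(alphabet = "character", values = "matrix"),
    validity = function(object) {
        msg <- .validAlphabet(object@alphabet)
        if (!isTRUE(msg)) return(msg)
        N <- length(object@alphabet)
        v <- object@values
        if (!is.numeric(v) || any(dim(v) != c(N, N)))
            return("values must be a numeric N x N matrix matching the alphabet")
        if (any(v[upper.tri(v, diag = TRUE)] != 0))
            return("diagonal and upper triangle must be identically zero")
        m <- mean(v[lower.tri(v)])
        if (abs(m - 1) > 1e-6)
            return("lower-triangle entries must be normalized to mean 1")
        TRUE
    })

#' ColorSubspace class
#'
#' A rectangular region of CIE L*a*b* space within which colors may be
#' placed: a lightness interval plus optional a*/b* bounds (default
#' unbounded), optionally intersected with the set of sRGB-displayable
#' colors. All bounds are inclusive. Membership is deterministic and pure.
#'
#' @slot lMin,lMax lightness bounds in \[0, 100\].
#' @slot aMin,aMax green-red bounds (may be infinite).
#' @slot bMin,bMax blue-yellow bounds (may be infinite).
#' @slot gamutRequired if \code{TRUE}, membership additionally requires
#'   that the color converts to sRGB without clipping.
#'
#' @seealso [colorSubspace()], [isMember()], [sampleSubspace()]
#' @export
setClass("ColorSubspace",
    representation(lMin = "numeric", lMax = "numeric",
                   aMin = "numeric", aMax = "numeric",
                   bMin = "numeric", bMax = "numeric",
                   gamutRequired = "logical"),
    validity = function(object) {
        b <- c(object@lMin, object@lMax, object@aMin, object@aMax,
               object@bMin, object@bMax)
        if (length(b) != 6 || any(is.na(b)))
            return("all six bounds must be single non-missing numbers")
        if (object@lMin >= object@lMax)
            return("lMin must be smaller than lMax")
        if (object@aMin > object@aMax || object@bMin > object@bMax)
            return("finite a*/b* bounds must be ordered")
        TRUE
    })

#' ColorConformation class
#'
#' An assignment of one L*a*b* color to each alphabet symbol: the state
#' the optimizer works on, an N x 3 matrix of (L*, a*, b*) rows.
#'
#' @slot alphabet character vector of symbols.
#' @slot colors numeric N x 3 matrix, columns L*, a*, b*.
#'
#' @seealso [colorConformation()], [totalScore()], [conformationToScheme()]
#' @export
setClass("ColorConformation",
    representation(alphabet = "character", colors = "matrix"),
    validity = function(object) {
        msg <- .validAlphabet(object@alphabet)
        if (!isTRUE(msg)) return(msg)
        N <- length(object@alphabet)
        if (!is.numeric(object@colors) || any(dim(object@colors) != c(N, 3)))
            return("colors must be a numeric N x 3 matrix matching the alphabet")
        if (anyNA(object@colors))
            return("colors must not contain missing values")
        if (any(object@colors[, 1] < 0 | object@colors[, 1] > 100))
            return("lightness values must lie in [0, 100]")
        TRUE
    })

#' ScoreBreakdown class
#'
#' The components of the total score of a color conformation against a
#' distance matrix: the harmonic term, the contrast term, their sum, the
#' dynamic scale factor and the mean pairwise color difference.
#'
#' @slot sHarmonic harmonic (spring) score.
#' @slot sContrast contrast score.
#' @slot sTotal total score, exactly \code{sHarmonic + sContrast}.
#' @slot scaleFactor scale factor relating color differences to distances.
#' @slot meanDifference mean pairwise perceptual difference.
#'
#' @seealso [totalScore()]
#' @export
setClass("ScoreBreakdown",
    representation(sHarmonic = "numeric", sContrast = "numeric",
                   sTotal = "numeric", scaleFactor = "numeric",
                   meanDifference = "numeric"))

#' AnnealingConfig class
#'
#' Settings for a simulated-annealing run: iteration budget, geometric
#' temperature and step-size schedules, contrast factor, difference
#' metric and ensemble layout.
#'
#' @slot nSteps iteration budget per instance.
#' @slot beta0 initial inverse temperature.
#' @slot tau time constant of the inverse-temperature growth.
#' @slot step0 initial per-component step half-width (L*a*b* units).
#' @slot stepTau time constant of the step-size decay.
#' @slot fc contrast factor weighting the contrast score.
#' @slot metric \code{"ciede2000"} or \code{"euclidean"}.
#' @slot ensembleSize number of independent instances.
#' @slot seeds integer vector of per-instance RNG seeds.
#' @slot globalMoves if \code{TRUE} (default) all N colors are perturbed
#'   each step; otherwise a single randomly chosen color is moved.
#'
#' @seealso [annealingConfig()], [runAnnealer()], [runEnsemble()]
#' @export
setClass("AnnealingConfig",
    representation(nSteps = "integer", beta0 = "numeric", tau = "numeric",
                   step0 = "numeric", stepTau = "numeric", fc = "numeric",
                   metric = "character", ensembleSize = "integer",
                   seeds = "integer", globalMoves = "logical"),
    validity = function(object) {
        if (object@nSteps < 1L) return("nSteps must be at least 1")
        if (object@beta0 <= 0) return("beta0 must be positive")
        if (object@tau <= 0) return("tau must be positive")
        if (object@step0 <= 0) return("step0 must be positive")
        if (object@stepTau <= 0) return("stepTau must be positive")
        if (object@fc < 0) return("fc must be nonnegative")
        if (!object@metric %in% c("ciede2000", "euclidean"))
            return("metric must be 'ciede2000' or 'euclidean'")
        if (object@ensembleSize < 1L) return("ensembleSize must be at least 1")
        if (length(object@seeds) != object@ensembleSize)
            return("seeds must supply one seed per ensemble instance")
        if (anyDuplicated(object@seeds))
            return("seeds must be unique")
        TRUE
    })

#' SAResult class
#'
#' Outcome of a single simulated-annealing instance: the best-so-far
#' conformation and score, the worst score visited, and the per-step
#' trajectory of current-state scores.
#'
#' @slot bestConformation best-so-far [ColorConformation-class].
#' @slot bestScore best-so-far total score.
#' @slot worstScore worst current-state score seen during the run.
#' @slot trajectory numeric vector of current-state scores, one per step.
#' @slot accepted logical vector, one per step: proposal accepted?
#' @slot seed the RNG seed of this instance.
#'
#' @seealso [runAnnealer()]
#' @export
setClass("SAResult",
    representation(bestConformation = "ColorConformation",
                   bestScore = "numeric", worstScore = "numeric",
                   trajectory = "numeric", accepted = "logical",
                   seed = "integer"),
    validity = function(object) {
        if (length(object@trajectory) &&
            object@bestScore > min(object@trajectory) + 1e-12)
            return("bestScore must not exceed any trajectory value")
        TRUE
    })

#' EnsembleResult class
#'
#' Aggregate of independent simulated-annealing instances: the ensemble
#' optimum (minimum of the per-instance best-so-far scores), the ensemble
#' worst, and the per-step mean and standard deviation of the instance
#' score trajectories.
#'
#' @slot instances list of [SAResult-class] objects.
#' @slot bestConformation conformation attaining the ensemble best score.
#' @slot bestScore minimum of the instance best scores.
#' @slot worstScore maximum of the instance worst scores.
#' @slot meanTrajectory per-step ensemble mean of current-state scores.
#' @slot sdTrajectory per-step ensemble standard deviation.
#'
#' @seealso [runEnsemble()]
#' @export
setClass("EnsembleResult",
    representation(instances = "list", bestConformation = "ColorConformation",
                   bestScore = "numeric", worstScore = "numeric",
                   meanTrajectory = "numeric", sdTrajectory = "numeric"))

#' BaselineTrace class
#'
#' Scores of independent uniformly sampled conformations, with running
#' prefix mean and standard deviation (the statistics "seen so far" after
#' t samples). The standard deviation uses the unbiased n-1 denominator
#' and is \code{NA} at t = 1.
#'
#' @slot scores per-sample total scores.
#' @slot runningMean prefix means.
#' @slot runningSd prefix standard deviations.
#' @slot seed RNG seed used to generate the trace.
#'
#' @seealso [randomBaseline()], [zScore()]
#' @export
setClass("BaselineTrace",
    representation(scores = "numeric", runningMean = "numeric",
                   runningSd = "numeric", seed = "integer"))

#' ColorScheme class
#'
#' A named map from alphabet symbols to sRGB hex colors, ready for
#' serialization and use by alignment-visualization software.
#'
#' @slot name free-text scheme name.
#' @slot alphabet character vector of symbols, in order.
#' @slot colors named character vector of lowercase "#rrggbb" strings,
#'   one per symbol.
#'
#' @seealso [conformationToScheme()], [writeSchemeJson()]
#' @export
setClass("ColorScheme",
    representation(name = "character", alphabet = "character",
                   colors = "character"),
    validity = function(object) {
        msg <- .validAlphabet(object@alphabet)
        if (!isTRUE(msg)) return(msg)
        if (!identical(sort(names(object@colors)), sort(object@alphabet)))
            return("colors must have exactly one entry per alphabet symbol")
        if (any(!grepl("^#[0-9a-f]{6}$", object@colors)))
            return("colors must be lowercase '#rrggbb' hex strings")
        TRUE
    })
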
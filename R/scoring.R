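#' Pairwise perceptual difference matrix of a conformation
#'
#' @param conformation a [ColorConformation-class].
#' @param metric \code{"ciede2000"} (default) or \code{"euclidean"}.
#' @return N x N numeric matrix whose strict lower triangle holds the
#'   pairwise color differences \code{C[i, j] = metric(color_i, color_j)}
#'   for j < i; diagonal and upper triangle are zero.
#' @export
differenceMatrix <- function(conformation, metric = "ciede2000") {
    stopifnot(is(conformation, "ColorConformation"))
    code <- .metricCode(metric)
    lab <- conformation@colors
    N <- nrow(lab)
    cmat <- matrix(0, N, N, dimnames = list(conformation@alphabet,
                                            conformation@alphabet))
    cmat[lower.tri(cmat)] <- cpp_pairwise_diff(lab, code)
    cmat
}

.triMean <- function(m) mean(m[lower.tri(m)])

#' Scale factor relating color differences to target distances
#'
#' The ratio of the mean target distance (1 by construction) to the mean
#' pairwise color difference: \code{n / sum(C)} over the n = N(N-1)/2
#' stored pairs. It changes dynamically with the conformation.
#'
#' @param c difference matrix as returned by [differenceMatrix()].
#' @return positive scalar with \code{scaleFactor(c) * mean(C) == 1}.
#' @export
scaleFactor <- function(c) {
    avg <- .triMean(c)
    if (avg <= 0)
        stop("degenerate conformation: all pairwise color differences are zero")
    1 / avg
}

#' Harmonic (spring) score
#'
#' Sum of squared deviations between scaled color differences and target
#' distances, \code{sum((fs * C - D)^2)} over the strict lower triangle:
#' a system of springs whose equilibrium lengths are the entries of the
#' distance matrix. Invariant under uniform dilation of all color
#' differences, since the scale factor cancels the scale.
#'
#' @param c difference matrix ([differenceMatrix()]).
#' @param d a [DistanceMatrix-class] or a matching N x N numeric matrix.
#' @param fs the scale factor ([scaleFactor()]).
#' @return nonnegative scalar.
#' @export
harmonicScore <- function(c, d, fs) {
    dv <- if (is(d, "DistanceMatrix")) d@values else as.matrix(d)
    if (!all(dim(c) == dim(dv)))
        stop("difference and distance matrices have mismatched dimensions")
    sum((fs * c[lower.tri(c)] - dv[lower.tri(dv)])^2)
}

#' Contrast score
#'
#' \code{fc / mean(C)}: a reciprocal penalty on the mean pairwise color
#' difference that favors widely spread (high-contrast) schemes, weighted
#' by the user-supplied contrast factor.
#'
#' @param c difference matrix ([differenceMatrix()]).
#' @param fc nonnegative contrast factor.
#' @return nonnegative scalar.
#' @export
contrastScore <- function(c, fc) {
    if (fc < 0) stop("'fc' must be nonnegative")
    avg <- .triMean(c)
    if (avg <= 0)
        stop("degenerate conformation: all pairwise color differences are zero")
    fc / avg
}

#' Total score of a color conformation
#'
#' The sum of the harmonic score and the contrast score. The harmonic
#' term pulls scaled pairwise color differences towards the matrix-derived
#' distances; the contrast term rewards overall spread.
#'
#' @param conformation a [ColorConformation-class].
#' @param d a [DistanceMatrix-class] over the same alphabet size.
#' @param fc contrast factor (default 500; see [annealingConfig()]).
#' @param metric \code{"ciede2000"} or \code{"euclidean"}.
#' @return a [ScoreBreakdown-class] with components \code{sHarmonic},
#'   \code{sContrast}, \code{sTotal}, \code{scaleFactor} and
#'   \code{meanDifference}.
#' @examples
#' d <- distanceMatrix(identitySubstitutionMatrix(LETTERS[1:3]))
#' conf <- colorConformation(LETTERS[1:3], sampleSubspace(colorSubspace(60, 75), 3))
#' totalScore(conf, d)
#' @export
totalScore <- function(conformation, d, fc = 500, metric = "ciede2000") {
    stopifnot(is(d, "DistanceMatrix"))
    if (length(conformation@alphabet) != length(d@alphabet))
        stop("conformation and distance matrix have different alphabet sizes")
    cmat <- differenceMatrix(conformation, metric)
    fs <- scaleFactor(cmat)
    sh <- harmonicScore(cmat, d, fs)
    sc <- contrastScore(cmat, fc)
    new("ScoreBreakdown", sHarmonic = sh, sContrast = sc, sTotal = sh + sc,
        scaleFactor = fs, meanDifference = .triMean(cmat))
}

setMethod("show", "ScoreBreakdown", function(object) {
    cat("ScoreBreakdown\n")
    cat("  harmonic: ", format(object@sHarmonic), "\n")
    cat("  contrast: ", format(object@sContrast), "\n")
    cat("  total:    ", format(object@sTotal), "\n")
    cat("  scale factor:", format(object@scaleFactor),
        " mean difference:", format(object@meanDifference), "\n")
})
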
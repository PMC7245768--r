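.asLabMatrix <- function(color) {
    if (is.null(dim(color))) {
        if (length(color) != 3)
            stop("a single color must be a length-3 (L, a, b) vector")
        color <- matrix(color, 1, 3)
    }
    color <- as.matrix(color)
    if (ncol(color) != 3)
        stop("colors must be given as an N x 3 matrix with columns L*, a*, b*")
    storage.mode(color) <- "double"
    color
}

#' Convert L*a*b* colors to sRGB
#'
#' Standard CIE L*a*b* (D65 white, 2 degree observer) -> XYZ -> linear
#' RGB -> sRGB gamma encoding. Colors whose pre-clamping linear channels
#' fall outside \[0, 1\] (beyond a 1e-9 tolerance) are not displayable;
#' they are signalled rather than treated as an error.
#'
#' @param color length-3 L*a*b* vector or N x 3 matrix.
#' @param outOfGamut how to signal non-displayable colors: \code{"na"}
#'   (default) returns NA rows, \code{"clip"} returns the channel-clamped
#'   color, \code{"error"} stops.
#' @return N x 3 matrix of sRGB components in \[0, 1\], with an
#'   \code{"inGamut"} logical attribute.
#' @examples
#' labToRgb(c(100, 0, 0))   # white
#' labToRgb(c(60, -200, 0)) # far outside the displayable gamut -> NA
#' @export
labToRgb <- function(color, outOfGamut = c("na", "clip", "error")) {
    outOfGamut <- match.arg(outOfGamut)
    lab <- .asLabMatrix(color)
    res <- cpp_lab_to_rgb(lab)
    rgb <- res$rgb
    ok <- res$in_gamut
    if (!all(ok)) {
        if (outOfGamut == "error")
            stop(sum(!ok), " color(s) fall outside the sRGB gamut")
        if (outOfGamut == "na")
            rgb[!ok, ] <- NA_real_
    }
    colnames(rgb) <- c("r", "g", "b")
    attr(rgb, "inGamut") <- ok
    rgb
}

#' Is an L*a*b* color displayable in sRGB?
#'
#' @param color length-3 vector or N x 3 matrix of L*a*b* colors.
#' @return logical vector.
#' @export
inGamut <- function(color) {
    as.logical(cpp_lab_to_rgb(.asLabMatrix(color))$in_gamut)
}

#' Convert sRGB colors to L*a*b*
#'
#' Inverse of [labToRgb()]; the round trip is the identity (to well below
#' 1e-6) for in-gamut colors.
#'
#' @param color length-3 sRGB vector or N x 3 matrix, components in \[0, 1\].
#' @return N x 3 matrix of L*a*b* components.
#' @export
rgbToLab <- function(color) {
    rgb <- .asLabMatrix(color) # same shape checks apply
    if (any(rgb < 0) || any(rgb > 1))
        stop("sRGB components must lie in [0, 1]")
    lab <- cpp_rgb_to_lab(rgb)
    colnames(lab) <- c("L", "a", "b")
    lab
}

#' CIEDE2000 perceptual color difference
#'
#' The full CIEDE2000 formula with standard parametric factors
#' kL = kC = kH = 1. Symmetric, nonnegative, and zero exactly for
#' identical colors.
#'
#' @param color1,color2 length-3 L*a*b* vectors or N x 3 matrices
#'   (compared row by row; a single color recycles).
#' @return numeric vector of differences.
#' @examples
#' ciede2000(c(50, 2.5, 0), c(50, 0, -2.5))
#' @export
ciede2000 <- function(color1, color2) {
    .pairMetric(color1, color2, 0L)
}

#' Euclidean L*a*b* color difference
#'
#' The plain Euclidean distance in L*a*b* coordinates, a fast
#' approximation to the perceptual difference.
#'
#' @inheritParams ciede2000
#' @return numeric vector of differences.
#' @examples
#' euclideanLab(c(50, 0, 0), c(50, 3, 4)) # 5
#' @export
euclideanLab <- function(color1, color2) {
    .pairMetric(color1, color2, 1L)
}

.pairMetric <- function(color1, color2, code) {
    m1 <- .asLabMatrix(color1)
    m2 <- .asLabMatrix(color2)
    if (nrow(m1) == 1 && nrow(m2) > 1) m1 <- m1[rep(1, nrow(m2)), , drop = FALSE]
    if (nrow(m2) == 1 && nrow(m1) > 1) m2 <- m2[rep(1, nrow(m1)), , drop = FALSE]
    if (nrow(m1) != nrow(m2))
        stop("color1 and color2 must have the same number of rows")
    cpp_color_diff(m1, m2, code)
}

.metricCode <- function(metric) {
    metric <- match.arg(metric, c("ciede2000", "euclidean"))
    if (metric == "ciede2000") 0L else 1L
}

#' Define a constrained L*a*b* color subspace
#'
#' @param lMin,lMax inclusive lightness bounds.
#' @param aMin,aMax,bMin,bMax inclusive a*/b* bounds; default unbounded.
#' @param gamutRequired require sRGB displayability (default \code{TRUE}).
#' @return a [ColorSubspace-class].
#' @examples
#' colorSubspace(60, 75)                 # default scheme-generation region
#' colorSubspace(50, 80, aMin = 0)       # red-green CVD friendly: a* >= 0
#' @export
colorSubspace <- function(lMin = 0, lMax = 100, aMin = -Inf, aMax = Inf,
                          bMin = -Inf, bMax = Inf, gamutRequired = TRUE) {
    new("ColorSubspace", lMin = as.numeric(lMin), lMax = as.numeric(lMax),
        aMin = as.numeric(aMin), aMax = as.numeric(aMax),
        bMin = as.numeric(bMin), bMax = as.numeric(bMax),
        gamutRequired = gamutRequired)
}

.subspaceBounds <- function(s) {
    c(s@lMin, s@lMax, s@aMin, s@aMax, s@bMin, s@bMax)
}

#' @describeIn isMember A color is a member iff it satisfies all finite
#'   bounds (inclusive) and, if required, converts to sRGB without
#'   clipping.
#' @export
setMethod("isMember", signature("ColorSubspace", "ANY"), function(subspace, color) {
    lab <- .asLabMatrix(color)
    as.logical(cpp_in_subspace(lab, .subspaceBounds(subspace),
                               subspace@gamutRequired))
})

#' Sample colors uniformly from a subspace
#'
#' Rejection sampling: L*, a*, b* are drawn uniformly from the bounding
#' box (the a*/b* box defaults to \[-128, 128\] where unbounded) and
#' rejected until they satisfy the subspace predicate. Uses R's RNG, so
#' results are reproducible under \code{set.seed()}.
#'
#' @param subspace a [ColorSubspace-class] with nonzero displayable volume.
#' @param n number of colors to draw.
#' @param maxReject rejection budget per draw before the subspace is
#'   declared empty.
#' @return n x 3 matrix of L*a*b* colors, all members of the subspace.
#' @examples
#' set.seed(1)
#' sampleSubspace(colorSubspace(60, 75), 5)
#' @export
sampleSubspace <- function(subspace, n = 1L, maxReject = 100000L) {
    stopifnot(is(subspace, "ColorSubspace"))
    out <- cpp_sample_subspace(as.integer(n), .subspaceBounds(subspace),
                               subspace@gamutRequired, as.integer(maxReject))
    colnames(out) <- c("L", "a", "b")
    out
}

#' Construct a color conformation
#'
#' @param alphabet character vector of symbols.
#' @param colors N x 3 matrix of L*a*b* colors, one row per symbol.
#' @return a [ColorConformation-class].
#' @export
colorConformation <- function(alphabet, colors) {
    colors <- .asLabMatrix(colors)
    rownames(colors) <- alphabet
    colnames(colors) <- c("L", "a", "b")
    new("ColorConformation", alphabet = as.character(alphabet), colors = colors)
}

#' @rdname accessors
#' @export
setMethod("alphabet", "ColorConformation", function(x) x@alphabet)
#' @rdname accessors
#' @export
setMethod("labColors", "ColorConformation", function(x) x@colors)

setMethod("show", "ColorSubspace", function(object) {
    fmt <- function(lo, hi) paste0("[", lo, ", ", hi, "]")
    cat("ColorSubspace: L* in", fmt(object@lMin, object@lMax),
        " a* in", fmt(object@aMin, object@aMax),
        " b* in", fmt(object@bMin, object@bMax), "\n")
    cat("  sRGB gamut required:", object@gamutRequired, "\n")
})

setMethod("show", "ColorConformation", function(object) {
    cat("ColorConformation over", length(object@alphabet), "symbols\n")
    print(utils::head(object@colors, 6))
    if (length(object@alphabet) > 6) cat("  ...\n")
})
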
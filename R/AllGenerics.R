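#' Accessors for MatrixPalette classes
#'
#' @param x an object of one of the package classes.
#' @return \code{alphabet}: the character vector of symbols.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("alphabet", function(x) standardGeneric("alphabet"))

#' @rdname accessors
#' @return \code{scores}: the substitution score matrix.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @return \code{distances}: the full N x N distance matrix (strict lower
#'   triangle populated).
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @rdname accessors
#' @return \code{nPairs}: the number of symbol pairs N(N-1)/2.
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname accessors
#' @return \code{labColors}: the N x 3 matrix of L*a*b* colors.
#' @export
setGeneric("labColors", function(x) standardGeneric("labColors"))

#' @rdname accessors
#' @return \code{bestScore}: the best-so-far total score.
#' @export
setGeneric("bestScore", function(x) standardGeneric("bestScore"))

#' @rdname accessors
#' @return \code{bestConformation}: the best-so-far color conformation.
#' @export
setGeneric("bestConformation", function(x) standardGeneric("bestConformation"))

#' @rdname accessors
#' @return \code{worstScore}: the worst score seen.
#' @export
setGeneric("worstScore", function(x) standardGeneric("worstScore"))

#' @rdname accessors
#' @return \code{trajectory}: the per-step score trajectory.
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))

#' @rdname accessors
#' @return \code{schemeColors}: the named symbol-to-hex map.
#' @export
setGeneric("schemeColors", function(x) standardGeneric("schemeColors"))

#' Convert a substitution matrix to a normalized distance matrix
#'
#' @param x a [SubstitutionMatrix-class].
#' @param ... further arguments passed to methods.
#' @return a [DistanceMatrix-class].
#' @export
setGeneric("distanceMatrix", function(x, ...) standardGeneric("distanceMatrix"))

#' Test membership of colors in a color subspace
#'
#' @param subspace a [ColorSubspace-class].
#' @param color a length-3 L*a*b* vector or an N x 3 matrix.
#' @return logical vector, one entry per color.
#' @export
setGeneric("isMember", function(subspace, color) standardGeneric("isMember"))
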
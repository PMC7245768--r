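#' Convert a color conformation to an sRGB color scheme
#'
#' Each L*a*b* color is converted to sRGB, quantized to 8-bit channels
#' (round half away from zero) and formatted as a lowercase "#rrggbb"
#' string. Gap or unknown symbols are not part of the alphabet and
#' therefore receive no color: a gap is the absence of a symbol.
#'
#' @param conformation a [ColorConformation-class] whose colors are all
#'   in the sRGB gamut.
#' @param name scheme name stored in the output.
#' @return a [ColorScheme-class].
#' @examples
#' conf <- colorConformation(c("A", "B"), rbind(c(100, 0, 0), c(0, 0, 0)))
#' schemeColors(conformationToScheme(conf)) # white, black
#' @export
conformationToScheme <- function(conformation, name = "scheme") {
    stopifnot(is(conformation, "ColorConformation"))
    rgb <- labToRgb(conformation@colors, outOfGamut = "error")
    hex <- apply(rgb, 1, function(ch) {
        v <- as.integer(floor(ch * 255 + 0.5)) # channels >= 0
        sprintf("#%02x%02x%02x", v[1], v[2], v[3])
    })
    names(hex) <- conformation@alphabet
    new("ColorScheme", name = name, alphabet = conformation@alphabet,
        colors = hex)
}

#' @rdname accessors
#' @export
setMethod("alphabet", "ColorScheme", function(x) x@alphabet)
#' @rdname accessors
#' @export
setMethod("schemeColors", "ColorScheme", function(x) x@colors)

#' Write / read a color scheme as JSON
#'
#' The JSON object has three keys: \code{"name"}, \code{"alphabet"} (the
#' ordered list of symbols) and \code{"colors"} (a symbol-to-hex map).
#' Reading is the exact inverse of writing.
#'
#' @param scheme a [ColorScheme-class].
#' @param path destination / source file path.
#' @return \code{writeSchemeJson}: the path, invisibly.
#'   \code{readSchemeJson}: a [ColorScheme-class].
#' @export
writeSchemeJson <- function(scheme, path) {
    stopifnot(is(scheme, "ColorScheme"))
    obj <- list(name = scheme@name,
                alphabet = as.list(scheme@alphabet),
                colors = as.list(scheme@colors[scheme@alphabet]))
    json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
    writeLines(json, path)
    invisible(path)
}

#' @rdname writeSchemeJson
#' @export
readSchemeJson <- function(path) {
    obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!all(c("name", "alphabet", "colors") %in% names(obj)))
        stop("scheme JSON must contain 'name', 'alphabet' and 'colors'")
    alph <- unlist(obj$alphabet, use.names = FALSE)
    cols <- unlist(obj$colors)
    missing <- setdiff(alph, names(cols))
    if (length(missing))
        stop("scheme JSON is missing colors for: ",
             paste(missing, collapse = ", "))
    new("ColorScheme", name = obj$name, alphabet = alph,
        colors = cols[alph])
}

#' Parse "#rrggbb" hex colors to sRGB components
#'
#' @param hex character vector of "#rrggbb" strings.
#' @return N x 3 matrix of sRGB components in \[0, 1\].
#' @export
hexToRgb <- function(hex) {
    if (any(!grepl("^#[0-9a-fA-F]{6}$", hex)))
        stop("malformed hex color string")
    out <- t(vapply(hex, function(h) {
        strtoi(c(substr(h, 2, 3), substr(h, 4, 5), substr(h, 6, 7)), 16L) / 255
    }, numeric(3)))
    colnames(out) <- c("r", "g", "b")
    rownames(out) <- names(hex)
    out
}

#' Generate a color scheme from a substitution matrix
#'
#' The full pipeline: parse or accept a substitution matrix, derive the
#' normalized distance matrix, minimize the total score with an ensemble
#' of simulated-annealing instances over the constrained subspace, and
#' convert the ensemble-best conformation to an sRGB scheme.
#'
#' @param matrix a [SubstitutionMatrix-class], a bundled matrix name
#'   (\code{"BLOSUM62"}, \code{"PAM250"}) or a path to an NCBI-style
#'   matrix file.
#' @param subspace a [ColorSubspace-class]; the default restricts
#'   lightness to \[60, 75\], a span wide enough for contrast but narrow
#'   enough for legible symbol overlays.
#' @param config an [AnnealingConfig-class].
#' @param seed master seed; instance i uses \code{seed + i - 1}.
#' @param name scheme name.
#' @return list with elements \code{scheme} ([ColorScheme-class]) and
#'   \code{ensemble} ([EnsembleResult-class]).
#' @examples
#' \donttest{
#' res <- generateScheme("BLOSUM62", seed = 1L,
#'                       config = annealingConfig(nSteps = 2000L,
#'                                                ensembleSize = 2L))
#' schemeColors(res$scheme)
#' }
#' @export
generateScheme <- function(matrix = "BLOSUM62",
                           subspace = colorSubspace(60, 75),
                           config = annealingConfig(), seed = 1L,
                           name = NULL) {
    sub <- if (is(matrix, "SubstitutionMatrix")) matrix
           else readSubstitutionMatrix(matrix)
    if (is.null(name))
        name <- if (is.character(matrix)) basename(matrix) else "scheme"
    d <- distanceMatrix(sub)
    ens <- runEnsemble(d, subspace, config, seed = seed)
    list(scheme = conformationToScheme(ens@bestConformation, name = name),
         ensemble = ens)
}

setMethod("show", "ColorScheme", function(object) {
    cat("ColorScheme '", object@name, "' over ", length(object@alphabet),
        " symbols\n", sep = "")
    print(object@colors)
})
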
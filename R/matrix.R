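#' Construct a substitution matrix
#'
#' @param alphabet character vector of unique symbols (length >= 2).
#' @param scores numeric N x N matrix; \code{scores[i, j]} is the score of
#'   substituting symbol i by symbol j.
#' @return a [SubstitutionMatrix-class]. A warning is emitted if any
#'   diagonal entry is not the maximum of its row and column (a symbol
#'   would then appear more similar to another symbol than to itself), or
#'   if the matrix is asymmetric; both are accepted.
#' @examples
#' substitutionMatrix(c("A", "B"), matrix(c(4, 1, 1, 5), 2, 2))
#' @export
substitutionMatrix <- function(alphabet, scores) {
    alphabet <- as.character(alphabet)
    scores <- as.matrix(scores)
    storage.mode(scores) <- "double"
    dimnames(scores) <- list(alphabet, alphabet)
    dom <- .isDiagonalDominant(scores)
    if (!dom)
        warning("some diagonal entries are not the maximum of their ",
                "row/column; derived distances may be negative")
    if (!isSymmetric(unname(scores)))
        warning("substitution matrix is asymmetric; distances use the ",
                "average of the two directions")
    new("SubstitutionMatrix", alphabet = alphabet, scores = scores,
        diagonalDominant = dom)
}

.isDiagonalDominant <- function(m) {
    d <- diag(m)
    all(d >= apply(m, 1, max)) && all(d >= apply(m, 2, max))
}

#' Build an identity substitution matrix
#'
#' A matrix with a single match score on the diagonal and a single
#' mismatch score everywhere else. Such a matrix makes all symbol pairs
#' equidistant, so the ideal color scheme places all symbols at equal
#' perceptual distance from each other.
#'
#' @param alphabet character vector of unique symbols.
#' @param match diagonal score; must exceed \code{mismatch}.
#' @param mismatch off-diagonal score.
#' @return a [SubstitutionMatrix-class].
#' @examples
#' identitySubstitutionMatrix(LETTERS[1:3])
#' @export
identitySubstitutionMatrix <- function(alphabet, match = 1, mismatch = 0) {
    if (!is.numeric(match) || !is.numeric(mismatch) || match <= mismatch)
        stop("'match' must be strictly greater than 'mismatch'")
    N <- length(alphabet)
    m <- matrix(mismatch, N, N)
    diag(m) <- match
    substitutionMatrix(alphabet, m)
}

#' Read a substitution matrix in NCBI/BLAST table format
#'
#' Parses the whitespace-delimited matrix dialect used by BLAST and EMBOSS:
#' optional \code{#} comment lines, a header row of symbols, then one row
#' per symbol, optionally prefixed by its symbol label. A \code{*} (stop /
#' any) column, if present, is dropped with a warning.
#'
#' @param file path to a matrix file, or a name of a bundled matrix
#'   (\code{"BLOSUM62"} or \code{"PAM250"}).
#' @param text optional character scalar or vector holding the table text
#'   directly; overrides \code{file}.
#' @return a [SubstitutionMatrix-class] with the alphabet in header order.
#' @examples
#' readSubstitutionMatrix("BLOSUM62")
#' readSubstitutionMatrix(text = "  A B\nA 4 1\nB 1 5")
#' @export
readSubstitutionMatrix <- function(file = "BLOSUM62", text = NULL) {
    if (is.null(text)) {
        path <- builtinMatrixPath(file)
        lines <- readLines(path)
    } else {
        lines <- unlist(strsplit(text, "\n", fixed = TRUE))
    }
    lines <- lines[!grepl("^\\s*#", lines)]
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2)
        stop("matrix table must contain a header row and at least one data row")
    tok <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
    header <- tok[[1]]
    rows <- tok[-1]

    drop <- header == "*"
    N0 <- length(header) # header width before dropping any '*' column
    if (any(drop)) {
        warning("ignoring '*' column/row in matrix table")
        header <- header[!drop]
        rows <- Filter(function(r) r[1] != "*", rows)
    }
    N <- length(header)
    if (anyDuplicated(header))
        stop("duplicate symbol in matrix header")
    if (length(rows) != N)
        stop("expected ", N, " data rows to match header, found ", length(rows))

    labeled <- vapply(rows, function(r) length(r) == N0 + 1L, logical(1))
    unlabeled <- vapply(rows, function(r) length(r) == N0, logical(1))
    if (all(labeled)) {
        rowlabs <- vapply(rows, `[`, character(1), 1L)
        if (!identical(rowlabs, header))
            stop("row labels do not match header symbols: expected (",
                 paste(header, collapse = ", "), "), found (",
                 paste(rowlabs, collapse = ", "), ")")
        cells <- lapply(rows, function(r) {
            keep <- r[-1L]
            if (any(drop)) keep <- keep[!drop]
            keep
        })
    } else if (all(unlabeled)) {
        cells <- lapply(rows, function(r) if (any(drop)) r[!drop] else r)
    } else {
        stop("inconsistent row lengths: rows must all be labeled or all unlabeled")
    }
    m <- suppressWarnings(vapply(cells, as.numeric, numeric(N)))
    if (anyNA(m))
        stop("non-numeric cell in matrix table")
    substitutionMatrix(header, t(m))
}

#' Path to a bundled substitution matrix file
#'
#' @param name matrix name (\code{"BLOSUM62"}, \code{"PAM250"}) or a path
#'   to an existing file, returned unchanged.
#' @return file path.
#' @export
builtinMatrixPath <- function(name) {
    if (file.exists(name)) return(name)
    path <- system.file("extdata", paste0(toupper(name), ".mat"),
                        package = "MatrixPalette")
    if (!nzchar(path))
        stop("unknown matrix '", name, "': not a file and not a bundled matrix")
    path
}

#' @describeIn distanceMatrix Derive normalized pairwise distances from a
#'   substitution matrix. For each symbol pair the raw distance is the
#'   average score drop relative to self-substitution,
#'   \code{((M[i,i] - M[i,j]) + (M[j,j] - M[j,i])) / 2} for j < i; the
#'   strict lower triangle is then scaled so its mean over the
#'   n = N(N-1)/2 pairs is exactly 1, making the result invariant to the
#'   magnitude of the substitution scores.
#' @export
setMethod("distanceMatrix", "SubstitutionMatrix", function(x, ...) {
    m <- x@scores
    N <- nrow(m)
    if (!x@diagonalDominant)
        warning("matrix is not diagonally dominant; some distances may be negative")
    d <- (outer(diag(m), diag(m), "+") - m - t(m)) / 2
    d[upper.tri(d, diag = TRUE)] <- 0
    avg <- mean(d[lower.tri(d)])
    if (avg == 0)
        stop("all pairwise distances are zero; cannot normalize to mean 1")
    d <- d / avg
    d[upper.tri(d, diag = TRUE)] <- 0
    new("DistanceMatrix", alphabet = x@alphabet, values = d)
})

# strict-lower-triangle entries in column-major pair order
.pairVector <- function(m) m[lower.tri(m)]

#' @rdname accessors
#' @export
setMethod("alphabet", "SubstitutionMatrix", function(x) x@alphabet)
#' @rdname accessors
#' @export
setMethod("alphabet", "DistanceMatrix", function(x) x@alphabet)
#' @rdname accessors
#' @export
setMethod("scores", "SubstitutionMatrix", function(x) x@scores)
#' @rdname accessors
#' @export
setMethod("distances", "DistanceMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("nPairs", "DistanceMatrix", function(x) {
    N <- length(x@alphabet)
    (N * (N - 1L)) %/% 2L
})

#' Is the substitution matrix diagonally dominant?
#'
#' @param x a [SubstitutionMatrix-class].
#' @return \code{TRUE} iff every diagonal entry is the maximum of its row
#'   and column.
#' @export
isDiagonalDominant <- function(x) {
    stopifnot(is(x, "SubstitutionMatrix"))
    x@diagonalDominant
}

setMethod("show", "SubstitutionMatrix", function(object) {
    cat("SubstitutionMatrix over", length(object@alphabet), "symbols:",
        paste(object@alphabet, collapse = " "), "\n")
    cat("  diagonal dominant:", object@diagonalDominant, "\n")
})

setMethod("show", "DistanceMatrix", function(object) {
    v <- .pairVector(object@values)
    cat("DistanceMatrix over", length(object@alphabet), "symbols (",
        length(v), "pairs ), mean", format(mean(v)), "\n")
    cat("  range: [", format(min(v)), ",", format(max(v)), "]\n")
})
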
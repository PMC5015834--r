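# Adjacency helpers. Matrices are dense (connectomes of interest have a few
# hundred nodes) with neuron names on both dimensions.

# weighted chemical adjacency, [pre, post]
.chemMatrix <- function(x) {
    nm <- x@neurons$name
    n <- length(nm)
    A <- matrix(0, n, n, dimnames = list(nm, nm))
    ed <- x@edges[x@edges$kind == "chemical", , drop = FALSE]
    if (nrow(ed))
        A[cbind(match(ed$pre, nm), match(ed$post, nm))] <- ed$weight
    A
}

# symmetric weighted gap adjacency
.gapMatrix <- function(x) {
    nm <- x@neurons$name
    n <- length(nm)
    A <- matrix(0, n, n, dimnames = list(nm, nm))
    ed <- x@edges[x@edges$kind == "gap", , drop = FALSE]
    if (nrow(ed)) {
        i <- match(ed$pre, nm); j <- match(ed$post, nm)
        A[cbind(i, j)] <- ed$weight
        A[cbind(j, i)] <- ed$weight
    }
    A
}

# directed logical adjacency under a channel; gap junctions count both ways
.dirAdj <- function(x, channel = "all") {
    switch(channel,
        all = .chemMatrix(x) > 0 | .gapMatrix(x) > 0,
        chemical_only = .chemMatrix(x) > 0,
        gap_only = .gapMatrix(x) > 0,
        stop("unknown channel: ", channel))
}

# dyad-state code matrix: 0 none, 1 forward (row -> col only),
# 2 backward, 3 reciprocal
.dyadCodes <- function(x, channel = "all") {
    A <- .dirAdj(x, channel)
    A + 2L * t(A)
}

.DYAD_STATES <- c("none", "forward", "backward", "reciprocal")

#' Dyad state of a neuron pair
#'
#' The connection state of an ordered pair (a, b): \code{"none"},
#' \code{"forward"} (a to b only), \code{"backward"} (b to a only) or
#' \code{"reciprocal"}. A gap junction is bidirectional, so under
#' \code{channel = "all"} a gap edge alone yields \code{"reciprocal"}, as
#' does a chemical edge one way plus a gap junction.
#'
#' @param x a [Connectome-class]
#' @param a,b neuron names, distinct
#' @param channel which synapse channel to consider
#' @return one of \code{"none"}, \code{"forward"}, \code{"backward"},
#'   \code{"reciprocal"}
#' @export
dyadState <- function(x, a, b, channel = c("all", "chemical_only", "gap_only")) {
    channel <- match.arg(channel)
    .checkNeuron(x, c(a, b))
    if (a == b) stop("a and b must be distinct")
    code <- .dyadCodes(x, channel)[a, b]
    .DYAD_STATES[code + 1L]
}

#' Direction-blind neighbors of a neuron
#'
#' All neurons linked to \code{a} by a chemical synapse (either direction)
#' or a gap junction, under the chosen channel.
#'
#' @inheritParams dyadState
#' @return character vector of neuron names (possibly empty)
#' @export
neighborsOf <- function(x, a, channel = c("all", "chemical_only", "gap_only")) {
    channel <- match.arg(channel)
    .checkNeuron(x, a)
    A <- .dirAdj(x, channel)
    names(which(A[a, ] | A[, a]))
}

#' Number of common neighbors of a pair
#'
#' Counts neurons z linked (direction-blind, chemical or gap under the
#' channel) to both \code{a} and \code{b}; \code{a} and \code{b} themselves
#' are excluded.
#'
#' @inheritParams dyadState
#' @return non-negative integer
#' @export
countCommon <- function(x, a, b, channel = c("all", "chemical_only", "gap_only")) {
    channel <- match.arg(channel)
    .checkNeuron(x, c(a, b))
    if (a == b) stop("a and b must be distinct")
    A <- .dirAdj(x, channel)
    U <- A | t(A)
    z <- U[a, ] & U[b, ]
    z[c(a, b)] <- FALSE
    sum(z)
}

# symmetric logical "is neighbor" matrix and the common-neighbor count
# matrix (entry [i,j] = number of z adjacent to both i and j; the diagonal
# is meaningless and callers must ignore it)
.undirAdj <- function(x, channel = "all") {
    A <- .dirAdj(x, channel)
    A | t(A)
}

.commonCounts <- function(U) {
    storage.mode(U) <- "integer"
    U %*% U
}
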
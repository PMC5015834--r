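# Null-model machinery: degree-preserving edge swaps and density-matched
# Erdos-Renyi graphs, plus the ensemble slope comparison.

#' Degree-preserving shuffle of a connectome
#'
#' Randomizes wiring by repeated double-edge swaps while conserving, for
#' every neuron, the chemical in-degree, chemical out-degree and gap degree
#' exactly. Chemical (directed) and gap (undirected) layers are shuffled
#' independently and never interconverted; weights travel with their edges,
#' so total weight per layer is conserved too. A proposed swap is rejected
#' when it would create a self-loop or duplicate an existing edge of the
#' same layer.
#'
#' @param x a [Connectome-class]
#' @param swapFactor attempted swaps per layer = \code{swapFactor} times
#'   the layer's edge count (default 10, a standard mixing heuristic)
#' @param seed integer seed; the function leaves the global RNG state
#'   untouched
#' @return a shuffled [Connectome-class] with an attribute
#'   \code{swaps} = c(chemical = ..., gap = ...) counting accepted swaps
#' @export
shuffleDegreePreserving <- function(x, swapFactor = 10, seed) {
    nm <- x@neurons$name
    n <- length(nm)
    ed <- x@edges
    chem <- ed[ed$kind == "chemical", , drop = FALSE]
    gap <- ed[ed$kind == "gap", , drop = FALSE]
    withSeed(seed, {
        resC <- .swapDirected(match(chem$pre, nm), match(chem$post, nm),
                              n, swapFactor)
        resG <- .swapUndirected(match(gap$pre, nm), match(gap$post, nm),
                                n, swapFactor)
    })
    chem$pre <- nm[resC$from]; chem$post <- nm[resC$to]
    ga <- nm[resG$from]; gb <- nm[resG$to]
    gap$pre <- pmin(ga, gb); gap$post <- pmax(ga, gb)
    out <- initialize(x, edges = rbind(chem, gap))
    attr(out, "swaps") <- c(chemical = resC$accepted, gap = resG$accepted)
    out
}

# directed double-edge swap on integer endpoint vectors
.swapDirected <- function(from, to, n, swapFactor) {
    m <- length(from)
    if (m < 2L) return(list(from = from, to = to, accepted = 0L))
    A <- matrix(FALSE, n, n)
    A[cbind(from, to)] <- TRUE
    attempts <- ceiling(swapFactor * m)
    acc <- 0L
    for (k in seq_len(attempts)) {
        # edges drawn with replacement: picking the same edge twice is a
        # rejected attempt, which also decorrelates the accepted-swap count
        i <- sample.int(m, 1L); j <- sample.int(m, 1L)
        if (i == j) next
        a <- from[i]; b <- to[i]; c <- from[j]; d <- to[j]
        # propose a->d, c->b
        if (a == d || c == b) next
        if (A[a, d] || A[c, b]) next
        A[a, b] <- FALSE; A[c, d] <- FALSE
        A[a, d] <- TRUE; A[c, b] <- TRUE
        to[i] <- d; to[j] <- b
        acc <- acc + 1L
    }
    list(from = from, to = to, accepted = acc)
}

# undirected swap; edge ends may be flipped before pairing so both legal
# rewirings are reachable
.swapUndirected <- function(from, to, n, swapFactor) {
    m <- length(from)
    if (m < 2L) return(list(from = from, to = to, accepted = 0L))
    A <- matrix(FALSE, n, n)
    A[cbind(from, to)] <- TRUE
    A[cbind(to, from)] <- TRUE
    attempts <- ceiling(swapFactor * m)
    acc <- 0L
    for (k in seq_len(attempts)) {
        i <- sample.int(m, 1L); j <- sample.int(m, 1L)
        if (i == j) next
        a <- from[i]; b <- to[i]; c <- from[j]; d <- to[j]
        if (stats::runif(1L) < 0.5) { tmp <- c; c <- d; d <- tmp }
        # propose {a,d}, {c,b}
        if (a == d || c == b) next
        if (A[a, d] || A[c, b]) next
        A[a, b] <- FALSE; A[b, a] <- FALSE
        A[c, d] <- FALSE; A[d, c] <- FALSE
        A[a, d] <- TRUE; A[d, a] <- TRUE
        A[c, b] <- TRUE; A[b, c] <- TRUE
        to[i] <- d; from[j] <- c; to[j] <- b
        acc <- acc + 1L
    }
    list(from = from, to = to, accepted = acc)
}

#' Density-matched Erdos-Renyi null
#'
#' Draws a directed chemical-only graph on the same neurons with the same
#' number of directed links as the source: each gap junction counts as two
#' directed links for density matching (it is bidirectional in every
#' query), and all null edges have weight 1.
#'
#' @param x a [Connectome-class]
#' @param seed integer seed
#' @return a [Connectome-class]
#' @export
erMatchedNull <- function(x, seed) {
    nm <- x@neurons$name
    n <- length(nm)
    ed <- x@edges
    m <- sum(ed$kind == "chemical") + 2L * sum(ed$kind == "gap")
    m <- min(m, n * (n - 1L))
    idx <- withSeed(seed, sample.int(n * (n - 1L), m))
    # index ordered pairs (i, j), i != j: row-major over the off-diagonal
    i <- (idx - 1L) %/% (n - 1L) + 1L
    r <- (idx - 1L) %% (n - 1L) + 1L
    j <- ifelse(r >= i, r + 1L, r)
    edges <- data.frame(pre = nm[i], post = nm[j], kind = "chemical",
                        weight = 1L, stringsAsFactors = FALSE)
    initialize(x, edges = edges)
}

#' Ensemble slope test for the common-neighbor rule
#'
#' Generates an ensemble of null networks (degree-preserving shuffles of
#' the input, or density-matched Erdos-Renyi graphs), fits the CNR line on
#' each, and compares the real network's slope with the null slope
#' distribution by z-score: z = (real - mean)/sd with a two-sided normal p.
#'
#' @param x a [Connectome-class]
#' @param generator \code{"degree_preserving"} or \code{"erdos_renyi"}
#' @param nNetworks ensemble size (>= 2)
#' @param seed integer seed for the ensemble
#' @param minPairsPerBin passed to [cnrCurve()]
#' @param swapFactor passed to [shuffleDegreePreserving()]
#' @return list of class \code{EnsembleResult}: \code{real_slope},
#'   \code{slopes}, \code{z}, \code{p}, \code{generator},
#'   \code{n_networks}, \code{n_dropped} (nulls with infeasible fits),
#'   \code{seed}
#' @export
ensembleSlopeTest <- function(x,
                              generator = c("degree_preserving",
                                            "erdos_renyi"),
                              nNetworks = 100L, seed = 1L,
                              minPairsPerBin = 5L, swapFactor = 10) {
    generator <- match.arg(generator)
    stopifnot(nNetworks >= 2L)
    real <- cnrCurve(x, minPairsPerBin = minPairsPerBin)
    if (!real$fit$feasible) stop("CNR fit infeasible on the input network")
    subseeds <- deriveSeeds(seed, nNetworks)
    slopes <- rep(NA_real_, nNetworks)
    for (b in seq_len(nNetworks)) {
        nullnet <- switch(generator,
            degree_preserving = shuffleDegreePreserving(
                x, swapFactor = swapFactor, seed = subseeds[b]),
            erdos_renyi = erMatchedNull(x, seed = subseeds[b]))
        cv <- cnrCurve(nullnet, minPairsPerBin = minPairsPerBin)
        if (cv$fit$feasible) slopes[b] <- cv$fit$slope
    }
    dropped <- sum(is.na(slopes))
    if (dropped > 0.2 * nNetworks)
        stop(sprintf("CNR fit infeasible on %d/%d null networks",
                     dropped, nNetworks))
    slopes <- slopes[!is.na(slopes)]
    mu <- mean(slopes); s <- stats::sd(slopes)
    z <- if (s > 0) (real$fit$slope - mu) / s else
         if (real$fit$slope == mu) 0 else Inf * sign(real$fit$slope - mu)
    p <- if (is.finite(z)) 2 * stats::pnorm(-abs(z)) else 0
    structure(list(real_slope = real$fit$slope, slopes = slopes,
                   z = z, p = p, generator = generator,
                   n_networks = nNetworks, n_dropped = dropped,
                   seed = seed),
              class = "EnsembleResult")
}

#' @export
print.EnsembleResult <- function(x, ...) {
    cat(sprintf(
        "EnsembleResult [%s, %d networks]: real slope %.4g, null %.4g +/- %.4g, z = %.2f, p = %.3g\n",
        x$generator, x$n_networks, x$real_slope, mean(x$slopes),
        stats::sd(x$slopes), x$z, x$p))
    invisible(x)
}
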
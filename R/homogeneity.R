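#' Upper-tail hypergeometric p value
#'
#' Probability of observing \code{k} or more successes when drawing
#' \code{n} items without replacement from a population of \code{N} items
#' of which \code{K} are successes. This is the homogeneity score of a
#' common-neighbor set: the chance that its dominant triad type appears at
#' least as often as observed, given that type's abundance across all sets.
#'
#' @param k observed successes (0 <= k <= min(n, K))
#' @param n sample size (set size)
#' @param K population successes (global count of the type)
#' @param N population size (total triads over all sets)
#' @return P[H >= k], in (0, 1]; vectorized over its arguments
#' @examples
#' hgtPValue(0, 5, 50, 100)   # 1
#' hgtPValue(5, 5, 50, 100)   # choose(50,5)/choose(100,5)
#' @export
hgtPValue <- function(k, n, K, N) {
    if (any(k < 0) || any(n > N) || any(K > N) || any(k > pmin(n, K)))
        stop("inconsistent hypergeometric arguments")
    # upper tail including k; phyper works in log space internally
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Assess homogeneity of common-neighbor sets
#'
#' For each set, the dominant triad type is its most frequent member type
#' (ties broken by smaller hypergeometric p, then lower canonical type id).
#' The hypergeometric population pools the member triads of all provided
#' sets (the test accounts for the relative abundance of each type across
#' sets). A set is homogeneous when the upper-tail hypergeometric p is at
#' most \code{alpha} and at least a \code{majorityFraction} of its members
#' share the dominant type.
#'
#' @param sets list of \code{CommonNeighborSet} as from [extractSets()];
#'   all must share one connectivity class (all connected or all
#'   unconnected), since the population is pooled within class
#' @param alpha per-set p-value threshold (default 0.05; no multiplicity
#'   correction is applied here -- see [enrichmentTests()])
#' @param majorityFraction minimum dominant-type share (default 0.5)
#' @return data.frame of class \code{homogeneityResults}, one row per set:
#'   \code{x}, \code{y}, \code{connected}, \code{dominant_type}, \code{k},
#'   \code{n}, \code{K}, \code{N}, \code{p_hgt}, \code{majority},
#'   \code{homogeneous}. The input sets ride along as attribute
#'   \code{"sets"} in the same order.
#' @export
assessHomogeneity <- function(sets, alpha = 0.05, majorityFraction = 0.5) {
    if (length(sets) == 0L) stop("no sets supplied")
    conn <- vapply(sets, function(s) s$connected, logical(1L))
    if (length(unique(conn)) != 1L)
        stop("sets must all share one connectivity class")
    types <- lapply(sets, function(s) s$members$type)
    Kj <- tabulate(unlist(types), nbins = 21L)
    N <- sum(Kj)
    rows <- lapply(seq_along(sets), function(i) {
        tt <- types[[i]]
        n <- length(tt)
        tab <- tabulate(tt, nbins = 21L)
        kmax <- max(tab)
        cand <- which(tab == kmax)
        if (length(cand) > 1L) {
            pc <- hgtPValue(kmax, n, Kj[cand], N)
            cand <- cand[order(pc, cand)][1L]
        }
        p <- hgtPValue(kmax, n, Kj[cand], N)
        data.frame(x = sets[[i]]$x, y = sets[[i]]$y,
                   connected = sets[[i]]$connected,
                   dominant_type = cand, k = kmax, n = n,
                   K = Kj[cand], N = N, p_hgt = p,
                   majority = kmax / n >= majorityFraction,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    res$homogeneous <- res$p_hgt <= alpha & res$majority
    attr(res, "sets") <- sets
    attr(res, "alpha") <- alpha
    attr(res, "majorityFraction") <- majorityFraction
    class(res) <- c("homogeneityResults", "data.frame")
    res
}

#' Shuffle set composition while preserving sizes and global type counts
#'
#' Pools the triad-type labels of all member slots across all sets,
#' permutes them uniformly, and redistributes them to the original slots.
#' Every set keeps its size and the global type multiset is exactly
#' conserved -- the null model for set homogeneity.
#'
#' @param sets list of \code{CommonNeighborSet} (>= 2 for a non-trivial
#'   shuffle)
#' @param seed integer seed
#' @return list of sets with permuted member types
#' @export
shuffleSets <- function(sets, seed) {
    pool <- unlist(lapply(sets, function(s) s$members$type))
    perm <- withSeed(seed, sample(pool))
    off <- 0L
    out <- lapply(sets, function(s) {
        n <- s$n
        s$members$type <- perm[(off + 1L):(off + n)]
        off <<- off + n
        s
    })
    out
}

#' Per-type enrichment of homogeneous sets against shuffled nulls
#'
#' Recomputes [assessHomogeneity()] on \code{R} independent set shuffles
#' and compares, per triad type and overall, the number of homogeneous
#' sets in the real data with the null distribution: z = (real - null
#' mean)/null sd, two-sided normal p, Bonferroni-corrected over the types
#' tested (those with any member triads). A zero-variance null is flagged
#' degenerate; its p is reported as the resampling bound 1/R when the real
#' count differs from the null and 1 otherwise.
#'
#' @param sets list of \code{CommonNeighborSet}
#' @param R number of shuffles (>= 10)
#' @param seed integer seed
#' @param alpha,majorityFraction passed to [assessHomogeneity()]
#' @return list of class \code{NullComparison}: \code{overall} (list
#'   \code{real}, \code{null_mean}, \code{null_sd}, \code{z}, \code{p}),
#'   \code{per_type} (data.frame \code{type}, \code{real},
#'   \code{null_mean}, \code{null_sd}, \code{z}, \code{p},
#'   \code{p_bonferroni}, \code{significant}, \code{degenerate}),
#'   \code{per_size} (data.frame of real vs null homogeneous counts by set
#'   size), \code{null_counts} (R x 21 matrix), \code{R}, \code{seed}
#' @export
enrichmentTests <- function(sets, R = 100L, seed = 1L, alpha = 0.05,
                            majorityFraction = 0.5) {
    stopifnot(R >= 10L)
    real <- assessHomogeneity(sets, alpha, majorityFraction)
    realByType <- tabulate(real$dominant_type[real$homogeneous], nbins = 21L)
    sizes <- real$n
    sizeLevels <- sort(unique(sizes))
    realBySize <- vapply(sizeLevels, function(s)
        sum(real$homogeneous & sizes == s), integer(1L))

    subseeds <- deriveSeeds(seed, R)
    nullByType <- matrix(0L, R, 21L)
    nullTotal <- integer(R)
    nullBySize <- matrix(0L, R, length(sizeLevels))
    for (b in seq_len(R)) {
        sh <- shuffleSets(sets, seed = subseeds[b])
        hr <- assessHomogeneity(sh, alpha, majorityFraction)
        nullByType[b, ] <- tabulate(hr$dominant_type[hr$homogeneous],
                                    nbins = 21L)
        nullTotal[b] <- sum(hr$homogeneous)
        nullBySize[b, ] <- vapply(sizeLevels, function(s)
            sum(hr$homogeneous & hr$n == s), integer(1L))
    }

    # z and normal p as in the headline analysis, but the p used for
    # significance is floored by the one-sided permutation estimate
    # (1 + #{null >= real})/(R + 1): the normal tail is an extrapolation
    # and badly anti-conservative when homogeneous counts are rare, while
    # the permutation p is exact at the resolution R affords. A
    # zero-variance null is flagged degenerate; its normal p is then the
    # permutation bound itself.
    zp <- function(realCount, nullVec) {
        mu <- mean(nullVec); s <- stats::sd(nullVec)
        pperm <- if (realCount > mu)
            (1 + sum(nullVec >= realCount)) / (R + 1) else 1
        if (s > 0) {
            z <- (realCount - mu) / s
            pnorm2 <- 2 * stats::pnorm(-abs(z))
            list(z = z, p = if (realCount > mu) max(pnorm2, pperm) else
                 pnorm2, degenerate = FALSE)
        } else if (realCount == mu) {
            list(z = 0, p = 1, degenerate = TRUE)
        } else {
            list(z = Inf * sign(realCount - mu),
                 p = if (realCount > mu) pperm else 1 / (R + 1),
                 degenerate = TRUE)
        }
    }

    tested <- which(tabulate(unlist(lapply(sets, function(s) s$members$type)),
                             nbins = 21L) > 0L)
    perType <- do.call(rbind, lapply(tested, function(j) {
        st <- zp(realByType[j], nullByType[, j])
        data.frame(type = j, real = realByType[j],
                   null_mean = mean(nullByType[, j]),
                   null_sd = stats::sd(nullByType[, j]),
                   z = st$z, p = st$p, degenerate = st$degenerate)
    }))
    perType$p_bonferroni <- pmin(1, perType$p * length(tested))
    perType$significant <- perType$p_bonferroni <= alpha

    ov <- zp(sum(real$homogeneous), nullTotal)
    perSize <- data.frame(size = sizeLevels, real = realBySize,
                          null_mean = colMeans(nullBySize),
                          null_sd = apply(nullBySize, 2L, stats::sd))

    structure(list(
        overall = list(real = sum(real$homogeneous),
                       null_mean = mean(nullTotal),
                       null_sd = stats::sd(nullTotal),
                       z = ov$z, p = ov$p, degenerate = ov$degenerate),
        per_type = perType, per_size = perSize,
        null_counts = nullByType, R = R, seed = seed,
        results = real),
        class = "NullComparison")
}

#' @export
print.NullComparison <- function(x, ...) {
    cat(sprintf(
        "NullComparison (R = %d shuffles): %d homogeneous sets vs null %.2f +/- %.2f (z = %.2f, p = %.3g)\n",
        x$R, x$overall$real, x$overall$null_mean, x$overall$null_sd,
        x$overall$z, x$overall$p))
    sig <- x$per_type[x$per_type$significant & x$per_type$real >
                      x$per_type$null_mean, ]
    if (nrow(sig))
        cat("  enriched types:", paste0("#", sig$type, collapse = ", "), "\n")
    invisible(x)
}

#' Fraction of total synaptic weight covered by homogeneous sets
#'
#' Sums the weights of every edge incident to at least one homogeneous set
#' -- the X-Y dyad edges plus the X-Z and Y-Z dyad edges of all members,
#' chemical and gap alike -- and divides by the total edge weight of the
#' connectome.
#'
#' @param x the [Connectome-class] the results were computed on
#' @param results a \code{homogeneityResults} data.frame
#' @return scalar in [0, 1]
#' @export
synapseCoverage <- function(x, results) {
    sets <- attr(results, "sets")
    if (is.null(sets)) stop("results carry no sets attribute")
    ed <- x@edges
    total <- sum(ed$weight)
    if (total == 0) return(0)
    covered <- character()
    for (i in which(results$homogeneous)) {
        s <- sets[[i]]
        pairs <- rbind(c(s$x, s$y),
                       cbind(s$x, s$members$z),
                       cbind(s$y, s$members$z))
        covered <- c(covered,
                     paste(pairs[, 1L], pairs[, 2L], sep = "\r"),
                     paste(pairs[, 2L], pairs[, 1L], sep = "\r"))
    }
    covered <- unique(covered)
    key <- paste(ed$pre, ed$post, sep = "\r")
    sum(ed$weight[key %in% covered]) / total
}

#' Bilateral-symmetry ratio of set pairs
#'
#' A pair is bilaterally symmetric when the two names differ only in a
#' terminal L/R (e.g. PHAL/PHAR). Returns the ratio of symmetric to
#' asymmetric X-Y pairs among homogeneous sets and among all sets, to test
#' whether homogeneity is driven by the worm's left-right anatomy.
#'
#' @param results a \code{homogeneityResults} data.frame
#' @return named numeric vector
#'   \code{c(homogeneous = ..., all = ...)}; a ratio is \code{Inf} when no
#'   asymmetric pair exists and \code{NaN} when a group is empty
#' @export
bilateralRatio <- function(results) {
    sym <- isBilateralPair(results$x, results$y)
    ratio <- function(idx) {
        ns <- sum(sym[idx]); na <- sum(!sym[idx])
        if (na == 0L && ns == 0L) NaN else ns / na
    }
    c(homogeneous = ratio(results$homogeneous),
      all = ratio(rep(TRUE, nrow(results))))
}

#' @rdname bilateralRatio
#' @param a,b character vectors of neuron names
#' @export
isBilateralPair <- function(a, b) {
    stem <- function(v) sub("[LR]$", "", v)
    side <- function(v) ifelse(grepl("[LR]$", v), substring(v, nchar(v)), "")
    sa <- side(a); sb <- side(b)
    sa != "" & sb != "" & sa != sb & stem(a) == stem(b)
}
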
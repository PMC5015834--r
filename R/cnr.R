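#' Common-neighbor-rule curve
#'
#' Bins every unordered neuron pair by its number of common neighbors and
#' computes the fraction of pairs in each bin that are themselves connected
#' (any dyad state other than none). An ordinary least-squares line is
#' fitted over the bins holding at least \code{minPairsPerBin} pairs;
#' optionally the fit is weighted by bin pair counts.
#'
#' @param x a [Connectome-class] with at least 3 neurons
#' @param minPairsPerBin bins with fewer pairs are excluded from the fit
#'   (default 5, so single-pair bins at high common-neighbor counts do not
#'   dominate the line)
#' @param weighted weight the least-squares fit by \code{n_pairs}
#' @param channel synapse channel
#' @return object of class \code{CNRCurve}: list with \code{bins}
#'   (data.frame \code{n_common}, \code{n_pairs}, \code{n_connected},
#'   \code{fraction}), \code{fit} (list \code{slope}, \code{intercept},
#'   \code{r_squared}, \code{feasible}), and \code{bins_used} (the
#'   \code{n_common} values entering the fit). When fewer than 2 bins are
#'   eligible the fit is flagged infeasible and its statistics are NA.
#' @export
cnrCurve <- function(x, minPairsPerBin = 5L, weighted = FALSE,
                     channel = c("all", "chemical_only", "gap_only")) {
    channel <- match.arg(channel)
    if (nNeurons(x) < 3L) stop("need at least 3 neurons")
    U <- .undirAdj(x, channel)
    CC <- .commonCounts(U)
    up <- upper.tri(CC)
    cn <- CC[up]
    conn <- U[up]
    bins <- aggregate(data.frame(n_pairs = 1L, n_connected = as.integer(conn)),
                      by = list(n_common = cn), FUN = sum)
    bins$fraction <- bins$n_connected / bins$n_pairs
    eligible <- bins$n_pairs >= minPairsPerBin
    fit <- list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, feasible = FALSE)
    if (sum(eligible) >= 2L) {
        d <- bins[eligible, , drop = FALSE]
        w <- if (weighted) d$n_pairs else NULL
        m <- stats::lm(fraction ~ n_common, data = d, weights = w)
        fit$slope <- unname(stats::coef(m)[2L])
        fit$intercept <- unname(stats::coef(m)[1L])
        ybar <- if (is.null(w)) mean(d$fraction) else
            stats::weighted.mean(d$fraction, w)
        sst <- sum((if (is.null(w)) 1 else w) * (d$fraction - ybar)^2)
        fit$r_squared <- if (sst > 0)
            1 - sum((if (is.null(w)) 1 else w) * stats::resid(m)^2) / sst
        else NA_real_
        fit$feasible <- TRUE
    }
    structure(list(bins = bins, fit = fit,
                   bins_used = bins$n_common[eligible],
                   channel = channel),
              class = "CNRCurve")
}

#' @export
print.CNRCurve <- function(x, ...) {
    cat(sprintf("CNRCurve: %d bins (%d used in fit)\n",
                nrow(x$bins), length(x$bins_used)))
    if (isTRUE(x$fit$feasible))
        cat(sprintf("  fit: slope %.4g, intercept %.4g, R^2 %.3f\n",
                    x$fit$slope, x$fit$intercept, x$fit$r_squared))
    else cat("  fit infeasible (fewer than 2 eligible bins)\n")
    invisible(x)
}

#' Distance controls for the common-neighbor rule
#'
#' Correlates either the common-neighbor count of neuron pairs
#' (\code{mode = "cn_vs_distance"}) or a 0/1 connected indicator
#' (\code{mode = "connectivity_vs_distance"}) with the absolute difference
#' of soma positions along the anterior--posterior axis. The one-tailed p
#' value tests for negative correlation via the t statistic
#' \eqn{r\sqrt{(m-2)/(1-r^2)}} on m - 2 degrees of freedom.
#'
#' @param x a [Connectome-class]; soma positions must be available for all
#'   neurons in scope
#' @param mode which quantity to correlate with distance
#' @param pairScope \code{"all_pairs"} or \code{"connected_pairs"} (the
#'   latter applies to \code{cn_vs_distance} only)
#' @param channel synapse channel
#' @return list of class \code{DistanceResult}: \code{r}, \code{p},
#'   \code{m} (number of pairs), \code{mode}, \code{pair_scope},
#'   \code{degenerate} (TRUE when a variable has zero variance, in which
#'   case r is NA and p = 1)
#' @export
distanceAnalysis <- function(x,
                             mode = c("cn_vs_distance",
                                      "connectivity_vs_distance"),
                             pairScope = c("all_pairs", "connected_pairs"),
                             channel = c("all", "chemical_only", "gap_only")) {
    mode <- match.arg(mode)
    pairScope <- match.arg(pairScope)
    channel <- match.arg(channel)
    pos <- x@neurons$soma_position
    if (anyNA(pos))
        stop("soma positions missing for ",
             sum(is.na(pos)), " neuron(s)")
    U <- .undirAdj(x, channel)
    up <- upper.tri(U)
    dist <- abs(outer(pos, pos, "-"))[up]
    if (mode == "connectivity_vs_distance") {
        val <- as.numeric(U[up])
        keep <- rep(TRUE, length(val))
    } else {
        CC <- .commonCounts(U)
        val <- as.numeric(CC[up])
        keep <- if (pairScope == "connected_pairs") U[up] else
                rep(TRUE, length(val))
    }
    dist <- dist[keep]; val <- val[keep]
    m <- length(val)
    if (m < 3L) stop("need at least 3 pairs in scope")
    if (stats::sd(dist) == 0 || stats::sd(val) == 0) {
        res <- list(r = NA_real_, p = 1, m = m, mode = mode,
                    pair_scope = pairScope, degenerate = TRUE)
        return(structure(res, class = "DistanceResult"))
    }
    r <- stats::cor(val, dist)
    tstat <- r * sqrt((m - 2) / (1 - r^2))
    p <- stats::pt(tstat, df = m - 2)   # lower tail: small when r < 0
    structure(list(r = r, p = p, m = m, mode = mode,
                   pair_scope = pairScope, degenerate = FALSE),
              class = "DistanceResult")
}

#' @export
print.DistanceResult <- function(x, ...) {
    cat(sprintf("DistanceResult [%s, %s]: r = %.3f, one-tailed p = %.3g (m = %d)\n",
                x$mode, x$pair_scope,
                ifelse(is.na(x$r), NaN, x$r), x$p, x$m))
    invisible(x)
}
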
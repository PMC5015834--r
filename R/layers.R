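# Layer localization of homogeneous sets (sensory / inter / premotor /
# motor). Layers are curated inputs, never inferred from topology.

# layer pair label for one set: ordered "X:Y" for a directed X-Y link
# (X is the source), unordered (sorted) otherwise
.layerPairLabel <- function(xLayer, yLayer, xy) {
    ifelse(xy == "forward",
           paste(xLayer, yLayer, sep = ":"),
           paste(pmin(xLayer, yLayer), pmax(xLayer, yLayer), sep = ":"))
}

# per-set layer annotation shared by the layer operations; NULL rows for
# unknown layers are flagged in column `known`
.setLayerFrame <- function(x, results) {
    sets <- attr(results, "sets")
    if (is.null(sets)) stop("results carry no sets attribute")
    lay <- neuronLayers(x)
    xy <- vapply(sets, function(s) s$xy, character(1L))
    lx <- unname(lay[results$x]); ly <- unname(lay[results$y])
    data.frame(dominant_type = results$dominant_type,
               homogeneous = results$homogeneous,
               x_layer = lx, y_layer = ly, xy = xy,
               pair = .layerPairLabel(lx, ly, xy),
               same = lx == ly,
               known = lx != "unknown" & ly != "unknown",
               stringsAsFactors = FALSE)
}

#' Layer-pair histogram of homogeneous sets
#'
#' For each homogeneous set type, counts how often the X-Y pair sits in the
#' same layer versus different layers, plus the full layer-pair matrix.
#' For set types whose X-Y link is directed the layer pair is ordered (X is
#' the source); for bidirectional or unconnected pairs it is unordered.
#' Sets with an unknown layer on either end are excluded from the counts
#' and reported in \code{n_unknown}.
#'
#' @param x the [Connectome-class] carrying the layer assignment
#' @param results a \code{homogeneityResults} data.frame
#' @return list with \code{same_diff} (data.frame \code{set_type},
#'   \code{same_layer}, \code{different_layer}), \code{pairs} (data.frame
#'   \code{set_type}, \code{layer_pair}, \code{count}) and
#'   \code{n_unknown}
#' @export
layerPairHistogram <- function(x, results) {
    d <- .setLayerFrame(x, results)
    d <- d[d$homogeneous, , drop = FALSE]
    nUnknown <- sum(!d$known)
    d <- d[d$known, , drop = FALSE]
    if (nrow(d) == 0L)
        return(list(same_diff = data.frame(set_type = integer(),
                                           same_layer = integer(),
                                           different_layer = integer()),
                    pairs = data.frame(set_type = integer(),
                                       layer_pair = character(),
                                       count = integer()),
                    n_unknown = nUnknown))
    sd_ <- aggregate(cbind(same_layer = d$same,
                           different_layer = !d$same),
                     by = list(set_type = d$dominant_type), FUN = sum)
    pr <- aggregate(list(count = rep(1L, nrow(d))),
                    by = list(set_type = d$dominant_type,
                              layer_pair = d$pair), FUN = sum)
    pr <- pr[order(pr$set_type, pr$layer_pair), ]
    rownames(pr) <- NULL
    list(same_diff = sd_, pairs = pr, n_unknown = nUnknown)
}

#' Layer-pair enrichment of homogeneous set types
#'
#' For every (set type, layer pair) cell an upper-tail hypergeometric test:
#' population N = homogeneous sets with known layers (all types), successes
#' K = those with the cell's layer pair, sample n = homogeneous sets of the
#' cell's type, observed k = the cell count. Bonferroni correction is over
#' all cells tested.
#'
#' @param x the [Connectome-class] carrying the layer assignment
#' @param results a \code{homogeneityResults} data.frame
#' @param threshold significance threshold applied to the
#'   Bonferroni-corrected p (default 0.005)
#' @param background \code{"homogeneous"} (default) restricts the
#'   population to homogeneous sets; \code{"all"} uses every set with
#'   known layers, as a sensitivity analysis
#' @return data.frame of class \code{LayerEnrichment}: \code{set_type},
#'   \code{layer_pair}, \code{count}, \code{n}, \code{K}, \code{N},
#'   \code{p_hgt}, \code{p_bonferroni}, \code{significant}
#' @export
layerEnrichment <- function(x, results, threshold = 0.005,
                            background = c("homogeneous", "all")) {
    background <- match.arg(background)
    d <- .setLayerFrame(x, results)
    d <- d[d$known, , drop = FALSE]
    pop <- if (background == "homogeneous")
        d[d$homogeneous, , drop = FALSE] else d
    samp <- d[d$homogeneous, , drop = FALSE]
    if (nrow(pop) == 0L || nrow(samp) == 0L)
        stop("no sets with known layers")
    N <- nrow(pop)
    types <- sort(unique(samp$dominant_type))
    pairsSeen <- sort(unique(pop$pair))
    cells <- expand.grid(set_type = types, layer_pair = pairsSeen,
                         stringsAsFactors = FALSE)
    cells$count <- mapply(function(tp, lp)
        sum(samp$dominant_type == tp & samp$pair == lp),
        cells$set_type, cells$layer_pair)
    cells$n <- vapply(cells$set_type, function(tp)
        sum(samp$dominant_type == tp), integer(1L))
    cells$K <- vapply(cells$layer_pair, function(lp)
        sum(pop$pair == lp), integer(1L))
    cells$N <- N
    # a sample larger than the success count can only happen under the
    # "all" background where samp is not a subset of a type's pop cells
    cells$p_hgt <- mapply(function(k, n, K, N)
        hgtPValue(min(k, K), min(n, N), K, N), cells$count, cells$n,
        cells$K, cells$N)
    nTested <- nrow(cells)
    cells$p_bonferroni <- pmin(1, cells$p_hgt * nTested)
    cells$significant <- cells$p_bonferroni <= threshold
    class(cells) <- c("LayerEnrichment", "data.frame")
    cells
}

#' Chemical/gap composition of the X-Y dyad in bidirectional sets
#'
#' For homogeneous sets of the bidirectional types (10--15), counts how
#' many X-Y dyads carry a chemical synapse and how many carry a gap
#' junction; a dyad with both channels contributes to both tallies.
#'
#' @param x the [Connectome-class]
#' @param results a \code{homogeneityResults} data.frame
#' @return data.frame: \code{set_type}, \code{n_sets}, \code{n_chemical},
#'   \code{n_gap}
#' @export
xySynapseComposition <- function(x, results) {
    keep <- results$homogeneous & results$dominant_type >= 10L &
            results$dominant_type <= 15L
    r <- results[keep, , drop = FALSE]
    if (nrow(r) == 0L)
        return(data.frame(set_type = integer(), n_sets = integer(),
                          n_chemical = integer(), n_gap = integer()))
    chem <- .chemMatrix(x); gapm <- .gapMatrix(x)
    hasChem <- chem[cbind(r$x, r$y)] > 0 | chem[cbind(r$y, r$x)] > 0
    hasGap <- gapm[cbind(r$x, r$y)] > 0
    out <- aggregate(cbind(n_sets = 1L, n_chemical = as.integer(hasChem),
                           n_gap = as.integer(hasGap)),
                     by = list(set_type = r$dominant_type), FUN = sum)
    out
}

#' Rerun the set analysis on the chemical-synapse network alone
#'
#' Discards all gap junctions, re-extracts common-neighbor sets, reassesses
#' homogeneity and recomputes the per-type enrichment against shuffled
#' nulls. Gap-driven set types (notably the mutually regulated #13 and
#' fully bidirectional #15) lose their overrepresentation under this
#' filter; a gap-free connectome gives results identical to the standard
#' pipeline.
#'
#' @param x a [Connectome-class]
#' @param minNeighbors,connectedOnly passed to [extractSets()]
#' @param alpha,majorityFraction passed to [assessHomogeneity()]
#' @param R,seed passed to [enrichmentTests()]
#' @return the \code{NullComparison} from [enrichmentTests()] on the
#'   chemical-only network
#' @export
chemicalOnlyReanalysis <- function(x, minNeighbors = 5L,
                                   connectedOnly = TRUE, alpha = 0.05,
                                   majorityFraction = 0.5, R = 100L,
                                   seed = 1L) {
    xc <- filterChannel(x, "chemical_only")
    sets <- extractSets(xc, minNeighbors = minNeighbors,
                        connectedOnly = connectedOnly)
    if (length(sets) == 0L) stop("no sets in the chemical-only network")
    enrichmentTests(sets, R = R, seed = seed, alpha = alpha,
                    majorityFraction = majorityFraction)
}

#' Joint layer distribution of the pair and its common neighbors
#'
#' Per set type, tabulates the (X-Y layer pair, Z layer) combinations over
#' all members of homogeneous sets; counts per type sum to the total
#' membership of that type's homogeneous sets (with known layers).
#'
#' @param x the [Connectome-class] carrying the layer assignment
#' @param results a \code{homogeneityResults} data.frame
#' @return data.frame: \code{set_type}, \code{xy_layers}, \code{z_layer},
#'   \code{count}
#' @export
xyVsZLayerDistribution <- function(x, results) {
    sets <- attr(results, "sets")
    d <- .setLayerFrame(x, results)
    lay <- neuronLayers(x)
    rows <- list()
    for (i in which(results$homogeneous & d$known)) {
        zl <- unname(lay[sets[[i]]$members$z])
        rows[[length(rows) + 1L]] <- data.frame(
            set_type = results$dominant_type[i],
            xy_layers = d$pair[i], z_layer = zl,
            stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L)
        return(data.frame(set_type = integer(), xy_layers = character(),
                          z_layer = character(), count = integer()))
    dd <- do.call(rbind, rows)
    out <- aggregate(list(count = rep(1L, nrow(dd))),
                     by = dd[c("set_type", "xy_layers", "z_layer")],
                     FUN = sum)
    out[order(out$set_type, out$xy_layers, out$z_layer), ]
}
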
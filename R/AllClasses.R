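#' @import methods
NULL

.LAYERS <- c("sensory", "inter", "premotor", "motor", "unknown")
.EDGE_KINDS <- c("chemical", "gap")

#' Connectome: a directed multigraph of chemical synapses and gap junctions
#'
#' The central container of the package. Neurons are identified by name and
#' carry an optional functional-layer assignment (sensory, inter, premotor,
#' motor, or unknown) and an optional scalar soma position along the
#' anterior--posterior body axis. Edges are of two kinds: chemical synapses
#' are directed and weighted by synapse count; gap junctions are symmetric,
#' stored once per unordered pair (with endpoints in sorted order), and
#' behave bidirectionally in every query.
#'
#' @slot neurons data.frame with columns \code{name} (character, unique),
#'   \code{layer} (character, one of sensory/inter/premotor/motor/unknown)
#'   and \code{soma_position} (numeric in [0,1], may be \code{NA}).
#' @slot edges data.frame with columns \code{pre}, \code{post} (character
#'   neuron names), \code{kind} (\code{"chemical"} or \code{"gap"}) and
#'   \code{weight} (positive integer count). At most one chemical edge per
#'   ordered pair and one gap edge per unordered pair.
#'
#' @seealso [makeConnectome()], [readEdgeList()], [dyadState()],
#'   [neighborsOf()]
#' @export
setClass("Connectome",
    representation(neurons = "data.frame", edges = "data.frame"))

setValidity("Connectome", function(object) {
    nr <- object@neurons
    ed <- object@edges
    msgs <- character()
    need_n <- c("name", "layer", "soma_position")
    need_e <- c("pre", "post", "kind", "weight")
    if (!all(need_n %in% names(nr)))
        return(sprintf("neurons must have columns %s",
                       paste(need_n, collapse = ", ")))
    if (!all(need_e %in% names(ed)))
        return(sprintf("edges must have columns %s",
                       paste(need_e, collapse = ", ")))
    if (anyDuplicated(nr$name))
        msgs <- c(msgs, "neuron names must be unique")
    if (!all(nr$layer %in% .LAYERS))
        msgs <- c(msgs, sprintf("layer must be one of %s",
                                paste(.LAYERS, collapse = "/")))
    pos <- nr$soma_position
    if (any(!is.na(pos) & (pos < 0 | pos > 1)))
        msgs <- c(msgs, "soma_position must lie in [0,1]")
    if (nrow(ed)) {
        if (!all(ed$kind %in% .EDGE_KINDS))
            msgs <- c(msgs, "edge kind must be 'chemical' or 'gap'")
        if (any(ed$pre == ed$post))
            msgs <- c(msgs, "self-edges are not allowed")
        bad <- !(ed$pre %in% nr$name) | !(ed$post %in% nr$name)
        if (any(bad))
            msgs <- c(msgs, sprintf("edge endpoints not in neuron table: %s",
                paste(unique(c(ed$pre[bad], ed$post[bad])), collapse = ", ")))
        if (any(ed$weight < 1) || any(ed$weight != round(ed$weight)))
            msgs <- c(msgs, "weights must be positive integers")
        chem <- ed[ed$kind == "chemical", , drop = FALSE]
        if (anyDuplicated(paste(chem$pre, chem$post, sep = "\r")))
            msgs <- c(msgs, "duplicate chemical edge for an ordered pair")
        gap <- ed[ed$kind == "gap", , drop = FALSE]
        if (nrow(gap)) {
            if (any(gap$pre > gap$post))
                msgs <- c(msgs, "gap edges must be stored with pre < post")
            if (anyDuplicated(paste(gap$pre, gap$post, sep = "\r")))
                msgs <- c(msgs, "duplicate gap edge for an unordered pair")
        }
    }
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setMethod("show", "Connectome", function(object) {
    ed <- object@edges
    nchem <- sum(ed$kind == "chemical")
    ngap <- sum(ed$kind == "gap")
    cat(sprintf("Connectome: %d neurons, %d chemical edges, %d gap junctions\n",
                nrow(object@neurons), nchem, ngap))
    lay <- table(factor(object@neurons$layer, levels = .LAYERS))
    lay <- lay[lay > 0]
    if (length(lay))
        cat("  layers:", paste(sprintf("%s=%d", names(lay), lay),
                               collapse = ", "), "\n")
    npos <- sum(!is.na(object@neurons$soma_position))
    if (npos)
        cat(sprintf("  soma positions for %d neurons\n", npos))
    invisible(object)
})
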
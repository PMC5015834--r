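#' Build a Connectome from neuron and edge tables
#'
#' Constructor used by all readers and generators. Parallel edge records of
#' the same kind and (ordered, for chemical; unordered, for gap) endpoint
#' pair are summed. Gap records given in either endpoint order are
#' canonicalized to sorted order; if a gap junction is recorded in both
#' orders the two directional totals must agree (a mirror record of the same
#' junction), otherwise the weights are inconsistent and loading fails.
#'
#' @param edges data.frame with columns \code{pre}, \code{post}, \code{kind}
#'   (\code{"chemical"}/\code{"gap"}), \code{weight}. May have zero rows.
#' @param neurons optional data.frame with column \code{name} and optional
#'   \code{layer} and \code{soma_position} columns. Neurons named here but
#'   absent from the edge list are retained as isolated nodes so that
#'   catalog counts stay stable; neurons appearing only in edges are added
#'   with layer \code{"unknown"}.
#' @param collapseReciprocalGap when TRUE (default), a gap pair recorded in
#'   both endpoint orders collapses to one record provided the weights
#'   match.
#' @return a validated [Connectome-class] object.
#' @examples
#' ed <- data.frame(pre = c("A", "B"), post = c("B", "C"),
#'                  kind = "chemical", weight = c(3L, 1L))
#' makeConnectome(ed)
#' @export
makeConnectome <- function(edges, neurons = NULL, collapseReciprocalGap = TRUE) {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (nrow(edges) == 0L)
        edges <- data.frame(pre = character(), post = character(),
                            kind = character(), weight = integer())
    edges$pre <- as.character(edges$pre)
    edges$post <- as.character(edges$post)
    edges$kind <- as.character(edges$kind)
    edges$weight <- as.integer(edges$weight)
    if (any(edges$pre == edges$post))
        stop("self-edges are not allowed (pre == post)")

    chem <- edges[edges$kind == "chemical", , drop = FALSE]
    gap <- edges[edges$kind == "gap", , drop = FALSE]

    if (nrow(chem)) {
        key <- paste(chem$pre, chem$post, sep = "\r")
        w <- tapply(chem$weight, key, sum)
        sp <- strsplit(names(w), "\r", fixed = TRUE)
        chem <- data.frame(pre = vapply(sp, `[`, "", 1L),
                           post = vapply(sp, `[`, "", 2L),
                           kind = "chemical", weight = as.integer(w))
    }
    if (nrow(gap)) {
        a <- pmin(gap$pre, gap$post)
        b <- pmax(gap$pre, gap$post)
        fwd <- gap$pre == a   # record already in canonical order?
        key <- paste(a, b, sep = "\r")
        wfwd <- tapply(ifelse(fwd, gap$weight, 0L), key, sum)
        wrev <- tapply(ifelse(fwd, 0L, gap$weight), key, sum)
        both <- wfwd > 0 & wrev > 0
        if (any(both)) {
            if (!collapseReciprocalGap)
                stop("gap junction recorded in both endpoint orders")
            bad <- both & (wfwd != wrev)
            if (any(bad))
                stop(sprintf(
                    "gap junction weight mismatch between mirror records: %s",
                    paste(gsub("\r", "-", names(wfwd)[bad]), collapse = ", ")))
        }
        w <- ifelse(both, wfwd, wfwd + wrev)
        sp <- strsplit(names(wfwd), "\r", fixed = TRUE)
        gap <- data.frame(pre = vapply(sp, `[`, "", 1L),
                          post = vapply(sp, `[`, "", 2L),
                          kind = "gap", weight = as.integer(w))
    }
    edges <- rbind(chem, gap)
    rownames(edges) <- NULL

    nm <- unique(c(edges$pre, edges$post))
    if (!is.null(neurons)) {
        neurons <- as.data.frame(neurons, stringsAsFactors = FALSE)
        stopifnot("name" %in% names(neurons))
        nm <- unique(c(as.character(neurons$name), nm))
    }
    nr <- data.frame(name = nm, layer = "unknown",
                     soma_position = NA_real_, stringsAsFactors = FALSE)
    if (!is.null(neurons)) {
        idx <- match(neurons$name, nr$name)
        if ("layer" %in% names(neurons)) {
            lay <- as.character(neurons$layer)
            lay[is.na(lay) | lay == ""] <- "unknown"
            nr$layer[idx] <- lay
        }
        if ("soma_position" %in% names(neurons))
            nr$soma_position[idx] <- as.numeric(neurons$soma_position)
    }
    new("Connectome", neurons = nr, edges = edges)
}

#' Accessors for Connectome objects
#'
#' @param x a [Connectome-class]
#' @param value replacement value: for `neuronLayers<-` a named character
#'   vector of layers, for `somaPositions<-` a named numeric vector of
#'   positions in [0,1].
#' @return \code{neuronNames}: character vector; \code{nNeurons}: integer;
#'   \code{edgeTable}, \code{neuronTable}: data.frame; \code{neuronLayers}:
#'   named character vector; \code{somaPositions}: named numeric vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("neuronNames", "Connectome", function(x) x@neurons$name)

#' @rdname accessors
#' @export
setMethod("nNeurons", "Connectome", function(x) nrow(x@neurons))

#' @rdname accessors
#' @export
setMethod("edgeTable", "Connectome", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("neuronTable", "Connectome", function(x) x@neurons)

#' @rdname accessors
#' @export
setMethod("neuronLayers", "Connectome", function(x)
    structure(x@neurons$layer, names = x@neurons$name))

#' @rdname accessors
#' @export
setMethod("somaPositions", "Connectome", function(x)
    structure(x@neurons$soma_position, names = x@neurons$name))

#' @rdname accessors
#' @export
setReplaceMethod("neuronLayers", "Connectome", function(x, value) {
    idx <- match(names(value), x@neurons$name)
    if (anyNA(idx))
        stop("unknown neuron(s): ", paste(names(value)[is.na(idx)], collapse = ", "))
    x@neurons$layer[idx] <- as.character(value)
    validObject(x)
    x
})

#' @rdname accessors
#' @export
setReplaceMethod("somaPositions", "Connectome", function(x, value) {
    idx <- match(names(value), x@neurons$name)
    if (anyNA(idx))
        stop("unknown neuron(s): ", paste(names(value)[is.na(idx)], collapse = ", "))
    x@neurons$soma_position[idx] <- as.numeric(value)
    validObject(x)
    x
})

#' Restrict a connectome to one synapse channel
#'
#' @param x a [Connectome-class]
#' @param channel \code{"all"}, \code{"chemical_only"} or \code{"gap_only"}
#' @return a [Connectome-class] with the same neuron table and only the
#'   edges of the requested channel. Used, e.g., to rerun the set analysis
#'   on the chemical-synapse network alone.
#' @export
filterChannel <- function(x, channel = c("all", "chemical_only", "gap_only")) {
    channel <- match.arg(channel)
    if (channel == "all") return(x)
    kind <- if (channel == "chemical_only") "chemical" else "gap"
    ed <- x@edges[x@edges$kind == kind, , drop = FALSE]
    rownames(ed) <- NULL
    initialize(x, edges = ed)
}

.checkNeuron <- function(x, nm) {
    bad <- setdiff(nm, x@neurons$name)
    if (length(bad))
        stop("unknown neuron(s): ", paste(bad, collapse = ", "))
    invisible(TRUE)
}
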
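#' Read a connectome edge list
#'
#' Three dialects are supported:
#' \describe{
#'   \item{\code{generic_csv}}{header \code{pre,post,kind,weight}; kind is
#'     \code{chemical} or \code{gap}; parallel records are summed and
#'     reciprocal gap records collapse to one junction (a weight mismatch
#'     between the two orders is an error).}
#'   \item{\code{wormatlas}}{the "neuronal wiring" spreadsheet layout with
#'     columns Neuron 1, Neuron 2, Type, Nbr (tab- or comma-separated).
#'     \code{S}/\code{Sp} rows become directed chemical edges pre to post;
#'     \code{R}/\code{Rp} rows are the mirrored records of the same synapses
#'     and are dropped; \code{EJ} rows become gap junctions; \code{NMJ} rows
#'     (neuromuscular targets, not neurons) are excluded. Exclusions and
#'     unknown type codes are reported via message/warning.}
#'   \item{\code{adjacency_matrix}}{a square numeric text matrix with neuron
#'     names as header row and first column; entry (i,j) > 0 is a chemical
#'     edge i to j of that weight. Gap junctions cannot be represented in
#'     this dialect.}
#' }
#'
#' @param path file to read
#' @param dialect one of \code{"generic_csv"}, \code{"wormatlas"},
#'   \code{"adjacency_matrix"}
#' @param neurons optional neuron table (see [makeConnectome()]); neurons
#'   listed there but absent from the file are kept as isolated nodes.
#' @return a [Connectome-class]
#' @seealso [writeEdgeList()], [readLayerTable()], [readPositionTable()]
#' @export
readEdgeList <- function(path,
                         dialect = c("generic_csv", "wormatlas",
                                     "adjacency_matrix"),
                         neurons = NULL) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    con <- switch(dialect,
        generic_csv = .readGenericCsv(path),
        wormatlas = .readWormatlas(path),
        adjacency_matrix = .readAdjacencyMatrix(path))
    makeConnectome(con, neurons = neurons)
}

.readGenericCsv <- function(path) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("pre", "post", "kind", "weight")
    if (!all(need %in% names(d)))
        stop("generic_csv requires header pre,post,kind,weight")
    bad <- which(!(d$kind %in% .EDGE_KINDS) | is.na(d$weight) |
                 d$pre == "" | d$post == "")
    if (length(bad))
        stop(sprintf("malformed row(s) at line(s) %s of %s",
                     paste(bad + 1L, collapse = ", "), path))
    d[need]
}

.readWormatlas <- function(path) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    d <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
    names(d) <- tolower(gsub("[^A-Za-z0-9]", "", names(d)))
    cols <- c("neuron1", "neuron2", "type", "nbr")
    if (!all(cols %in% names(d)))
        stop("wormatlas dialect requires columns Neuron 1, Neuron 2, Type, Nbr")
    d <- d[cols]
    names(d) <- c("pre", "post", "type", "weight")
    d$type <- toupper(trimws(d$type))

    nmj <- d$type == "NMJ" | d$post == "NMJ" | d$pre == "NMJ"
    if (any(nmj))
        message(sprintf("wormatlas: excluded %d neuromuscular (NMJ) rows",
                        sum(nmj)))
    d <- d[!nmj, , drop = FALSE]

    recv <- d$type %in% c("R", "RP")
    send <- d$type %in% c("S", "SP")
    ej <- d$type == "EJ"
    unk <- !(recv | send | ej)
    if (any(unk)) {
        warning(sprintf("wormatlas: skipped %d rows with unknown type code(s): %s",
                        sum(unk), paste(unique(d$type[unk]), collapse = ", ")))
    }
    chem <- d[send, c("pre", "post", "weight")]
    chem$kind <- "chemical"
    gap <- d[ej, c("pre", "post", "weight")]
    gap$kind <- "gap"
    out <- rbind(chem, gap)[, c("pre", "post", "kind", "weight")]
    message(sprintf(
        "wormatlas: %d neurons, %d chemical records (R/Rp mirrors dropped), %d gap records",
        length(unique(c(out$pre, out$post))), nrow(chem), nrow(gap)))
    out
}

.readAdjacencyMatrix <- function(path) {
    m <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1L,
                                     check.names = FALSE))
    if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
        stop("adjacency_matrix must be square with matching row/column names")
    idx <- which(m > 0, arr.ind = TRUE)
    idx <- idx[idx[, 1L] != idx[, 2L], , drop = FALSE]
    data.frame(pre = rownames(m)[idx[, 1L]],
               post = colnames(m)[idx[, 2L]],
               kind = "chemical",
               weight = as.integer(m[idx]),
               stringsAsFactors = FALSE)
}

#' Write a connectome as a generic CSV edge list
#'
#' Emits the \code{pre,post,kind,weight} format read back by
#' [readEdgeList()] with \code{dialect = "generic_csv"}; a write/read round
#' trip reproduces the edge multiset and neuron set (isolated neurons are
#' not representable in an edge list and must travel via the layer table).
#'
#' @param x a [Connectome-class]
#' @param path output file
#' @export
writeEdgeList <- function(x, path) {
    utils::write.csv(x@edges, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a neuron-to-layer table
#'
#' CSV with header \code{neuron,layer}; layers are sensory, inter, premotor
#' (aliases pre-motor/pre_motor/pm accepted), motor, or unknown.
#'
#' @param path file to read
#' @return named character vector of layers, suitable for
#'   \code{neuronLayers<-}
#' @export
readLayerTable <- function(path) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("neuron", "layer") %in% names(d)))
        stop("layer table requires header neuron,layer")
    lay <- tolower(trimws(d$layer))
    lay[lay %in% c("pre-motor", "pre_motor", "pm", "premotor")] <- "premotor"
    lay[lay %in% c("s", "sensory")] <- "sensory"
    lay[lay %in% c("i", "inter", "interneuron")] <- "inter"
    lay[lay %in% c("m", "motor")] <- "motor"
    bad <- !(lay %in% .LAYERS)
    if (any(bad))
        stop("unrecognized layer value(s): ", paste(unique(d$layer[bad]), collapse = ", "))
    structure(lay, names = d$neuron)
}

#' Read a neuron soma-position table
#'
#' CSV with header \code{neuron,position}; positions are scalars in [0,1]
#' along the anterior--posterior axis.
#'
#' @param path file to read
#' @return named numeric vector, suitable for \code{somaPositions<-}
#' @export
readPositionTable <- function(path) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("neuron", "position") %in% names(d)))
        stop("position table requires header neuron,position")
    structure(as.numeric(d$position), names = d$neuron)
}
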
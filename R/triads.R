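# Role-preserving triad taxonomy.
#
# A triad is (X, Y, Z) where {X,Y} is the focal pair and Z one of its common
# neighbors. The X-Y dyad is forward (X to Y only), reciprocal, or none; the
# X-Z and Y-Z dyads are forward (pair member to Z), backward (Z to pair
# member) or reciprocal -- never none, else Z would not be a common
# neighbor. With X and Y distinguishable when their dyad is directed and
# exchangeable otherwise, this gives 9 + 6 + 6 = 21 types.
#
# Ids follow one lexicographic rule: within each X-Y block, (xz, yz) is
# enumerated with state order forward < backward < reciprocal, X-dyad outer;
# for reciprocal/none X-Y the pair (xz, yz) is canonicalized (sorted) first.
# This rule reproduces all the anchored identities: #1 multi-output FFL,
# #2 multi-inter FFL, #5 multi-input FFL, #10 mutually regulating,
# #13 mutually regulated, #15 fully bidirectional.

.PAIR_STATES <- c("forward", "backward", "reciprocal")

.TRIAD_LABELS <- c("1" = "multi_output_FFL", "2" = "multi_inter_FFL",
                   "5" = "multi_input_FFL", "10" = "mutually_regulating",
                   "13" = "mutually_regulated", "15" = "fully_bidirectional")

#' Enumerate the 21 role-preserving triad types
#'
#' @return data.frame with columns \code{id} (1..21), \code{xy}
#'   (\code{forward}/\code{reciprocal}/\code{none}), \code{xz}, \code{yz}
#'   (\code{forward} = pair member to Z, \code{backward} = Z to pair member,
#'   or \code{reciprocal}; canonically sorted when X and Y are
#'   exchangeable), and \code{label} (named field-standard identities where
#'   one exists, \code{""} otherwise).
#' @examples
#' tt <- triadTypes()
#' table(tt$xy)  # 9 forward, 6 reciprocal, 6 none
#' @export
triadTypes <- function() {
    rows <- list()
    for (s1 in .PAIR_STATES) for (s2 in .PAIR_STATES)
        rows[[length(rows) + 1L]] <- c("forward", s1, s2)
    for (xy in c("reciprocal", "none"))
        for (i in 1:3) for (j in i:3)
            rows[[length(rows) + 1L]] <-
                c(xy, .PAIR_STATES[i], .PAIR_STATES[j])
    out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(out) <- c("xy", "xz", "yz")
    out$id <- seq_len(nrow(out))
    out$label <- ifelse(is.na(.TRIAD_LABELS[as.character(out$id)]), "",
                        .TRIAD_LABELS[as.character(out$id)])
    out[, c("id", "xy", "xz", "yz", "label")]
}

#' Classify one triad by its three dyad states
#'
#' The X-Y state may also be given as \code{"backward"} (Y to X only), in
#' which case roles are swapped to the canonical forward orientation. When
#' X and Y are exchangeable (reciprocal or unconnected pair) the (xz, yz)
#' pair is canonicalized, so \code{classifyTriad(xy, a, b)} equals
#' \code{classifyTriad(xy, b, a)} for those states.
#'
#' @param xy dyad state of the pair: \code{forward}, \code{backward},
#'   \code{reciprocal} or \code{none}
#' @param xz,yz dyad state of each pair member with Z, relative to the pair
#'   member (\code{forward} = member to Z); must not be \code{none}
#' @return one row of [triadTypes()]: id, dyad triple and label
#' @examples
#' classifyTriad("reciprocal", "forward", "forward")$id    # 10
#' classifyTriad("reciprocal", "backward", "backward")$id  # 13
#' @export
classifyTriad <- function(xy, xz, yz) {
    if (xz == "none" || yz == "none")
        stop("Z must be a common neighbor: xz and yz may not be 'none'")
    if (!xz %in% .PAIR_STATES || !yz %in% .PAIR_STATES)
        stop("invalid dyad state")
    if (xy == "backward") {
        xy <- "forward"
        tmp <- xz; xz <- yz; yz <- tmp
    }
    if (!xy %in% c("forward", "reciprocal", "none"))
        stop("invalid xy state: ", xy)
    if (xy != "forward") {
        r <- match(c(xz, yz), .PAIR_STATES)
        if (r[1L] > r[2L]) { tmp <- xz; xz <- yz; yz <- tmp }
    }
    tt <- triadTypes()
    tt[tt$xy == xy & tt$xz == xz & tt$yz == yz, , drop = FALSE]
}

# id lookup array indexed [xy in 1:3 (forward/reciprocal/none),
# xz in 1:3, yz in 1:3]; canonicalization baked in
.triadLookup <- function() {
    tt <- triadTypes()
    arr <- array(NA_integer_, dim = c(3L, 3L, 3L))
    xymap <- c(forward = 1L, reciprocal = 2L, none = 3L)
    for (k in seq_len(nrow(tt))) {
        i <- xymap[tt$xy[k]]
        a <- match(tt$xz[k], .PAIR_STATES)
        b <- match(tt$yz[k], .PAIR_STATES)
        arr[i, a, b] <- tt$id[k]
        if (i != 1L) arr[i, b, a] <- tt$id[k]
    }
    arr
}

#' Extract common-neighbor sets from a connectome
#'
#' A set is an unordered pair {X, Y} together with all of its common
#' neighbors, each classified into one of the 21 triad types. Pairs whose
#' dyad is backward are reoriented so X is the source of the X-Y link.
#'
#' @param x a [Connectome-class]
#' @param minNeighbors minimum number of common neighbors for a pair to
#'   form a set (the main analysis uses 5 to limit chance homogeneity in
#'   small sets)
#' @param connectedOnly keep only sets whose X-Y pair is itself connected
#' @param channel synapse channel for the whole analysis
#' @return list of \code{CommonNeighborSet} objects, each a list with
#'   elements \code{x}, \code{y}, \code{connected}, \code{xy} (dyad state),
#'   \code{n}, and \code{members} (data.frame with columns \code{z},
#'   \code{type})
#' @export
extractSets <- function(x, minNeighbors = 5L, connectedOnly = TRUE,
                        channel = c("all", "chemical_only", "gap_only")) {
    channel <- match.arg(channel)
    stopifnot(minNeighbors >= 1L)
    nm <- x@neurons$name
    U <- .undirAdj(x, channel)
    CODE <- .dyadCodes(x, channel)   # 0 none / 1 fwd / 2 bwd / 3 recip
    CC <- .commonCounts(U)
    lut <- .triadLookup()
    xymap <- c(3L, 1L, 1L, 2L)       # dyad code 0..3 -> lut xy index

    sets <- list()
    n <- length(nm)
    for (i in seq_len(n - 1L)) {
        js <- which(CC[i, ] >= minNeighbors)
        js <- js[js > i]
        for (j in js) {
            code <- CODE[i, j]
            if (connectedOnly && code == 0L) next
            # reorient so X is the source of a directed X-Y link
            if (code == 2L) { xi <- j; yi <- i } else { xi <- i; yi <- j }
            zs <- which(U[i, ] & U[j, ])
            zs <- zs[zs != i & zs != j]
            ids <- lut[cbind(xymap[code + 1L], CODE[xi, zs], CODE[yi, zs])]
            sets[[length(sets) + 1L]] <- structure(list(
                x = nm[xi], y = nm[yi],
                connected = code != 0L,
                xy = if (code == 0L) "none" else
                     if (code == 3L) "reciprocal" else "forward",
                n = length(zs),
                members = data.frame(z = nm[zs], type = ids,
                                     stringsAsFactors = FALSE)),
                class = "CommonNeighborSet")
        }
    }
    sets
}

#' @export
print.CommonNeighborSet <- function(x, ...) {
    cat(sprintf("CommonNeighborSet: {%s, %s} (%s), %d common neighbors\n",
                x$x, x$y, x$xy, x$n))
    tab <- table(x$members$type)
    cat("  triad types:", paste(sprintf("#%s x%d", names(tab), tab),
                                collapse = ", "), "\n")
    invisible(x)
}
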
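# Shared fixtures and independent oracles. Everything here is built in
# code at test time; the oracles deliberately avoid the package's own code
# paths.

# small random connectome with both channels
randomConnectome <- function(n = 20L, pChem = 0.15, pGap = 0.05,
                             seed = 1L, weights = FALSE) {
    set.seed(seed)
    nm <- sprintf("n%02d", seq_len(n))
    ut <- t(combn(n, 2L))
    chem <- NULL
    for (dir in 1:2) {
        keep <- runif(nrow(ut)) < pChem
        if (any(keep)) {
            a <- ut[keep, , drop = FALSE]
            if (dir == 2L) a <- a[, 2:1, drop = FALSE]
            chem <- rbind(chem, data.frame(
                pre = nm[a[, 1L]], post = nm[a[, 2L]], kind = "chemical",
                weight = if (weights) sample(1:5, nrow(a), TRUE) else 1L))
        }
    }
    keep <- runif(nrow(ut)) < pGap
    gap <- if (any(keep)) data.frame(
        pre = nm[ut[keep, 1L]], post = nm[ut[keep, 2L]], kind = "gap",
        weight = if (weights) sample(1:3, sum(keep), TRUE) else 1L) else NULL
    ed <- rbind(chem, gap)
    if (is.null(ed))
        ed <- data.frame(pre = nm[1L], post = nm[2L], kind = "chemical",
                         weight = 1L)
    makeConnectome(ed, neurons = data.frame(name = nm))
}

# ---- independent triad-classification oracle -------------------------------
# Re-derives the 21-type table from first principles: enumerate all dyad
# triples, canonicalize the exchangeable-pair cases by explicit double
# labeling, and number the canonical forms with the documented
# lexicographic rule (forward < backward < reciprocal, X-dyad outer,
# forward-XY block first, then reciprocal, then none).

oracleTriadTable <- function() {
    st <- c("forward", "backward", "reciprocal")
    rows <- expand.grid(xy = c("forward", "reciprocal", "none"),
                        xz = st, yz = st, stringsAsFactors = FALSE)
    canon <- function(xy, xz, yz) {
        if (xy == "forward") return(c(xy, xz, yz))
        # X and Y exchangeable: both labelings, keep the lexicographically
        # smaller (xz, yz) under the state order
        o <- match(c(xz, yz), st)
        if (o[1L] <= o[2L]) c(xy, xz, yz) else c(xy, yz, xz)
    }
    keys <- apply(rows, 1L, function(r) paste(canon(r[1], r[2], r[3]),
                                              collapse = "|"))
    uniq <- unique(keys)
    # order canonical forms: xy block, then xz, then yz
    parts <- do.call(rbind, strsplit(uniq, "|", fixed = TRUE))
    ord <- order(match(parts[, 1L], c("forward", "reciprocal", "none")),
                 match(parts[, 2L], st), match(parts[, 3L], st))
    ids <- seq_along(uniq)
    names(ids) <- uniq[ord]
    data.frame(xy = rows$xy, xz = rows$xz, yz = rows$yz,
               id = unname(ids[keys]), stringsAsFactors = FALSE)
}

# classify every triple of a connectome by brute force, returning one row
# per (unordered pair, common neighbor) incidence
oracleTriples <- function(con, minNeighbors = 1L, connectedOnly = FALSE) {
    nm <- neuronNames(con)
    ed <- edgeTable(con)
    link <- matrix(FALSE, length(nm), length(nm), dimnames = list(nm, nm))
    for (r in seq_len(nrow(ed))) {
        link[ed$pre[r], ed$post[r]] <- TRUE
        if (ed$kind[r] == "gap") link[ed$post[r], ed$pre[r]] <- TRUE
    }
    state <- function(a, b) {
        f <- link[a, b]; bwd <- link[b, a]
        if (f && bwd) "reciprocal" else if (f) "forward" else
        if (bwd) "backward" else "none"
    }
    tab <- oracleTriadTable()
    out <- list()
    n <- length(nm)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        zs <- nm[-c(i, j)]
        zs <- zs[vapply(zs, function(z)
            state(nm[i], z) != "none" && state(nm[j], z) != "none",
            logical(1L))]
        if (length(zs) < minNeighbors) next
        xy <- state(nm[i], nm[j])
        if (connectedOnly && xy == "none") next
        if (xy == "backward") { x <- nm[j]; y <- nm[i]; xy <- "forward" }
        else { x <- nm[i]; y <- nm[j] }
        for (z in zs) {
            id <- tab$id[tab$xy == xy & tab$xz == state(x, z) &
                         tab$yz == state(y, z)]
            out[[length(out) + 1L]] <- data.frame(
                x = x, y = y, z = z, id = id, stringsAsFactors = FALSE)
        }
    }
    if (length(out)) do.call(rbind, out) else
        data.frame(x = character(), y = character(), z = character(),
                   id = integer())
}

# ---- log-space combinatorial oracle for the hypergeometric tail -----------
oracleHGT <- function(k, n, K, N) {
    js <- k:min(n, K)
    terms <- lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)
    mx <- max(terms)
    exp(mx) * sum(exp(terms - mx))
}

# minimal pure set collection for homogeneity tests: sizes and type vectors
makeSets <- function(typeVectors, connected = TRUE) {
    lapply(seq_along(typeVectors), function(i) {
        tv <- typeVectors[[i]]
        structure(list(x = sprintf("X%02d", i), y = sprintf("Y%02d", i),
                       connected = connected,
                       xy = if (connected) "reciprocal" else "none",
                       n = length(tv),
                       members = data.frame(
                           z = sprintf("Z%02d_%02d", i, seq_along(tv)),
                           type = tv, stringsAsFactors = FALSE)),
                  class = "CommonNeighborSet")
    })
}
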
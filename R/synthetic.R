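# Synthetic connectome generators. These emulate the statistical structure
# the analysis assumes -- heavy-tail degrees, a tunable common-neighbor
# rule, planted homogeneous common-neighbor sets, bilateral L/R name pairs,
# layer labels and 1-D soma positions -- so the whole pipeline is testable
# without any real wiring data.

#' Erdos-Renyi random connectome
#'
#' Each ordered (directed) or unordered (undirected) node pair receives an
#' independent chemical edge of weight 1 with probability \code{p}. An
#' undirected draw is emitted as a reciprocal pair of directed chemical
#' edges, so dyad queries see it as bidirectional.
#'
#' @param n node count (>= 2)
#' @param p edge probability in [0, 1]
#' @param directed draw ordered pairs (default) or unordered pairs
#' @param seed integer seed
#' @return a [Connectome-class]
#' @export
generateER <- function(n, p, directed = TRUE, seed) {
    stopifnot(n >= 2L, p >= 0, p <= 1)
    nm <- sprintf("N%03d", seq_len(n))
    pairs <- withSeed(seed, {
        if (directed) {
            idx <- which(stats::runif(n * (n - 1L)) < p)
            i <- (idx - 1L) %/% (n - 1L) + 1L
            r <- (idx - 1L) %% (n - 1L) + 1L
            cbind(i, ifelse(r >= i, r + 1L, r))
        } else {
            ut <- utils::combn(n, 2L)
            keep <- stats::runif(ncol(ut)) < p
            sel <- ut[, keep, drop = FALSE]
            cbind(c(sel[1L, ], sel[2L, ]), c(sel[2L, ], sel[1L, ]))
        }
    })
    makeConnectome(.chemEdgeFrame(nm[pairs[, 1L]], nm[pairs[, 2L]]),
                   neurons = data.frame(name = nm))
}

# chemical edge frame that stays well-formed with zero rows
.chemEdgeFrame <- function(pre, post, weight = rep(1L, length(pre))) {
    data.frame(pre = pre, post = post,
               kind = rep("chemical", length(pre)),
               weight = as.integer(weight), stringsAsFactors = FALSE)
}

#' Clustered connectome with a tunable common-neighbor rule
#'
#' Nodes are split into \code{nClusters} latent groups; directed chemical
#' edges appear with probability \code{pIn} within a group and \code{pOut}
#' between groups. Raising \code{pIn/pOut} strengthens the common-neighbor
#' rule: same-group pairs accumulate both common neighbors and direct
#' links, so connection probability climbs with shared-neighbor count.
#'
#' @param n node count
#' @param nClusters number of groups
#' @param pIn,pOut within/between edge probabilities
#' @param seed integer seed
#' @return a [Connectome-class]
#' @export
generateClustered <- function(n, nClusters = 10L, pIn = 0.4, pOut = 0.01,
                              seed = 1L) {
    stopifnot(n >= nClusters, pIn >= 0, pIn <= 1, pOut >= 0, pOut <= 1)
    nm <- sprintf("N%03d", seq_len(n))
    grp <- rep_len(seq_len(nClusters), n)
    pairs <- withSeed(seed, {
        same <- outer(grp, grp, "==")
        prob <- ifelse(same, pIn, pOut)
        diag(prob) <- 0
        hit <- matrix(stats::runif(n * n), n, n) < prob
        which(hit, arr.ind = TRUE)
    })
    makeConnectome(.chemEdgeFrame(nm[pairs[, 1L]], nm[pairs[, 2L]]),
                   neurons = data.frame(name = nm))
}

#' Preferential-attachment connectome (heavy-tailed degrees)
#'
#' Wraps \code{igraph::sample_pa} to produce a scale-free directed graph,
#' the degree-heterogeneity knob of the generator suite: at equal density
#' its degree distribution has a much heavier tail than an Erdos-Renyi
#' draw.
#'
#' @param n node count
#' @param m edges added per step
#' @param power preferential-attachment exponent
#' @param seed integer seed
#' @return a [Connectome-class]
#' @export
generatePreferential <- function(n, m = 3L, power = 1, seed = 1L) {
    gr <- withSeed(seed, igraph::sample_pa(n, power = power, m = m,
                                           directed = TRUE))
    el <- igraph::as_edgelist(gr, names = FALSE)
    nm <- sprintf("N%03d", seq_len(n))
    makeConnectome(.chemEdgeFrame(nm[el[, 1L]], nm[el[, 2L]]),
                   neurons = data.frame(name = nm))
}

#' Specification of one family of planted homogeneous sets
#'
#' @param triadType triad type id in 1..21 (see [triadTypes()])
#' @param nZ number of common neighbors per set (>= 5, the pipeline's
#'   set-size threshold)
#' @param xLayer,yLayer,zLayer layer assignment of the planted roles
#' @param count how many such sets to plant
#' @return list of class \code{PlantedSetSpec}
#' @export
plantedSetSpec <- function(triadType, nZ = 6L, xLayer = "inter",
                           yLayer = xLayer, zLayer = "inter", count = 1L) {
    stopifnot(triadType %in% 1:21, nZ >= 5L, count >= 1L,
              all(c(xLayer, yLayer, zLayer) %in% .LAYERS))
    structure(list(triad_type = as.integer(triadType), n_z = as.integer(nZ),
                   x_layer = xLayer, y_layer = yLayer, z_layer = zLayer,
                   count = as.integer(count)),
              class = "PlantedSetSpec")
}

# channel rule for the planted bidirectional X-Y link, mirroring the
# empirical composition: mutually-regulating pairs are chemically coupled,
# mutually-regulated and fully bidirectional pairs are gap-coupled
.xyChannelRule <- function(triadType) {
    if (triadType %in% c(13L, 15L)) "gap" else "chemical"
}

# edges realizing one dyad state between two named nodes
.dyadEdges <- function(a, b, state, channel = "chemical") {
    switch(state,
        forward = data.frame(pre = a, post = b, kind = "chemical",
                             weight = 1L),
        backward = data.frame(pre = b, post = a, kind = "chemical",
                              weight = 1L),
        reciprocal = if (channel == "gap")
            data.frame(pre = min(a, b), post = max(a, b), kind = "gap",
                       weight = 1L)
        else
            data.frame(pre = c(a, b), post = c(b, a), kind = "chemical",
                       weight = 1L),
        none = data.frame(pre = character(), post = character(),
                          kind = character(), weight = integer()))
}

#' Connectome with planted homogeneous common-neighbor sets
#'
#' Plants every requested set exactly: all dyads of the requested triad
#' type are wired (the bidirectional X-Y link uses the per-type channel
#' rule: gap for types 13 and 15, chemical otherwise; Z dyads are
#' chemical), then an Erdos-Renyi background of directed chemical edges is
#' overlaid at probability \code{pBackground}, never deleting or
#' duplicating a planted edge. Nodes get uniform soma positions, a
#' \code{bilateralFraction} of each layer receives L/R partner names with
#' shared positions, and every node carries its layer label.
#'
#' @param nPerLayer named integer vector of node counts per layer, e.g.
#'   \code{c(sensory = 30, inter = 40, premotor = 20, motor = 30)}
#' @param planted list of [plantedSetSpec()] objects
#' @param pBackground background edge probability
#' @param bilateralFraction fraction of nodes given L/R paired names
#' @param seed integer seed; identical seeds give byte-identical output
#' @return list with elements \code{connectome} (a [Connectome-class]) and
#'   \code{truth} (class \code{SyntheticGroundTruth}: \code{planted} --
#'   list of x, y, z, triad_type --, \code{n_background_edges},
#'   \code{seed})
#' @export
generatePlanted <- function(nPerLayer = c(sensory = 30L, inter = 40L,
                                          premotor = 20L, motor = 30L),
                            planted = list(), pBackground = 0.02,
                            bilateralFraction = 0, seed = 1L) {
    stopifnot(all(names(nPerLayer) %in% .LAYERS),
              pBackground >= 0, pBackground <= 1,
              bilateralFraction >= 0, bilateralFraction <= 1)
    prefix <- c(sensory = "SN", inter = "IN", premotor = "PM",
                motor = "MN", unknown = "UN")
    withSeed(seed, {
        nodes <- lapply(names(nPerLayer), function(l) {
            k <- nPerLayer[[l]]
            nm <- sprintf("%s%03d", prefix[[l]], seq_len(k))
            npairs <- floor(bilateralFraction * k / 2)
            if (npairs > 0) {
                pr <- seq_len(2L * npairs)
                stems <- sprintf("%sB%02d", prefix[[l]],
                                 rep(seq_len(npairs), each = 2L))
                nm[pr] <- paste0(stems, rep(c("L", "R"), npairs))
            }
            pos <- stats::runif(k)
            if (npairs > 0) {
                even <- 2L * seq_len(npairs)
                pos[even] <- pos[even - 1L]   # partners share a position
            }
            data.frame(name = nm, layer = l, soma_position = pos,
                       stringsAsFactors = FALSE)
        })
        nr <- do.call(rbind, nodes)

        tt <- triadTypes()
        free <- lapply(split(nr$name, nr$layer), sample)
        take <- function(layer, k) {
            pool <- free[[layer]]
            if (length(pool) < k)
                stop(sprintf("infeasible planted spec: need %d free '%s' nodes, have %d",
                             k, layer, length(pool)))
            picked <- pool[seq_len(k)]
            free[[layer]] <<- pool[-seq_len(k)]
            picked
        }
        plantedEdges <- list()
        truthSets <- list()
        for (spec in planted) {
            row <- tt[tt$id == spec$triad_type, ]
            for (cnt in seq_len(spec$count)) {
                xy <- take(spec$x_layer, 1L)
                yy <- take(spec$y_layer, 1L)
                zz <- take(spec$z_layer, spec$n_z)
                ee <- list(.dyadEdges(xy, yy, row$xy,
                                      .xyChannelRule(spec$triad_type)))
                for (z in zz) {
                    ee <- c(ee, list(.dyadEdges(xy, z, row$xz),
                                     .dyadEdges(yy, z, row$yz)))
                }
                plantedEdges <- c(plantedEdges, ee)
                truthSets[[length(truthSets) + 1L]] <-
                    list(x = xy, y = yy, z = zz,
                         triad_type = spec$triad_type)
            }
        }
        pe <- if (length(plantedEdges)) do.call(rbind, plantedEdges) else
            data.frame(pre = character(), post = character(),
                       kind = character(), weight = integer())

        # background overlay: directed chemical edges, planted edges kept
        n <- nrow(nr)
        bg <- data.frame(pre = character(), post = character(),
                         kind = character(), weight = integer())
        if (pBackground > 0) {
            idx <- which(stats::runif(n * (n - 1L)) < pBackground)
            i <- (idx - 1L) %/% (n - 1L) + 1L
            r <- (idx - 1L) %% (n - 1L) + 1L
            j <- ifelse(r >= i, r + 1L, r)
            bg <- .chemEdgeFrame(nr$name[i], nr$name[j])
            pchem <- pe[pe$kind == "chemical", , drop = FALSE]
            dup <- paste(bg$pre, bg$post) %in% paste(pchem$pre, pchem$post)
            bg <- bg[!dup, , drop = FALSE]
        }
        con <- makeConnectome(rbind(pe, bg), neurons = nr)
    })
    truth <- structure(list(planted = truthSets,
                            n_background_edges = nrow(bg), seed = seed),
                       class = "SyntheticGroundTruth")
    list(connectome = con, truth = truth)
}

#' Write a synthetic bundle in the package's standard file formats
#'
#' Emits \code{edges.csv} (generic_csv dialect), \code{layers.csv},
#' \code{positions.csv} and \code{truth.json} into \code{dir}, so synthetic
#' data flow through the same readers as real data.
#'
#' @param x a [Connectome-class]
#' @param truth optional \code{SyntheticGroundTruth} sidecar
#' @param dir output directory (created if needed)
#' @return \code{dir}, invisibly
#' @export
writeSyntheticBundle <- function(x, truth = NULL, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeEdgeList(x, file.path(dir, "edges.csv"))
    nr <- x@neurons
    utils::write.csv(data.frame(neuron = nr$name, layer = nr$layer),
                     file.path(dir, "layers.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(data.frame(neuron = nr$name,
                                position = nr$soma_position),
                     file.path(dir, "positions.csv"), row.names = FALSE,
                     quote = FALSE)
    if (!is.null(truth))
        jsonlite::write_json(unclass(truth),
                             file.path(dir, "truth.json"),
                             auto_unbox = TRUE, digits = NA)
    invisible(dir)
}
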
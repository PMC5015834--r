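#' Run the full connectome analysis pipeline
#'
#' Orchestrates every stage in dependency order -- load or generate the
#' connectome, CNR curve and distance controls, null-ensemble slope tests,
#' common-neighbor set extraction, homogeneity assessment with shuffled-set
#' enrichment, layer localization and X-Y channel composition, and the
#' headline circuit-dynamics simulations -- and writes per-stage JSON/CSV
#' reports plus a coarse-grained summary table (per significant homogeneous
#' set type: its dominant layer pair and X-Y channel composition).
#'
#' @param config either a path to a YAML file or a list with entries:
#'   \describe{
#'     \item{input}{list \code{edges}, optional \code{layers},
#'       \code{positions} (file paths), optional \code{dialect}} or
#'     \item{synthetic}{list passed to [generatePlanted()] (fields
#'       \code{n_per_layer}, \code{planted} -- each a list with
#'       \code{triad_type}, \code{n_z}, layers, \code{count} --,
#'       \code{p_background}, \code{bilateral_fraction})}
#'     \item{thresholds}{optional list \code{min_neighbors} (5),
#'       \code{alpha} (0.05), \code{majority} (0.5),
#'       \code{enrichment_threshold} (0.005), \code{min_pairs_per_bin} (5)}
#'     \item{nulls}{optional list \code{n_networks} (100),
#'       \code{shuffles} (100)}
#'     \item{seed}{master seed (default 1); every random stage derives its
#'       own sub-seed from it}
#'   }
#' @param outDir output directory; reports and the verbatim config are
#'   written there
#' @return invisibly, a list with the stage results (\code{connectome},
#'   \code{cnr}, \code{distance}, \code{ensembles}, \code{sets},
#'   \code{homogeneity}, \code{enrichment}, \code{layers},
#'   \code{dynamics}, \code{summary})
#' @export
runPipeline <- function(config, outDir) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(config, file.path(outDir, "config.yaml"))
    th <- config$thresholds
    minNeighbors <- th$min_neighbors %||% 5L
    alpha <- th$alpha %||% 0.05
    majority <- th$majority %||% 0.5
    enrThreshold <- th$enrichment_threshold %||% 0.005
    minBin <- th$min_pairs_per_bin %||% 5L
    nNetworks <- config$nulls$n_networks %||% 100L
    nShuffles <- config$nulls$shuffles %||% 100L
    seed <- config$seed %||% 1L
    seeds <- deriveSeeds(seed, 8L)

    con <- .pipelineInput(config, seeds[1L])
    out <- list(connectome = con)
    saveJSON <- function(obj, name)
        jsonlite::write_json(obj, file.path(outDir, name),
                             auto_unbox = TRUE, digits = NA, force = TRUE,
                             na = "null")

    cnr <- cnrCurve(con, minPairsPerBin = minBin)
    out$cnr <- cnr
    saveJSON(list(bins = cnr$bins, fit = cnr$fit), "cnr.json")

    havePos <- !anyNA(somaPositions(con))
    if (havePos) {
        out$distance <- list(
            cn = distanceAnalysis(con, "cn_vs_distance", "connected_pairs"),
            connectivity = distanceAnalysis(con, "connectivity_vs_distance"))
        saveJSON(lapply(out$distance, unclass), "distance.json")
    } else {
        message("pipeline: soma positions unavailable, distance stage skipped")
        out$distance <- NULL
    }

    out$ensembles <- list(
        degree_preserving = ensembleSlopeTest(
            con, "degree_preserving", nNetworks = nNetworks,
            seed = seeds[2L], minPairsPerBin = minBin),
        erdos_renyi = ensembleSlopeTest(
            con, "erdos_renyi", nNetworks = nNetworks,
            seed = seeds[3L], minPairsPerBin = minBin))
    saveJSON(lapply(out$ensembles, function(e)
        e[c("real_slope", "z", "p", "generator", "n_networks")]),
        "ensembles.json")

    sets <- extractSets(con, minNeighbors = minNeighbors,
                        connectedOnly = TRUE)
    out$sets <- sets
    if (length(sets) == 0L)
        stop("pipeline: no common-neighbor sets at the configured threshold")
    enr <- enrichmentTests(sets, R = nShuffles, seed = seeds[4L],
                           alpha = alpha, majorityFraction = majority)
    hom <- enr$results
    out$homogeneity <- hom
    out$enrichment <- enr
    saveJSON(list(n_sets = length(sets),
                  n_homogeneous = sum(hom$homogeneous),
                  synapse_coverage = synapseCoverage(con, hom),
                  bilateral_ratio = as.list(bilateralRatio(hom)),
                  overall = enr$overall, per_type = enr$per_type),
             "homogeneity.json")
    utils::write.csv(as.data.frame(hom),
                     file.path(outDir, "homogeneity.csv"),
                     row.names = FALSE)

    haveLayers <- any(neuronLayers(con) != "unknown")
    if (haveLayers) {
        out$layers <- list(
            histogram = layerPairHistogram(con, hom),
            enrichment = layerEnrichment(con, hom,
                                         threshold = enrThreshold),
            composition = xySynapseComposition(con, hom),
            xy_vs_z = xyVsZLayerDistribution(con, hom))
        saveJSON(out$layers, "layers.json")
    } else {
        message("pipeline: no layer assignment, layer stage skipped")
        out$layers <- NULL
    }

    out$dynamics <- .headlineDynamics()
    saveJSON(out$dynamics, "dynamics.json")

    out$summary <- .pipelineSummary(out, enrThreshold)
    utils::write.csv(out$summary, file.path(outDir, "summary.csv"),
                     row.names = FALSE)
    invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.pipelineInput <- function(config, seed) {
    if (!is.null(config$input)) {
        inp <- config$input
        neurons <- NULL
        if (!is.null(inp$layers)) {
            lay <- readLayerTable(inp$layers)
            neurons <- data.frame(name = names(lay), layer = unname(lay))
        }
        con <- readEdgeList(inp$edges, dialect = inp$dialect %||%
                            "generic_csv", neurons = neurons)
        if (!is.null(inp$positions)) {
            pos <- readPositionTable(inp$positions)
            pos <- pos[names(pos) %in% neuronNames(con)]
            somaPositions(con) <- pos
        }
        con
    } else if (!is.null(config$synthetic)) {
        syn <- config$synthetic
        planted <- lapply(syn$planted, function(ps)
            plantedSetSpec(ps$triad_type, ps$n_z %||% 6L,
                           ps$x_layer %||% "inter",
                           ps$y_layer %||% ps$x_layer %||% "inter",
                           ps$z_layer %||% "inter", ps$count %||% 1L))
        npl <- unlist(syn$n_per_layer) %||%
            c(sensory = 30L, inter = 40L, premotor = 20L, motor = 30L)
        generatePlanted(nPerLayer = npl, planted = planted,
                        pBackground = syn$p_background %||% 0.02,
                        bilateralFraction = syn$bilateral_fraction %||% 0,
                        seed = seed)$connectome
    } else stop("config needs an 'input' or 'synthetic' block")
}

# the two headline circuit simulations, connected vs unconnected twins
.headlineDynamics <- function() {
    amp <- function(connected) {
        sim <- simulateCircuit(buildCircuit("mutually_regulating",
                                            connected = connected))
        as.list(amplificationMetrics(sim, "Z1", threshold = 0.1))
    }
    coord <- function(connected) {
        spec <- buildCircuit("mutually_regulated", connected = connected,
                             betaOverride = c("Z1->X" = 2),
                             KOverride = c("Z1->X" = 10))
        coordinationMetric(simulateCircuit(spec), "X", "Y")
    }
    list(mutually_regulating = list(connected = amp(TRUE),
                                    unconnected = amp(FALSE)),
         mutually_regulated = list(connected = coord(TRUE),
                                   unconnected = coord(FALSE)))
}

.pipelineSummary <- function(out, enrThreshold) {
    pt <- out$enrichment$per_type
    sig <- pt[pt$significant & pt$real > pt$null_mean, , drop = FALSE]
    if (nrow(sig) == 0L)
        return(data.frame(set_type = integer(), label = character(),
                          n_homogeneous = integer(),
                          dominant_layer_pair = character(),
                          xy_channel = character()))
    tt <- triadTypes()
    rows <- lapply(sig$type, function(tp) {
        lp <- NA_character_
        if (!is.null(out$layers)) {
            pr <- out$layers$histogram$pairs
            pr <- pr[pr$set_type == tp, , drop = FALSE]
            if (nrow(pr)) lp <- pr$layer_pair[which.max(pr$count)]
        }
        ch <- NA_character_
        if (!is.null(out$layers)) {
            cp <- out$layers$composition
            cp <- cp[cp$set_type == tp, , drop = FALSE]
            if (nrow(cp))
                ch <- if (cp$n_gap > cp$n_chemical) "gap" else
                      if (cp$n_gap < cp$n_chemical) "chemical" else "mixed"
        }
        data.frame(set_type = tp, label = tt$label[tt$id == tp],
                   n_homogeneous = sig$real[sig$type == tp],
                   dominant_layer_pair = lp, xy_channel = ch,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
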
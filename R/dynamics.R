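# Graded-potential dynamics of the two headline circuit types. C. elegans
# neurons respond with graded (non-spiking) potentials, so chemical
# transmission is modeled as a saturating Michaelis-Menten drive and gap
# junctions as linear diffusive coupling:
#
#   dA_i/dt = sum_chem sign * beta * A_pre / (K + A_pre)
#           + sum_gap g * (A_j - A_i) + s_i(t) - alpha * A_i

#' Build a mutually-regulating or mutually-regulated circuit
#'
#' \code{mutually_regulating} (type #10): X and Y synapse each other
#' chemically (when \code{connected}) and both are presynaptic to every Z.
#' \code{mutually_regulated} (type #13): X and Y share a gap junction
#' (when \code{connected}) and both are postsynaptic to every Z. Defaults
#' are alpha = beta = K = 1 and gap coupling g = 1.
#'
#' Stimulus defaults: a rectangular pulse of amplitude 1 and duration 1
#' time unit to X (mutually regulating), or staggered pulses to Z1 and Z2
#' offset by half a pulse width (mutually regulated, emulating
#' unsynchronized upstream drive).
#'
#' @param setType \code{"mutually_regulating"} or
#'   \code{"mutually_regulated"}
#' @param connected include the X-Y link
#' @param nZ number of Z units (>= 1)
#' @param alpha,beta,K,g default rate constants (all > 0): decay, maximal
#'   synaptic rate, half-saturation, gap coupling
#' @param betaOverride,KOverride,signOverride named numeric vectors keyed
#'   \code{"PRE->POST"} overriding individual chemical links (sign -1
#'   makes a link inhibitory)
#' @param stimulus optional data.frame \code{node}, \code{onset},
#'   \code{duration}, \code{amplitude} replacing the default schedule
#' @return list of class \code{CircuitSpec} with elements \code{nodes},
#'   \code{chem} (pre, post, beta, K, sign), \code{gap} (a, b, g),
#'   \code{alpha} (named per node), \code{stimulus}
#' @export
buildCircuit <- function(setType = c("mutually_regulating",
                                     "mutually_regulated"),
                         connected = TRUE, nZ = 2L,
                         alpha = 1, beta = 1, K = 1, g = 1,
                         betaOverride = NULL, KOverride = NULL,
                         signOverride = NULL, stimulus = NULL) {
    setType <- match.arg(setType)
    stopifnot(nZ >= 1L, alpha > 0, beta > 0, K > 0, g > 0)
    zs <- paste0("Z", seq_len(nZ))
    nodes <- c("X", "Y", zs)
    chem <- data.frame(pre = character(), post = character())
    gap <- data.frame(a = character(), b = character(), g = numeric())
    if (setType == "mutually_regulating") {
        if (connected)
            chem <- data.frame(pre = c("X", "Y"), post = c("Y", "X"))
        chem <- rbind(chem,
                      data.frame(pre = rep(c("X", "Y"), each = nZ),
                                 post = rep(zs, 2L)))
        if (is.null(stimulus))
            stimulus <- data.frame(node = "X", onset = 1, duration = 1,
                                   amplitude = 1)
    } else {
        if (connected)
            gap <- data.frame(a = "X", b = "Y", g = g)
        chem <- data.frame(pre = rep(zs, each = 2L),
                           post = rep(c("X", "Y"), nZ))
        if (is.null(stimulus))
            stimulus <- data.frame(node = c("Z1", "Z2")[seq_len(min(2L, nZ))],
                                   onset = c(1, 1.5)[seq_len(min(2L, nZ))],
                                   duration = 1, amplitude = 1)
    }
    chem$beta <- beta
    chem$K <- K
    chem$sign <- 1
    key <- paste0(chem$pre, "->", chem$post)
    applyOverride <- function(col, ov) {
        if (is.null(ov)) return(chem[[col]])
        bad <- setdiff(names(ov), key)
        if (length(bad)) stop("override for absent link(s): ",
                              paste(bad, collapse = ", "))
        v <- chem[[col]]
        v[match(names(ov), key)] <- unname(ov)
        v
    }
    chem$beta <- applyOverride("beta", betaOverride)
    chem$K <- applyOverride("K", KOverride)
    chem$sign <- applyOverride("sign", signOverride)
    structure(list(nodes = nodes, chem = chem, gap = gap,
                   alpha = structure(rep(alpha, length(nodes)),
                                     names = nodes),
                   stimulus = stimulus, set_type = setType,
                   connected = connected),
              class = "CircuitSpec")
}

#' Integrate circuit dynamics
#'
#' Fixed-step fourth-order Runge-Kutta integration (via
#' \pkg{deSolve}) from the all-zero initial state. Fixed stepping keeps
#' trajectories exactly reproducible; convergence should be checked by
#' halving \code{dt} (the suite does).
#'
#' @param spec a \code{CircuitSpec} from [buildCircuit()]
#' @param tEnd end time (> 0)
#' @param dt time step (default 0.01)
#' @return list of class \code{SimulationResult}: \code{time} (vector),
#'   \code{activity} (matrix time x node), \code{spec}, \code{dt}
#' @export
simulateCircuit <- function(spec, tEnd = 30, dt = 0.01) {
    stopifnot(inherits(spec, "CircuitSpec"), tEnd > 0, dt > 0)
    nodes <- spec$nodes
    n <- length(nodes)
    pre <- match(spec$chem$pre, nodes)
    post <- match(spec$chem$post, nodes)
    ga <- match(spec$gap$a, nodes)
    gb <- match(spec$gap$b, nodes)
    stim <- spec$stimulus
    stimNode <- match(stim$node, nodes)
    if (anyNA(stimNode)) stop("stimulus names unknown node(s)")
    beta <- spec$chem$beta; Khalf <- spec$chem$K; sgn <- spec$chem$sign
    gcoef <- spec$gap$g
    alpha <- unname(spec$alpha)

    deriv <- function(t, A, parms) {
        dA <- -alpha * A
        if (length(pre)) {
            drive <- sgn * beta * A[pre] / (Khalf + A[pre])
            for (e in seq_along(post)) dA[post[e]] <- dA[post[e]] + drive[e]
        }
        if (length(ga)) {
            flow <- gcoef * (A[gb] - A[ga])
            for (e in seq_along(ga)) {
                dA[ga[e]] <- dA[ga[e]] + flow[e]
                dA[gb[e]] <- dA[gb[e]] - flow[e]
            }
        }
        if (nrow(stim)) {
            on <- t >= stim$onset & t < stim$onset + stim$duration
            if (any(on)) for (s in which(on))
                dA[stimNode[s]] <- dA[stimNode[s]] + stim$amplitude[s]
        }
        list(dA)
    }
    times <- seq(0, tEnd, by = dt)
    sol <- deSolve::ode(y = structure(rep(0, n), names = nodes),
                        times = times, func = deriv, parms = NULL,
                        method = "rk4")
    structure(list(time = sol[, 1L],
                   activity = sol[, -1L, drop = FALSE],
                   spec = spec, dt = dt),
              class = "SimulationResult")
}

#' Peak and supra-threshold duration of one unit's trajectory
#'
#' \code{peak} is the trajectory maximum; \code{time_above} is the measure
#' of the time grid on which activity exceeds \code{threshold}.
#'
#' @param result a \code{SimulationResult}
#' @param node node name
#' @param threshold activation threshold
#' @return named numeric vector \code{c(peak = ..., time_above = ...)}
#' @export
amplificationMetrics <- function(result, node, threshold) {
    A <- result$activity[, node]
    c(peak = max(A), time_above = sum(A > threshold) * result$dt)
}

#' Maximal activity divergence between two units
#'
#' \code{max_t |A_a(t) - A_b(t)|}: small values mean the two units are
#' activated evenly (coordinated), as gap coupling promotes.
#'
#' @param result a \code{SimulationResult}
#' @param a,b node names
#' @return non-negative scalar
#' @export
coordinationMetric <- function(result, a, b) {
    max(abs(result$activity[, a] - result$activity[, b]))
}
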
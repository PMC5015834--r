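test_that("circuit construction wires the two set types correctly", {
    mr <- buildCircuit("mutually_regulating", connected = TRUE, nZ = 2L)
    expect_equal(nrow(mr$chem), 6L)   # X<->Y plus 2 links to each Z
    expect_equal(nrow(mr$gap), 0L)
    mru <- buildCircuit("mutually_regulating", connected = FALSE, nZ = 2L)
    expect_equal(nrow(mru$chem), 4L)

    md <- buildCircuit("mutually_regulated", connected = TRUE, nZ = 2L)
    expect_equal(nrow(md$chem), 4L)   # Z_i -> X, Z_i -> Y
    expect_equal(nrow(md$gap), 1L)
    expect_true(all(md$chem$pre %in% c("Z1", "Z2")))
    mdu <- buildCircuit("mutually_regulated", connected = FALSE, nZ = 2L)
    expect_equal(nrow(mdu$gap), 0L)
    expect_equal(nrow(mdu$chem), 4L)

    # asymmetric overrides stored exactly
    sp <- buildCircuit("mutually_regulated", connected = TRUE, nZ = 2L,
                       betaOverride = c("Z1->X" = 2),
                       KOverride = c("Z1->X" = 10))
    key <- paste0(sp$chem$pre, "->", sp$chem$post)
    expect_equal(sp$chem$beta[key == "Z1->X"], 2)
    expect_equal(sp$chem$beta[key == "Z1->Y"], 1)
    expect_equal(sp$chem$K[key == "Z1->X"], 10)
    expect_equal(sp$chem$K[key == "Z1->Y"], 1)
    expect_error(buildCircuit("mutually_regulated",
                              betaOverride = c("X->Q" = 2)), "absent")
    expect_error(buildCircuit("mutually_regulating", nZ = 0L))
})

test_that("fixed points and closed forms of the ODE are reproduced", {
    # zero stimulus, zero state -> identically zero
    spec <- buildCircuit("mutually_regulating",
                         stimulus = data.frame(node = "X", onset = 0,
                                               duration = 0, amplitude = 0))
    sim <- simulateCircuit(spec, tEnd = 5, dt = 0.01)
    expect_true(all(sim$activity == 0))

    # single node, constant input: A -> s/alpha
    one <- structure(list(nodes = "X",
                          chem = data.frame(pre = character(),
                                            post = character(),
                                            beta = numeric(), K = numeric(),
                                            sign = numeric()),
                          gap = data.frame(a = character(), b = character(),
                                           g = numeric()),
                          alpha = c(X = 2),
                          stimulus = data.frame(node = "X", onset = 0,
                                                duration = 100,
                                                amplitude = 3)),
                     class = "CircuitSpec")
    simA <- simulateCircuit(one, tEnd = 10, dt = 0.01)
    expect_equal(unname(simA$activity[nrow(simA$activity), "X"]), 1.5,
                 tolerance = 1e-6)

    # pure gap pair with no decay: states converge to the mean, sum fixed
    pair <- structure(list(nodes = c("X", "Y"),
                           chem = one$chem,
                           gap = data.frame(a = "X", b = "Y", g = 1),
                           alpha = c(X = 1e-12, Y = 1e-12),
                           stimulus = data.frame(node = "X", onset = 0,
                                                 duration = 0.5,
                                                 amplitude = 4)),
                      class = "CircuitSpec")
    simP <- simulateCircuit(pair, tEnd = 20, dt = 0.005)
    A <- simP$activity
    total <- rowSums(A)
    after <- simP$time > 0.5
    expect_lt(diff(range(total[after])), 1e-4)   # conserved after the pulse
    expect_equal(unname(A[nrow(A), "X"]), unname(A[nrow(A), "Y"]),
                 tolerance = 1e-6)
})

test_that("trajectories stay non-negative and converge under step halving", {
    spec <- buildCircuit("mutually_regulating", connected = TRUE)
    s1 <- simulateCircuit(spec, tEnd = 20, dt = 0.02)
    s2 <- simulateCircuit(spec, tEnd = 20, dt = 0.01)
    expect_true(all(s1$activity >= 0))
    shared <- s2$activity[seq(1L, nrow(s2$activity), by = 2L), ]
    # rectangular stimulus edges limit accuracy to O(dt) locally, so the
    # step-halving error is dominated by the pulse onset
    e1 <- max(abs(s1$activity - shared))
    expect_lt(e1, 5e-3)
    s4 <- simulateCircuit(spec, tEnd = 20, dt = 0.005)
    shared2 <- s4$activity[seq(1L, nrow(s4$activity), by = 2L), ]
    e2 <- max(abs(s2$activity - shared2))
    expect_lt(e2, e1)   # refinement converges

    spec13 <- buildCircuit("mutually_regulated", connected = TRUE)
    s3 <- simulateCircuit(spec13, tEnd = 20, dt = 0.02)
    expect_true(all(s3$activity >= 0))
})

test_that("amplification metrics: analytic triangle and flat-zero cases", {
    flat <- list(time = seq(0, 1, 0.1),
                 activity = matrix(0, 11L, 1L,
                                   dimnames = list(NULL, "X")),
                 dt = 0.1)
    class(flat) <- "SimulationResult"
    expect_equal(amplificationMetrics(flat, "X", 0.5),
                 c(peak = 0, time_above = 0))
    # triangle ramp 0..1..0 over [0,2], threshold 0.5 -> above on (1, 3)/2
    tg <- seq(0, 2, 0.001)
    tri <- ifelse(tg <= 1, tg, 2 - tg)
    simT <- structure(list(time = tg,
                           activity = matrix(tri, ncol = 1L,
                                             dimnames = list(NULL, "Z")),
                           dt = 0.001), class = "SimulationResult")
    m <- amplificationMetrics(simT, "Z", 0.5)
    expect_equal(unname(m["peak"]), 1)
    expect_equal(unname(m["time_above"]), 1, tolerance = 0.01)
    # coordination metric arithmetic
    two <- structure(list(time = tg,
                          activity = cbind(A = rep(1, length(tg)),
                                           B = rep(3, length(tg))),
                          dt = 0.001), class = "SimulationResult")
    expect_equal(coordinationMetric(two, "A", "B"), 2)
    expect_equal(coordinationMetric(two, "A", "A"), 0)
})

test_that("positive X-Y feedback amplifies and prolongs the Z response", {
    run <- function(connected)
        simulateCircuit(buildCircuit("mutually_regulating",
                                     connected = connected),
                        tEnd = 30, dt = 0.01)
    on <- run(TRUE); off <- run(FALSE)
    for (thr in c(0.05, 0.1, 0.2)) {
        mOn <- amplificationMetrics(on, "Z1", thr)
        mOff <- amplificationMetrics(off, "Z1", thr)
        expect_gt(mOn["peak"], mOff["peak"])
        expect_gt(mOn["time_above"], mOff["time_above"])
    }
    # direction holds across pulse amplitudes and durations
    for (amp in c(0.5, 2)) for (dur in c(0.5, 2)) {
        st <- data.frame(node = "X", onset = 1, duration = dur,
                         amplitude = amp)
        a <- simulateCircuit(buildCircuit("mutually_regulating",
                                          connected = TRUE,
                                          stimulus = st), 30, 0.01)
        b <- simulateCircuit(buildCircuit("mutually_regulating",
                                          connected = FALSE,
                                          stimulus = st), 30, 0.01)
        expect_gt(max(a$activity[, "Z1"]), max(b$activity[, "Z1"]))
    }
})

test_that("gap coupling evens out X/Y activity, monotonically in g", {
    metric <- function(connected, g = 1) {
        spec <- buildCircuit("mutually_regulated", connected = connected,
                             g = g,
                             betaOverride = c("Z1->X" = 2),
                             KOverride = c("Z1->X" = 10))
        coordinationMetric(simulateCircuit(spec, 30, 0.01), "X", "Y")
    }
    expect_lt(metric(TRUE), metric(FALSE))
    gs <- c(0.25, 0.5, 1, 2, 4)
    vals <- vapply(gs, function(g) metric(TRUE, g), numeric(1L))
    expect_true(all(diff(vals) <= 1e-9))   # weakly decreasing in g
})

test_that("a negative feedback link integrates without blowing up", {
    spec <- buildCircuit("mutually_regulating", connected = TRUE,
                         signOverride = c("Y->X" = -1))
    sim <- simulateCircuit(spec, tEnd = 20, dt = 0.01)
    expect_true(all(is.finite(sim$activity)))
})
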
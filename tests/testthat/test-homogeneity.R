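test_that("hypergeometric tail: closed forms and the combinatorial oracle", {
    expect_equal(hgtPValue(0, 5, 50, 100), 1)
    # all draws must be successes and K = n: single admissible draw
    expect_equal(hgtPValue(4, 4, 4, 30), 1 / choose(30, 4))
    expect_equal(hgtPValue(5, 5, 50, 100), choose(50, 5) / choose(100, 5))
    expect_equal(hgtPValue(5, 5, 50, 100), 0.02814, tolerance = 2e-4)
    expect_error(hgtPValue(6, 5, 50, 100), "inconsistent")
    expect_error(hgtPValue(3, 5, 2, 100), "inconsistent")

    set.seed(101)
    for (i in 1:300) {
        N <- sample(10:400, 1L)
        K <- sample.int(N, 1L)
        n <- sample.int(N, 1L)
        k <- sample(0:min(n, K), 1L)
        expect_equal(hgtPValue(k, n, K, N), oracleHGT(k, n, K, N),
                     tolerance = 1e-12)
    }
})

test_that("hypergeometric tail matches Monte-Carlo urn sampling within 3 SE", {
    set.seed(202)
    B <- 20000L
    for (case in list(c(3, 6, 20, 60), c(5, 8, 15, 40), c(2, 10, 30, 90))) {
        k <- case[1]; n <- case[2]; K <- case[3]; N <- case[4]
        draws <- replicate(B, sum(sample(rep(c(1L, 0L), c(K, N - K)), n)))
        phat <- mean(draws >= k)
        se <- sqrt(phat * (1 - phat) / B)
        expect_lt(abs(hgtPValue(k, n, K, N) - phat), 3 * se + 1e-12)
    }
})

test_that("tail probability is non-increasing in k", {
    set.seed(33)
    for (i in 1:50) {
        N <- sample(20:200, 1L); K <- sample.int(N, 1L)
        n <- sample.int(N, 1L)
        ks <- 0:min(n, K)
        p <- hgtPValue(ks, n, K, N)
        expect_true(all(diff(p) <= 1e-14))
    }
})

test_that("homogeneity combines hypergeometric evidence with the majority rule", {
    # one pure set of a globally rare type -> homogeneous
    sets <- makeSets(c(list(rep(10L, 6L)),
                       replicate(8L, sample(c(1L, 2L, 5L), 6L, TRUE),
                                 simplify = FALSE)))
    res <- assessHomogeneity(sets)
    expect_s3_class(res, "homogeneityResults")
    expect_equal(res$dominant_type[1L], 10L)
    expect_true(res$homogeneous[1L])
    expect_equal(res$N, rep(sum(res$n), nrow(res)))

    # overwhelming p but minority share -> not homogeneous
    big <- makeSets(c(list(c(rep(10L, 4L), c(1L, 2L, 5L, 1L, 2L, 5L))),
                      replicate(20L, rep(c(1L, 2L, 5L), 4L),
                                simplify = FALSE)))
    rb <- assessHomogeneity(big)
    expect_equal(rb$dominant_type[1L], 10L)
    expect_equal(rb$k[1L] / rb$n[1L], 0.4)
    expect_lt(rb$p_hgt[1L], 0.01)
    expect_false(rb$majority[1L])
    expect_false(rb$homogeneous[1L])

    # invariance to set ordering
    perm <- c(5L, 1L, 4L, 2L, 3L, 9L, 6L, 8L, 7L)
    res2 <- assessHomogeneity(sets[perm])
    expect_equal(res$p_hgt[perm], res2$p_hgt)
    expect_equal(res$homogeneous[perm], res2$homogeneous)

    expect_error(assessHomogeneity(list()), "no sets")
    mixed <- c(makeSets(list(rep(1L, 5L)), connected = TRUE),
               makeSets(list(rep(1L, 5L)), connected = FALSE))
    expect_error(assessHomogeneity(mixed), "connectivity class")
})

test_that("set shuffling conserves sizes and the global type multiset", {
    sets <- makeSets(list(rep(10L, 7L), c(1L, 1L, 2L, 5L, 5L),
                          rep(13L, 6L), c(15L, 15L, 14L, 13L, 12L, 11L)))
    for (seed in 1:20) {
        sh <- shuffleSets(sets, seed = seed)
        expect_equal(vapply(sh, function(s) s$n, integer(1L)),
                     vapply(sets, function(s) s$n, integer(1L)))
        expect_equal(sort(unlist(lapply(sh, function(s) s$members$type))),
                     sort(unlist(lapply(sets, function(s) s$members$type))))
    }
    # a single set keeps its composition
    one <- shuffleSets(sets[1L], seed = 3L)
    expect_equal(sort(one[[1L]]$members$type),
                 sort(sets[[1L]]$members$type))
})

test_that("shuffled counts follow the exact hypergeometric distribution", {
    # two sets of 5 with disjoint pure types: the count of type A in the
    # first set is hypergeometric(N = 10, K = 5, n = 5)
    sets <- makeSets(list(rep(1L, 5L), rep(2L, 5L)))
    B <- 10000L
    counts <- vapply(seq_len(B), function(b)
        sum(shuffleSets(sets, seed = b)[[1L]]$members$type == 1L),
        integer(1L))
    obs <- tabulate(counts + 1L, 6L)
    expected <- stats::dhyper(0:5, 5, 5, 5) * B
    chisq <- sum((obs - expected)^2 / expected)
    # 5 df; 99.9% quantile ~ 20.5
    expect_lt(chisq, qchisq(0.999, df = 5))
})

test_that("enrichment flags planted types and passes null self-consistency", {
    set.seed(77)
    noise <- replicate(25L, sample(c(1L, 2L, 5L, 16L), 6L, TRUE),
                       simplify = FALSE)
    sets <- makeSets(c(replicate(8L, rep(10L, 6L), simplify = FALSE), noise))
    nc <- enrichmentTests(sets, R = 100L, seed = 9L)
    pt <- nc$per_type
    expect_true(pt$significant[pt$type == 10L])
    expect_gt(pt$z[pt$type == 10L], 0)
    expect_false(any(pt$significant[pt$type != 10L] &
                     pt$real[pt$type != 10L] > pt$null_mean[pt$type != 10L]))
    expect_gt(nc$overall$real, nc$overall$null_mean)

    # a shuffle of the real sets should mostly not be called enriched;
    # the z-test's normal approximation on small discrete counts is mildly
    # anti-conservative, so the family-wise error exceeds the nominal 5%
    ok <- 0L
    for (rep in 1:20) {
        control <- shuffleSets(sets, seed = 500L + rep)
        ncc <- enrichmentTests(control, R = 100L, seed = rep)
        enriched <- ncc$per_type$significant &
            ncc$per_type$real > ncc$per_type$null_mean
        if (!any(enriched)) ok <- ok + 1L
    }
    expect_gte(ok, 16L)
})

test_that("synapse coverage and bilateral ratios compute as defined", {
    # connectome that is exactly one planted set -> coverage 1
    g <- generatePlanted(planted = list(plantedSetSpec(10, nZ = 5)),
                         pBackground = 0, seed = 21L)
    sets <- extractSets(g$connectome, 5L)
    res <- assessHomogeneity(sets)
    res$homogeneous <- TRUE   # coverage is defined given the flags
    expect_equal(synapseCoverage(g$connectome, res), 1)
    res$homogeneous <- FALSE
    expect_equal(synapseCoverage(g$connectome, res), 0)

    # toy arithmetic: covered weight 7 of total 10
    con <- makeConnectome(data.frame(
        pre = c("X", "Y", "X", "Y", "Q"),
        post = c("Y", "X", "Z1", "Z1", "R"),
        kind = "chemical", weight = c(2L, 2L, 2L, 1L, 3L)))
    sets2 <- extractSets(con, minNeighbors = 1L)
    r2 <- assessHomogeneity(sets2)
    r2$homogeneous <- TRUE
    expect_equal(synapseCoverage(con, r2), 0.7)

    expect_true(isBilateralPair("PHAL", "PHAR"))
    expect_false(isBilateralPair("AVHR", "ADLR"))
    expect_false(isBilateralPair("PHAL", "PHAL"))
    expect_false(isBilateralPair("PHA", "PHB"))
    fake <- data.frame(x = c("AAAL", "Q1", "Q3", "Q5", "Q7"),
                       y = c("AAAR", "Q2", "Q4", "Q6", "Q8"),
                       homogeneous = TRUE)
    expect_equal(unname(bilateralRatio(fake)["homogeneous"]), 0.25)
})
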
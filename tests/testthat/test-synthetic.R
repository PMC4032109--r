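test_that("generators are bit-reproducible for a fixed seed", {
    a <- genConeTrajectory(60, n = 100, seed = 61)
    b <- genConeTrajectory(60, n = 100, seed = 61)
    expect_identical(a$trajectory@xyz, b$trajectory@xyz)
    c <- genConeTrajectory(60, n = 100, seed = 62)
    expect_false(identical(a$trajectory@xyz, c$trajectory@xyz))

    h1 <- genHbondTrajectory(0.5, n = 100, seed = 61)
    h2 <- genHbondTrajectory(0.5, n = 100, seed = 61)
    expect_identical(h1$trajectory@xyz, h2$trajectory@xyz)

    i1 <- genConfinedIonTrajectory(0.4, n = 100, seed = 61)
    i2 <- genConfinedIonTrajectory(0.4, n = 100, seed = 61)
    expect_identical(i1$trajectory@xyz, i2$trajectory@xyz)
})

test_that("generators restore the caller's RNG state", {
    set.seed(99)
    before <- .Random.seed
    invisible(genConeTrajectory(30, n = 50, seed = 1))
    expect_identical(.Random.seed, before)
})

test_that("analytic cone S2 covers limits correctly", {
    expect_equal(genConeTrajectory(1e-3, n = 2, seed = 1)$s2, 1,
                 tolerance = 1e-6)
    expect_equal(genConeTrajectory(90, n = 2, seed = 1)$s2, 0)
    expect_equal(genConeTrajectory(60, n = 2, seed = 1)$s2, 0.140625)
    expect_error(genConeTrajectory(0, n = 10), "theta0")
    expect_error(genConeTrajectory(181, n = 10), "theta0")
})

test_that("analytic two-site S2 covers degenerate cases", {
    expect_equal(genTwoSiteTrajectory(0, 0.5, n = 2)$s2, 1)
    expect_equal(genTwoSiteTrajectory(90, 1, n = 2)$s2, 1)   # single site
    expect_equal(genTwoSiteTrajectory(90, 0.5, n = 2)$s2, 0.25)
    g <- genTwoSiteTrajectory(90, 1, n = 100, seed = 63)
    expect_equal(computeS2(extractBondVectors(g$trajectory)[[1]]), 1,
                 tolerance = 1e-12)
    expect_error(genTwoSiteTrajectory(90, 1.2, n = 10), "p must")
})

test_that("two-site estimator matches the brute-force ensemble value", {
    ## independent oracle: evaluate the estimator on the exact two-member
    ## orientation ensemble weighted by populations
    p <- 0.3; beta <- 70 * pi / 180
    mu <- rbind(c(0, 0, 1), c(sin(beta), 0, cos(beta)))
    M <- p * tcrossprod(mu[1, ]) + (1 - p) * tcrossprod(mu[2, ])
    oracle <- 0.5 * (3 * sum(M^2) - 1)
    g <- genTwoSiteTrajectory(70, 0.3, n = 2e5, seed = 64)
    expect_equal(g$s2, oracle, tolerance = 1e-12)
    expect_lt(abs(computeS2(extractBondVectors(g$trajectory)[[1]]) - oracle),
              0.02)
})

test_that("trajectories survive PDB round-trips with S2 unchanged", {
    g <- genConeTrajectory(45, n = 400, seed = 65)
    s2Direct <- computeS2(extractBondVectors(g$trajectory)[[1]])
    f <- withr::local_tempfile(fileext = ".pdb")
    writeTrajectory(g$trajectory, f)
    back <- readTrajectory(f, topology(g$trajectory), 10)
    s2Back <- computeS2(extractBondVectors(back)[[1]])
    expect_lt(abs(s2Direct - s2Back), 1e-3)
})

test_that("telegraph endpoints are exact at p = 0 and p = 1", {
    g1 <- genHbondTrajectory(1, n = 20, seed = 66)
    expect_equal(hbondOccupancy(g1$trajectory, g1$donor,
                                g1$acceptor)$occupancy, 1.0)
    g0 <- genHbondTrajectory(0, n = 20, seed = 66)
    expect_equal(hbondOccupancy(g0$trajectory, g0$donor,
                                g0$acceptor)$occupancy, 0.0)
})

test_that("a nearly frozen confined ion stays in one voxel", {
    g <- genConfinedIonTrajectory(1e-9, n = 100, seed = 67)
    grid <- accumulateDensity(g$trajectory, g$ion)
    expect_equal(sum(gridValues(grid) > 0), 1L)
    expect_error(genConfinedIonTrajectory(0, n = 10), "sigma")
})

test_that("zero-magnitude tumbling returns the input unchanged", {
    g <- genConeTrajectory(30, n = 20, seed = 68)
    t0 <- applyGlobalTumbling(g$trajectory, maxAngle = 0,
                              maxTranslation = 0)
    expect_identical(t0@xyz, g$trajectory@xyz)
})

test_that("alignment after tumbling restores a rigid ion exactly", {
    g <- genConfinedIonTrajectory(1e-9, n = 50, seed = 69)
    tumbled <- applyGlobalTumbling(g$trajectory, seed = 70)
    expect_gt(max(abs(tumbled@xyz - g$trajectory@xyz)), 0.1)
    aligned <- alignFrames(tumbled, topology(g$trajectory))
    tr <- ionTrace(aligned, g$ion, reference = g$center)
    expect_lt(ionRmsd(tr), 1e-6)
})

test_that("tumbling then alignment preserves cone S2", {
    g <- genConeTrajectory(60, n = 3000, seed = 71)
    s2Twin <- computeS2(extractBondVectors(g$trajectory)[[1]])
    tumbled <- applyGlobalTumbling(g$trajectory, seed = 72)
    aligned <- alignFrames(tumbled, topology(g$trajectory))
    s2Aligned <- computeS2(extractBondVectors(aligned)[[1]])
    expect_lt(abs(s2Aligned - s2Twin), 0.02)
})

test_that("poly-Asp cone scaffolds expose one series per residue", {
    g <- genConeTrajectory(40, n = 200, nResidues = 3, seed = 73)
    bv <- extractBondVectors(g$trajectory)
    expect_length(bv, 3)
    expect_false(identical(bv[[1]]@vectors, bv[[2]]@vectors))
})
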
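test_that("a fixed bond vector gives S2 of exactly 1", {
    v <- matrix(rep(c(0, 0, 1), 10), ncol = 3, byrow = TRUE)
    expect_equal(computeS2(v), 1, tolerance = 1e-12)
    u <- c(1, 2, 2) / 3
    v2 <- matrix(rep(u, 7), ncol = 3, byrow = TRUE)
    expect_equal(computeS2(v2), 1, tolerance = 1e-12)
})

test_that("estimator equals the brute-force double loop", {
    set.seed(21)
    for (rep in 1:5) {
        v <- rUnitSphere(20)
        expect_equal(computeS2(v), s2BruteForce(v), tolerance = 1e-12)
    }
})

test_that("S2 is invariant under sign flips and global rotations", {
    set.seed(22)
    v <- rUnitSphere(200)
    base <- computeS2(v)
    flip <- sample(c(-1, 1), 200, replace = TRUE)
    expect_equal(computeS2(v * flip), base, tolerance = 1e-12)
    for (rep in 1:3) {
        R <- randRotQR()
        expect_equal(computeS2(v %*% t(R)), base, tolerance = 1e-10)
    }
})

test_that("isotropic vectors give S2 near zero", {
    set.seed(23)
    expect_lt(abs(computeS2(rUnitSphere(1e5))), 0.01)
})

test_that("non-unit vectors are rejected", {
    v <- matrix(rep(c(0, 0, 2), 5), ncol = 3, byrow = TRUE)
    expect_error(computeS2(v), "unit")
    expect_error(computeS2(rUnitSphere(1)), "2 frames")
})

test_that("bond vectors are extracted along the class-specific axis", {
    ## Asp: CB -> CG, constant (0, 0, 1)
    top <- newStructure(data.frame(
        atomName = c("CB", "CG"), resName = "ASP", chain = "A", resNo = 1,
        x = 0, y = 0, z = c(0, 2)))
    traj <- constantTrajectory(top, 4)
    bv <- extractBondVectors(traj)
    expect_length(bv, 1)
    expect_equal(bv[[1]]@bond, c("CB", "CG"))
    expect_true(all(abs(sweep(bv[[1]]@vectors, 2, c(0, 0, 1))) < 1e-12))

    ## Gln: bond reported as CG -> CD
    topQ <- newStructure(data.frame(
        atomName = c("CG", "CD"), resName = "GLN", chain = "A", resNo = 5,
        x = c(0, 1.5), y = 0, z = 0))
    bvQ <- extractBondVectors(constantTrajectory(topQ, 3))
    expect_equal(bvQ[[1]]@bond, c("CG", "CD"))

    ## missing bond atom is an extraction error naming the residue
    topBad <- newStructure(data.frame(
        atomName = c("CB"), resName = "ASP", chain = "A", resNo = 9,
        x = 0, y = 0, z = 0))
    expect_error(extractBondVectors(constantTrajectory(topBad, 3)), "A 9")
})

test_that("cone-generator vectors respect the cone semi-angle bound", {
    g <- genConeTrajectory(30, n = 2000, seed = 24)
    bv <- extractBondVectors(g$trajectory)[[1]]
    polar <- acos(pmin(1, bv@vectors[, 3])) * 180 / pi
    expect_lt(max(polar), 30 + 1e-6)
})

test_that("estimated S2 decreases strictly with cone semi-angle", {
    est <- vapply(c(10, 30, 60, 90), function(th) {
        g <- genConeTrajectory(th, n = 2e5, seed = 25)
        computeS2(extractBondVectors(g$trajectory)[[1]])
    }, numeric(1))
    expect_true(all(diff(est) < 0))
    analytic <- (cos(c(10, 30, 60, 90) * pi / 180) *
                 (1 + cos(c(10, 30, 60, 90) * pi / 180)) / 2)^2
    expect_true(all(abs(est - analytic) < 0.01))
})

test_that("block SEM is zero for a constant series", {
    v <- matrix(rep(c(0, 0, 1), 100), ncol = 3, byrow = TRUE)
    b <- blockSEM(v, 10)
    expect_equal(b$sem, 0, tolerance = 1e-12)
    expect_equal(b$s2, 1, tolerance = 1e-12)
})

test_that("two-block SEM matches the hand formula |a - b| / 2", {
    ## block 1: constant +z (s2 = 1); block 2: half +z half +x (s2 = 0.25)
    v <- rbind(matrix(rep(c(0, 0, 1), 10), ncol = 3, byrow = TRUE),
               matrix(rep(c(0, 0, 1, 1, 0, 0), 5), ncol = 3, byrow = TRUE))
    b <- blockSEM(v, 2)
    a1 <- computeS2(v[1:10, ]); a2 <- computeS2(v[11:20, ])
    expect_equal(a1, 1, tolerance = 1e-12)
    expect_equal(a2, 0.25, tolerance = 1e-12)
    expect_equal(b$sem, abs(a1 - a2) / 2, tolerance = 1e-12)
})

test_that("block SEM brackets the isotropic limit", {
    set.seed(26)
    v <- rUnitSphere(2e4)
    b <- blockSEM(v, 10)
    expect_gt(b$sem, 0)
    expect_lt(abs(b$s2), 3 * b$sem + 0.01)
})

test_that("blockSEM validates its arguments", {
    v <- rUnitSphere(10)
    expect_error(blockSEM(v, 1), "at least 2")
    expect_error(blockSEM(v, 8), "per block")
})

test_that("identical conditions show zero differences, none significant", {
    g <- genConeTrajectory(45, n = 2000, seed = 27)
    tab <- orderParameters(g$trajectory)
    cmp <- compareS2(tab, tab)
    expect_true(all(cmp$deltaS2 == 0))
    expect_false(any(cmp$significant))
})

test_that("the significance rule is 1.96 pooled SEMs", {
    a <- data.frame(chain = "A", resNo = 1, resName = "ASP",
                    s2 = 0.9, sem = 0.06)
    b <- data.frame(chain = "A", resNo = 1, resName = "ASP",
                    s2 = 0.4, sem = 0.08)
    cmp <- compareS2(a, b)
    expect_equal(cmp$deltaS2, 0.5)
    expect_equal(cmp$pooledSem, 0.1)
    expect_true(cmp$significant)
    b$s2 <- 0.75   # |delta| = 0.15 < 1.96 * 0.1
    expect_false(compareS2(a, b)$significant)
    expect_error(compareS2(a, data.frame(chain = "A", resNo = 2,
                                         s2 = 1, sem = 0)), "match")
})

test_that("null comparison of independent conditions flags few residues", {
    ## 20 residues, both conditions isotropic: nominal 5% false positives
    set.seed(28)
    mkCondition <- function() {
        rows <- lapply(1:20, function(r) {
            b <- blockSEM(rUnitSphere(2000), 10)
            data.frame(chain = "A", resNo = r, resName = "ASP",
                       s2 = b$s2, sem = b$sem)
        })
        do.call(rbind, rows)
    }
    cmp <- compareS2(mkCondition(), mkCondition())
    expect_lte(sum(cmp$significant), 3)
})
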
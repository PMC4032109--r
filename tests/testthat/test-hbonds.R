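test_that("Arg donor against Asp acceptor yields 10 triads", {
    tr <- enumerateTriads(argAspStructure(), "A:1", "A:2")
    expect_equal(nrow(tr), 10L)        # 5 hydrogens x 2 carboxylate oxygens
    expect_setequal(unique(tr$acceptorAtom), c("OD1", "OD2"))
    expect_setequal(unique(tr$donorAtom), c("NE", "NH1", "NH2"))
})

test_that("Asn sidechain donor against Glu acceptor yields 4 triads", {
    tr <- enumerateTriads(asnGluStructure(), "A:1", "A:2")
    expect_equal(nrow(tr), 4L)         # 2 amide hydrogens x OE1/OE2
})

test_that("a residue pair with no donors gives an empty triad list", {
    s <- newStructure(data.frame(
        atomName = c("CB", "CG", "OD1"), resName = c("ALA", "ASP", "ASP"),
        chain = "A", resNo = c(1L, 2L, 2L), x = c(0, 5, 6), y = 0, z = 0))
    expect_equal(nrow(enumerateTriads(s, "A:1", "A:2")), 0L)
})

test_that("a bare nitrogen donor is skipped with a chemistry warning", {
    s <- newStructure(data.frame(
        atomName = c("ND2", "CG", "OD1"),
        resName = c("ASN", "ASP", "ASP"),
        chain = "A", resNo = c(1L, 2L, 2L), x = c(0, 5, 6), y = 0, z = 0))
    expect_warning(tr <- enumerateTriads(s, "A:1", "A:2"), "no bound hydrogen")
    expect_equal(nrow(tr), 0L)
})

test_that("protonated His nitrogens are not counted as acceptors", {
    s <- newStructure(data.frame(
        atomName = c("NE", "HE", "ND1", "HD1", "NE2"),
        resName = c("ARG", "ARG", "HIS", "HIS", "HIS"),
        chain = "A", resNo = c(1L, 1L, 2L, 2L, 2L),
        x = c(0, 0, 5, 5, 7), y = 0, z = c(0, 1, 0, 1, 0)))
    tr <- enumerateTriads(s, "A:1", "A:2")
    expect_equal(unique(tr$acceptorAtom), "NE2")   # ND1 carries HD1
    expect_equal(nrow(tr), 1L)
})

test_that("geometric criteria follow strict distance and deviation cutoffs", {
    crit <- hbondCriteria()
    d <- c(0, 0, 0); h <- c(0, 0, 1)
    expect_true(hbondInFrame(d, h, c(0, 0, 3.0), crit))    # collinear, 3.0 A
    expect_false(hbondInFrame(d, h, c(0, 0, 3.2), crit))   # distance fails
    ## 45 degrees deviation at 2.83 A: distance passes, angle fails
    expect_false(hbondInFrame(d, h, c(2, 0, 2), crit))
    ## strict inequalities exactly at the cutoffs
    expect_false(hbondInFrame(d, h, c(0, 0, 3.1), crit))
    a25 <- 2 * c(sin(25 * pi / 180), 0, cos(25 * pi / 180))
    expect_false(hbondInFrame(d, h, a25, crit))
    a24 <- 2 * c(sin(24.9 * pi / 180), 0, cos(24.9 * pi / 180))
    expect_true(hbondInFrame(d, h, a24, crit))
    expect_error(hbondInFrame(d, d, c(0, 0, 3), crit), "coincides")
})

test_that("the D-H-A supplement convention matches hand trigonometry", {
    crit <- hbondCriteria(convention = "dha-supplement")
    d <- c(0, 0, 0); h <- c(0, 0, 1)
    expect_true(hbondInFrame(d, h, c(0, 0, 3.0), crit))    # DHA = 180
    ## H displaced sideways: DHA = 135 degrees, supplement 45 > 25
    expect_false(hbondInFrame(d, c(sqrt(.5), 0, sqrt(.5)), c(0, 0, 3), crit))
})

test_that("a permanently bonded triad has occupancy 1", {
    g <- genHbondTrajectory(1, n = 50, seed = 31)
    row <- hbondOccupancy(g$trajectory, g$donor, g$acceptor)
    expect_equal(row$occupancy, 1.0)
    g0 <- genHbondTrajectory(0, n = 50, seed = 31)
    expect_equal(hbondOccupancy(g0$trajectory, g0$donor,
                                g0$acceptor)$occupancy, 0.0)
})

test_that("telegraph occupancy concentrates at the generator probability", {
    g <- genHbondTrajectory(0.3, n = 2000, seed = 32)
    row <- hbondOccupancy(g$trajectory, g$donor, g$acceptor)
    expect_lt(abs(row$occupancy - 0.3), 0.03)
    expect_equal(row$occupancy * row$nFrames, round(row$occupancy *
                                                    row$nFrames))
})

test_that("occupancy is invariant under rigid motion of every frame", {
    g <- genHbondTrajectory(0.4, n = 300, seed = 33)
    base <- hbondOccupancy(g$trajectory, g$donor, g$acceptor)$occupancy
    tumbled <- applyGlobalTumbling(g$trajectory, seed = 34)
    expect_equal(hbondOccupancy(tumbled, g$donor, g$acceptor)$occupancy,
                 base)
})

test_that("pair occupancy is at least any single-triad occupancy", {
    ## Asn donor vs Glu acceptor with per-frame noise on all atoms
    s <- asnGluStructure()
    set.seed(35)
    n <- 400
    base <- as.vector(t(coords(s)))
    xyz <- matrix(rep(base, each = n), nrow = n) +
        matrix(rnorm(n * length(base), sd = 0.6), nrow = n)
    traj <- newTrajectory(s, xyz, 10)
    crit <- hbondCriteria(maxDistance = 4, maxAngle = 60)
    pair <- hbondOccupancy(traj, "A:1", "A:2", crit)
    tr <- enumerateTriads(s, "A:1", "A:2")
    cols <- function(i) xyz[, (3 * (i - 1) + 1):(3 * i)]
    for (k in seq_len(nrow(tr))) {
        single <- mean(hbondInFrame(cols(tr$d[k]), cols(tr$h[k]),
                                    cols(tr$a[k]), crit))
        expect_gte(pair$occupancy, single)
    }
    expect_gt(pair$occupancy, 0)   # noise level chosen to make bonds form
})

test_that("a pair with no triads reports occupancy zero with a warning", {
    top <- newStructure(data.frame(
        atomName = c("CB", "CB2"), resName = c("ALA", "ALA"), chain = "A",
        resNo = c(1L, 2L), x = c(0, 5), y = 0, z = 0))
    traj <- constantTrajectory(top, 5)
    expect_warning(row <- hbondOccupancy(traj, "A:1", "A:2"), "no donor")
    expect_equal(row$occupancy, 0)
})

test_that("estimated occupancy sits inside 99% binomial bands", {
    n <- 1000; p <- 0.3
    lo <- qbinom(0.005, n, p) / n
    hi <- qbinom(0.995, n, p) / n
    inside <- vapply(1:200, function(r) {
        g <- genHbondTrajectory(p, n = n, seed = r)
        occ <- hbondOccupancy(g$trajectory, g$donor, g$acceptor)$occupancy
        occ >= lo && occ <= hi
    }, logical(1))
    expect_gte(sum(inside), 194)   # nominal 198 of 200
})

test_that("hbondNetwork tabulates pairs by trajectory", {
    gA <- genHbondTrajectory(0.8, n = 500, seed = 36)
    gB <- genHbondTrajectory(0.1, n = 500, seed = 37)
    tab <- hbondNetwork(list(condA = gA$trajectory, condB = gB$trajectory),
                        pairs = cbind("A:1", "A:2"))
    expect_named(tab, c("donor", "acceptor", "condA", "condB"))
    expect_gt(tab$condA, tab$condB)
})
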
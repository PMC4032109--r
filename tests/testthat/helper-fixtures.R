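## Independent oracles and tiny fixtures used across test files.
## These deliberately avoid the package's own code paths.

## uniform sampler on the unit sphere (z uniform in [-1,1])
rUnitSphere <- function(n) {
    z <- runif(n, -1, 1)
    phi <- runif(n, 0, 2 * pi)
    s <- sqrt(pmax(0, 1 - z^2))
    cbind(s * cos(phi), s * sin(phi), z)
}

## brute-force evaluation of the order-parameter estimator: explicit
## double loop over the x,y,z component indices
s2BruteForce <- function(v) {
    tot <- 0
    for (i in 1:3) for (j in 1:3)
        tot <- tot + mean(v[, i] * v[, j])^2
    0.5 * (3 * tot - 1)
}

## independent uniform random proper rotation via QR decomposition
randRotQR <- function() {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
}

## RMSD of mobile onto reference after centroid matching under rotation R
rmsdUnderRotation <- function(mobile, reference, R) {
    P <- sweep(mobile, 2, colMeans(mobile))
    Q <- sweep(reference, 2, colMeans(reference))
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
}

## arginine donor + aspartate acceptor pair: 5 donor hydrogens, 2 acceptors
argAspStructure <- function() {
    newStructure(data.frame(
        atomName = c("CZ", "NE", "HE", "NH1", "HH11", "HH12",
                     "NH2", "HH21", "HH22", "CG", "OD1", "OD2"),
        resName = c(rep("ARG", 9), rep("ASP", 3)),
        chain = "A",
        resNo = c(rep(1L, 9), rep(2L, 3)),
        x = c(1, 0, 0, 2, 2, 2.6, 4, 4, 4.6, 8, 8, 8.9),
        y = c(1, 0, 0, 0, 0.2, -0.7, 0, 0.2, -0.7, 0, 1.2, -0.5),
        z = c(0.5, 0, 1, 0, 1, -0.5, 0, 1, -0.5, 0, 0.3, 0.3),
        stringsAsFactors = FALSE))
}

## asparagine donor + glutamate acceptor: 2 hydrogens x 2 acceptors
asnGluStructure <- function() {
    newStructure(data.frame(
        atomName = c("CG", "OD1", "ND2", "HD21", "HD22",
                     "CD", "OE1", "OE2"),
        resName = c(rep("ASN", 5), rep("GLU", 3)),
        chain = "A",
        resNo = c(rep(1L, 5), rep(2L, 3)),
        x = c(0, -0.6, 1, 1, 1.6, 6, 6, 6.9),
        y = c(0, 1, -0.7, -0.7, -1.3, 0, 1.2, -0.5),
        z = c(0, 0, 0, 1, -0.5, 0, 0.3, 0.3),
        stringsAsFactors = FALSE))
}

## constant-coordinate trajectory around a given structure
constantTrajectory <- function(structure, n, frameSpacing = 10) {
    xyz <- matrix(rep(as.vector(t(coords(structure))), each = n), nrow = n)
    newTrajectory(structure, xyz, frameSpacing)
}
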
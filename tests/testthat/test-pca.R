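# two-residue pair (alignment skipped below 3 residues) with prescribed
# per-coordinate variance, both states drawn from the same law
twoResPair <- function(nFrames = 200, seedR = 1, seedP = 2, sdVec = NULL) {
  cas <- makeCASystem(2)
  mk <- function(seed) {
    set.seed(seed)
    co <- array(rep(cas$reference, each = nFrames), c(nFrames, 2, 3))
    if (!is.null(sdVec)) {
      noise <- array(stats::rnorm(nFrames * 6), c(nFrames, 2, 3))
      for (i in 1:2) for (k in 1:3)
        co[, i, k] <- co[, i, k] + noise[, i, k] * sdVec[(i - 1) * 3 + k]
    }
    newTrajectory(cas$system, co)
  }
  new("StatePair", reduced = list(mk(seedR)), ptm = list(mk(seedP)),
      selection = "")
}

test_that("degenerate ensembles give zero eigenvalues; single-direction variance gives PC1 = 100%", {
  frozen <- twoResPair()
  p <- combinedPCA(frozen)
  expect_true(all(pcaEigenvalues(p) == 0))

  oneDir <- twoResPair(sdVec = c(0.3, 0, 0, 0, 0, 0))
  p1 <- combinedPCA(oneDir)
  expect_equal(pcaVarianceFractions(p1)[1], 1.0, tolerance = 1e-12)
})

test_that("a known covariance is recovered at large n", {
  cas <- makeCASystem(1)
  cov3 <- diag(c(4, 1, 0.25))
  mk <- function(seed) sampleFluctuationTrajectory(
    fluctuationModel(cas$reference, covariance3n = cov3, seed = seed),
    25000, cas$system)
  pair <- new("StatePair", reduced = list(mk(41)), ptm = list(mk(42)),
              selection = "")
  p <- combinedPCA(pair)
  expect_lt(max(abs(pcaEigenvalues(p) / c(4, 1, 0.25) - 1)), 0.05)
})

test_that("eigen identities hold: trace, variance fractions, orthonormality, reconstruction", {
  base <- corrMatrixFromBlocks(6, list(list(members = c(1, 4), rho = 0.5)))
  fx <- makeStatePairFixture(list(corr = base), nFrames = 150, seed = 6,
                             replicas = 2)
  p <- combinedPCA(fx$pair)
  expect_lt(abs(sum(pcaEigenvalues(p)) - p@trace), 1e-9)
  expect_equal(sum(pcaVarianceFractions(p)), 1, tolerance = 1e-9)
  G <- crossprod(pcaEigenvectors(p))
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-9)

  # completeness: the full mode set carries all positional variance, so
  # back-projection is lossless and squared projections recover the trace
  allProj <- do.call(rbind, pcaProjections(p))
  expect_lt(abs(sum(allProj^2) / (nrow(allProj) - 1) - p@trace), 1e-8)
})

test_that("combined PCA is invariant to frame order and rigid contamination", {
  base <- corrMatrixFromBlocks(5, list(list(members = c(2, 3), rho = 0.4)))
  fx <- makeStatePairFixture(list(corr = base), nFrames = 120, seed = 9)
  p <- combinedPCA(fx$pair)

  contaminated <- new("StatePair",
                      reduced = lapply(fx$pair@reduced, contaminateRigid,
                                       seed = 5),
                      ptm = lapply(fx$pair@ptm, contaminateRigid, seed = 6),
                      selection = "")
  pc <- combinedPCA(contaminated)
  expect_lt(max(abs(pcaEigenvalues(p) - pcaEigenvalues(pc))), 1e-9)

  flip <- function(tr) newTrajectory(trajSystem(tr),
                                     trajCoords(tr)[rev(seq_len(nFrames(tr))), , ,
                                                    drop = FALSE],
                                     frameTimes(tr))
  reordered <- new("StatePair", reduced = lapply(fx$pair@reduced, flip),
                   ptm = lapply(fx$pair@ptm, flip), selection = "")
  pr <- combinedPCA(reordered)
  expect_lt(max(abs(pcaEigenvalues(p) - pcaEigenvalues(pr))), 1e-9)
})

# a handmade single-mode PCAResult whose per-residue magnitudes are known
madeUpResult <- function(mags) {
  m <- length(mags)
  v <- as.numeric(rbind(mags, 0, 0))
  v <- v / sqrt(sum(v^2))
  res <- data.frame(chain = "A", resid = seq_len(m),
                    label = paste0("A:", seq_len(m)),
                    stringsAsFactors = FALSE)
  new("PCAResult", values = 1, vectors = matrix(v, ncol = 1),
      varianceFractions = 1, trace = 1,
      projections = list(src = matrix(0, 1, 1)),
      sources = data.frame(source = "src", state = "reduced", replica = 1,
                           group = "all", stringsAsFactors = FALSE),
      residues = res, center = numeric(3 * m))
}

test_that("mode contributions and top sets match the sort-and-accumulate rule", {
  r <- madeUpResult(c(0.5, 0.3, 0.1, 0.1))
  mc <- modeResidueContributions(r, 1, fraction = 0.5)
  expect_equal(mc$contributions$contribution, c(0.5, 0.3, 0.1, 0.1))
  expect_equal(mc$topSet, "A:1")

  # independent oracle: sort descending, accumulate, stop at the fraction
  mags <- c(0.15, 0.4, 0.05, 0.25, 0.15)
  oracleTop <- function(mags, fraction) {
    ord <- order(-mags, seq_along(mags))
    k <- which(cumsum(mags[ord]) >= fraction)[1]
    sort(ord[seq_len(k)])
  }
  r2 <- madeUpResult(mags)
  mc2 <- modeResidueContributions(r2, 1, fraction = 0.5)
  expect_equal(mc2$topSet, paste0("A:", oracleTop(mags, 0.5)))

  uniform <- madeUpResult(rep(0.25, 4))
  expect_equal(modeResidueContributions(uniform, 1, 0.5)$topSet,
               c("A:1", "A:2"))

  single <- madeUpResult(c(0, 1, 0))
  mc3 <- modeResidueContributions(single, 1, 0.5)
  expect_equal(mc3$topSet, "A:2")
  expect_equal(mc3$contributions$contribution[2], 1.0)
})

test_that("centroid shifts recover exact and generative displacements", {
  same <- twoResPair(sdVec = rep(0.1, 6), seedR = 3, seedP = 3)
  p0 <- combinedPCA(same)
  expect_lt(max(abs(centroidShift(p0))), 1e-12)

  # ptm = reduced + constant offset: shift equals the offset's projection
  cas <- makeCASystem(2)
  set.seed(77)
  nf <- 300
  co <- array(rep(cas$reference, each = nf), c(nf, 2, 3)) +
    array(stats::rnorm(nf * 6, sd = 0.1), c(nf, 2, 3))
  delta <- c(0.05, -0.02, 0.01, 0.03, 0, -0.04)
  coP <- co
  for (i in 1:2) for (k in 1:3)
    coP[, i, k] <- co[, i, k] + delta[(i - 1) * 3 + k]
  pair <- new("StatePair",
              reduced = list(newTrajectory(cas$system, co)),
              ptm = list(newTrajectory(cas$system, coP)), selection = "")
  p <- combinedPCA(pair)
  # flat ordering is (x1, y1, z1, x2, y2, z2)
  expected <- as.numeric(t(pcaEigenvectors(p)) %*% delta)
  expect_equal(as.numeric(centroidShift(p)), expected, tolerance = 1e-9)

  oneState <- p
  oneState@sources$state <- "reduced"
  expect_error(centroidShift(oneState), "no ptm sources")
})
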
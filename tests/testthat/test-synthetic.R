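test_that("degenerate and perfectly coupled fluctuation models behave exactly", {
  cas <- makeCASystem(4)
  frozen <- fluctuationModel(cas$reference, sds = 0, seed = 1)
  tr <- sampleFluctuationTrajectory(frozen, 5, cas$system)
  for (f in 1:5)
    expect_equal(matrix(trajCoords(tr)[f, , ], ncol = 3), cas$reference,
                 ignore_attr = TRUE)

  R <- corrMatrixFromBlocks(2, list(list(members = 1:2, rho = 1)))
  m <- fluctuationModel(makeCASystem(2)$reference, sds = 0.1, corr = R,
                        seed = 2)
  tr2 <- sampleFluctuationTrajectory(m, 500)
  expect_equal(dccmValues(dccMatrix(tr2, fit = FALSE))[1, 2], 1,
               tolerance = 1e-9)
})

test_that("recipe correlations are recovered within Monte-Carlo error", {
  R <- corrMatrixFromBlocks(6, list(list(members = c(2, 5), rho = 0.6)))
  m <- fluctuationModel(makeCASystem(6)$reference, sds = 0.1, corr = R,
                        seed = 3)
  tr <- sampleFluctuationTrajectory(m, 20000)
  C <- dccmValues(dccMatrix(tr, fit = FALSE))
  expect_lt(abs(C[2, 5] - 0.6), 0.03)
  expect_lt(max(abs(C[1, 3]), abs(C[3, 6])), 0.05)
})

test_that("non-PSD recipes are rejected; generators are seed-reproducible", {
  badR <- corrMatrixFromBlocks(3, list(list(members = 1:3, rho = -0.6)))
  expect_error(fluctuationModel(makeCASystem(3)$reference, corr = badR),
               "positive semi-definite")

  cas <- makeCASystem(4)
  m <- fluctuationModel(cas$reference, sds = 0.1, seed = 42)
  a <- sampleFluctuationTrajectory(m, 50, cas$system)
  b <- sampleFluctuationTrajectory(m, 50, cas$system)
  expect_identical(trajCoords(a), trajCoords(b))

  w1 <- sampleCrooksWork(1, 1, 100, seed = 9)
  w2 <- sampleCrooksWork(1, 1, 100, seed = 9)
  expect_identical(w1$forward, w2$forward)
  g1 <- sampleGateSeries(c(closed = 0.3, open = 0.6), 0.02,
                         matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
                         200, seed = 5)
  g2 <- sampleGateSeries(c(closed = 0.3, open = 0.6), 0.02,
                         matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
                         200, seed = 5)
  expect_identical(g1$distance, g2$distance)
})

test_that("gate series honor absorbing, symmetric and 3-state stationary laws", {
  const <- sampleGateSeries(c(closed = 0.30), 0, matrix(1, 1, 1), 100,
                            seed = 1)
  expect_true(all(const$distance == 0.30))
  expect_true(all(const$state == "closed"))

  sym <- sampleGateSeries(c(closed = 0.3, open = 0.6), 0.01,
                          matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
                          50000, seed = 7)
  expect_lt(abs(mean(sym$state == "closed") - 0.5), 0.02)

  pi0 <- c(0.2, 0.5, 0.3)
  P <- metropolisTransition(pi0)
  expect_equal(powerStationary(P), pi0, tolerance = 1e-10)
  g3 <- sampleGateSeries(c(closed = 0.3, open = 0.55, wide_open = 0.8),
                         0.02, P, 50000, seed = 8)
  occ <- table(factor(g3$state,
                      c("closed", "open", "wide_open"))) / 50000
  expect_lt(max(abs(as.numeric(occ) - pi0)), 0.02)
})

test_that("embedded gate distances reproduce the series to 1e-9 nm", {
  cas <- makeCASystem(6)
  m <- fluctuationModel(cas$reference, sds = 0.05, seed = 3)
  tr <- sampleFluctuationTrajectory(m, 50, cas$system)
  gd <- gateDefinition(lower = 2, upper = 5)

  emb <- embedGateInStructure(tr, c(2L, 5L), rep(0.5, 50))
  expect_equal(gateDistanceSeries(emb, gd, "A"), rep(0.5, 50),
               tolerance = 1e-9)

  two <- embedGateInStructure(tr, c(2L, 5L), c(0.3, 0.8, rep(0.5, 48)))
  expect_equal(gateDistanceSeries(two, gd, "A")[1:2], c(0.3, 0.8),
               tolerance = 1e-9)

  set.seed(10)
  series <- stats::runif(50, 0.2, 1.2)
  rnd <- embedGateInStructure(tr, c(2L, 5L), series)
  expect_lt(max(abs(gateDistanceSeries(rnd, gd, "A") - series)), 1e-9)
  # all other atoms untouched
  others <- setdiff(1:6, 5)
  expect_identical(trajCoords(rnd)[, others, ], trajCoords(tr)[, others, ])
  expect_error(embedGateInStructure(tr, c(2L, 2L), series), "distinct")
})

test_that("Crooks work samples satisfy the fluctuation relation", {
  ws <- sampleCrooksWork(2, 1, 1e5, seed = 21)
  # generator algebra: mean(F) - mean(R) = 2 dG in expectation
  expect_lt(abs((mean(ws$forward) - mean(ws$reverse)) - 2 * 2), 0.02)

  # log P_F(W) - log P_R(-W) must be linear in W with slope 1,
  # intercept -dG (densities estimated on a common grid)
  dF <- stats::density(ws$forward, n = 512, from = 0, to = 4)
  dR <- stats::density(-ws$reverse, n = 512, from = 0, to = 4)
  keep <- dF$y > 0.02 & dR$y > 0.02
  fit <- stats::lm(log(dF$y[keep] / dR$y[keep]) ~ dF$x[keep])
  expect_lt(abs(stats::coef(fit)[2] - 1), 0.05)
  expect_lt(abs(stats::coef(fit)[1] - (-2)), 0.05 * 2)

  # reversible limit
  tiny <- sampleCrooksWork(0, 1e-6, 100, seed = 2)
  expect_lt(max(abs(c(tiny$forward, tiny$reverse))), 1e-4)
  expect_error(sampleCrooksWork(1, 0, 10), "sigma")
  expect_error(sampleCrooksWork(1, 1, 0), "positive")
})

test_that("state-pair fixtures carry a recoverable redistribution truth", {
  n <- 12
  base <- corrMatrixFromBlocks(n, list(list(members = c(3, 4), rho = 0.6)))

  # no perturbation: scores vanish
  null <- makeStatePairFixture(list(corr = base), nFrames = 20000, seed = 31)
  dR <- dccMatrix(null$pair@reduced, fit = FALSE)
  dP <- dccMatrix(null$pair@ptm, fit = FALSE)
  sc <- redistributionScore(dR, dP)
  expect_true(all(null$truth$score == 0))
  expect_lt(max(abs(sc$score)), 0.05)

  # flipped and added couplings push the affected residues' sign
  pert <- corrMatrixFromBlocks(n, list(list(members = c(3, 4), rho = -0.6),
                                       list(members = c(7, 8), rho = 0.5)))
  fx <- makeStatePairFixture(list(corr = base), perturb = pert,
                             nFrames = 20000, seed = 32)
  expect_true(all(fx$truth$sign[c(3, 4)] == -1))
  expect_true(all(fx$truth$sign[c(7, 8)] == 1))
  est <- redistributionScore(dccMatrix(fx$pair@reduced, fit = FALSE),
                             dccMatrix(fx$pair@ptm, fit = FALSE))
  perturbed <- fx$truth$sign != 0
  agree <- sign(est$score[perturbed]) == fx$truth$sign[perturbed]
  expect_gte(mean(agree), 0.95)

  expect_error(
    makeStatePairFixture(list(corr = base),
                         perturb = corrMatrixFromBlocks(n + 1)),
    "identical residue sets")
})
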
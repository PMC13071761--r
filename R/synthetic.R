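#' One-bead-per-residue synthetic topology
#'
#' Builds a coarse CA-only system: one carbon "CA" atom per residue placed
#' on an idealized alpha-helical trace (0.23 nm radius, 0.15 nm rise, 100
#' degrees per residue), neutral charges, nominal LJ parameters and a 12 Da
#' mass. The helical reference keeps rigid-body superposition
#' well-conditioned, which a straight-line trace would not. The workhorse
#' topology behind the Gaussian fluctuation fixtures.
#'
#' @param nRes number of residues.
#' @param chain chain ID (default "A").
#' @param resname residue name for every residue (default "ALA"), or a
#'   vector of length `nRes`.
#' @return list with `system` ([MolecularSystem-class]) and `reference`
#'   (nRes x 3 coordinates, nm).
#' @export
makeCASystem <- function(nRes, chain = "A", resname = "ALA") {
  resname <- rep_len(resname, nRes)
  atoms <- data.frame(
    atom_id = seq_len(nRes), name = "CA", element = "C",
    chain = chain, resid = seq_len(nRes), resname = resname,
    charge = 0, sigma_nm = 0.34, epsilon_kcal = 0.1, mass = 12.011,
    stringsAsFactors = FALSE)
  ang <- (seq_len(nRes) - 1) * 100 * pi / 180
  ref <- cbind(0.23 * cos(ang), 0.23 * sin(ang),
               0.15 * (seq_len(nRes) - 1))
  list(system = newMolecularSystem(atoms), reference = ref)
}

#' Residue-residue correlation matrix from block recipes
#'
#' Starts from the identity and sets the requested residue-pair couplings;
#' each block assigns correlation `rho` to every pair of its members.
#' Positive-semi-definiteness is validated when the matrix enters
#' [fluctuationModel()].
#'
#' @param n number of residues.
#' @param blocks list of `list(members = <residue indices>, rho = <value>)`.
#' @return n x n symmetric matrix with unit diagonal.
#' @export
corrMatrixFromBlocks <- function(n, blocks = list()) {
  R <- diag(n)
  for (b in blocks) {
    if (any(b$rho < -1 | b$rho > 1))
      stop("recipe correlations must lie in [-1, 1]", call. = FALSE)
    for (i in b$members) for (j in b$members)
      if (i != j) R[i, j] <- b$rho
  }
  R
}

#' Gaussian fluctuation model with a prescribed correlation structure
#'
#' Defines the generative law for synthetic ensembles: frames are
#' independent draws reference + delta with delta zero-mean Gaussian.
#' The covariance is given either as a residue-level recipe (per-residue
#' standard deviations plus a residue-residue correlation matrix, expanded
#' isotropically so x, y and z carry the same coupling -- which makes the
#' target DCCM equal the recipe correlations exactly) or as a full
#' 3n x 3n covariance.
#'
#' @param reference n x 3 reference coordinates (nm), e.g. from
#'   [makeCASystem()].
#' @param sds per-residue isotropic standard deviation (nm), scalar or
#'   length n.
#' @param corr n x n residue correlation matrix (default identity).
#' @param covariance3n optional full 3n x 3n covariance (nm^2); overrides
#'   `sds`/`corr`.
#' @param seed integer seed.
#' @param ar1 optional AR(1) frame-memory coefficient in [0, 1); 0 (the
#'   default) gives i.i.d. frames.
#' @return a FluctuationModel (list) for [sampleFluctuationTrajectory()].
#' @export
fluctuationModel <- function(reference, sds = 0.1, corr = NULL,
                             covariance3n = NULL, seed = 1L, ar1 = 0) {
  reference <- as.matrix(reference)
  n <- nrow(reference)
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must be in [0, 1)", call. = FALSE)
  psdFactor <- function(S, what) {
    S <- (S + t(S)) / 2
    eg <- eigen(S, symmetric = TRUE)
    if (min(eg$values) < -1e-8 * max(abs(eg$values), 1))
      stop(what, " is not positive semi-definite", call. = FALSE)
    eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nrow(S))
  }
  if (!is.null(covariance3n)) {
    if (!all(dim(covariance3n) == 3L * n))
      stop("covariance3n must be 3n x 3n", call. = FALSE)
    L <- psdFactor(covariance3n, "covariance")
    mode <- "full"
  } else {
    if (is.null(corr)) corr <- diag(n)
    if (any(abs(corr) > 1 + 1e-12))
      stop("recipe correlations must lie in [-1, 1]", call. = FALSE)
    sds <- rep_len(sds, n)
    S <- corr * outer(sds, sds)
    L <- psdFactor(S, "correlation recipe")
    mode <- "recipe"
  }
  structure(list(reference = reference, L = L, mode = mode, seed = seed,
                 ar1 = ar1, n = n), class = "FluctuationModel")
}

#' Sample an ensemble from a fluctuation model
#'
#' @param model a [fluctuationModel()].
#' @param nFrames number of frames (>= 2).
#' @param system optional [MolecularSystem-class]; defaults to a CA-only
#'   system matching the model size.
#' @return a [Trajectory-class].
#' @export
sampleFluctuationTrajectory <- function(model, nFrames, system = NULL) {
  if (nFrames < 2L) stop("nFrames must be >= 2", call. = FALSE)
  if (is.null(system)) system <- makeCASystem(model$n)$system
  set.seed(model$seed)
  n <- model$n
  drawDelta <- function() {
    if (model$mode == "recipe") {
      # independent x/y/z draws sharing the residue-level factor
      d <- array(0, c(nFrames, n, 3L))
      for (k in 1:3)
        d[, , k] <- matrix(stats::rnorm(nFrames * n), nFrames) %*% t(model$L)
      d
    } else {
      flat <- matrix(stats::rnorm(nFrames * 3L * n), nFrames) %*% t(model$L)
      d <- array(0, c(nFrames, n, 3L))
      for (k in 1:3) d[, , k] <- flat[, seq(k, 3L * n, by = 3L)]
      d
    }
  }
  delta <- drawDelta()
  if (model$ar1 > 0) {
    phi <- model$ar1; sc <- sqrt(1 - phi^2)
    for (f in 2:nFrames)
      delta[f, , ] <- phi * delta[f - 1L, , ] + sc * delta[f, , ]
  }
  co <- array(0, c(nFrames, n, 3L))
  for (k in 1:3)
    co[, , k] <- matrix(delta[, , k], nFrames, n) +
      matrix(model$reference[, k], nFrames, n, byrow = TRUE)
  newTrajectory(system, co)
}

# stationary distribution of a row-stochastic matrix
.stationaryDistribution <- function(P) {
  eg <- eigen(t(P))
  i <- which.min(abs(eg$values - 1))
  v <- abs(Re(eg$vectors[, i]))
  v / sum(v)
}

#' Sample a two/three-state Markov gate-distance series
#'
#' A first-order Markov chain over the gate states; the observed distance
#' at each frame is Normal(state mean, state sd). Hidden state labels are
#' returned as ground truth.
#'
#' @param means named numeric: per-state mean gate distance (nm), e.g.
#'   `c(closed = 0.3, open = 0.55, wide_open = 0.8)`.
#' @param sds per-state sd (nm), scalar or per state; 0 gives a
#'   deterministic emission.
#' @param transition row-stochastic transition matrix (rows/cols in the
#'   order of `means`); rows must sum to 1 within 1e-12.
#' @param nFrames chain length.
#' @param seed integer seed.
#' @param init initial state distribution (default: the stationary
#'   distribution of `transition`).
#' @return list with `distance` (nm) and `state` (labels).
#' @export
sampleGateSeries <- function(means, sds, transition, nFrames, seed = 1L,
                             init = NULL) {
  k <- length(means)
  transition <- as.matrix(transition)
  if (!all(dim(transition) == k))
    stop("transition matrix must be ", k, " x ", k, call. = FALSE)
  if (any(abs(rowSums(transition) - 1) > 1e-12))
    stop("transition matrix rows must sum to 1", call. = FALSE)
  if (any(sds < 0)) stop("state sds must be >= 0", call. = FALSE)
  sds <- rep_len(sds, k)
  if (is.null(init)) init <- .stationaryDistribution(transition)
  set.seed(seed)
  path <- integer(nFrames)
  path[1] <- sample.int(k, 1L, prob = init)
  for (f in seq_len(nFrames - 1L))
    path[f + 1L] <- sample.int(k, 1L, prob = transition[path[f], ])
  dist <- stats::rnorm(nFrames, mean = means[path], sd = sds[path])
  list(distance = as.numeric(dist),
       state = names(means)[path])
}

#' Impose a gate-distance series on a trajectory
#'
#' Per frame, the second atom of the pair is moved along the pair axis so
#' that the separation equals the series value (within 1e-9 nm); all other
#' atoms are untouched. Coincident pair atoms are separated along z.
#'
#' @param traj a [Trajectory-class].
#' @param pairAtoms integer(2): atom row indices of the gate pair.
#' @param series distances (nm), one per frame.
#' @return the modified [Trajectory-class].
#' @export
embedGateInStructure <- function(traj, pairAtoms, series) {
  if (pairAtoms[1] == pairAtoms[2])
    stop("gate pair atoms must be distinct", call. = FALSE)
  if (length(series) != nFrames(traj))
    stop("series length must equal the frame count", call. = FALSE)
  i <- pairAtoms[1]; j <- pairAtoms[2]
  co <- traj@coords
  for (f in seq_len(dim(co)[1])) {
    u <- co[f, j, ] - co[f, i, ]
    nu <- sqrt(sum(u^2))
    u <- if (nu < 1e-12) c(0, 0, 1) else u / nu
    co[f, j, ] <- co[f, i, ] + series[f] * u
  }
  newTrajectory(traj@system, co, traj@times)
}

#' Crooks-consistent Gaussian work samples with known free energy
#'
#' Forward work ~ Normal(dG + sigma^2/2, sigma^2) and reverse work ~
#' Normal(-dG + sigma^2/2, sigma^2), in kT units. This Gaussian pair
#' satisfies the Crooks fluctuation relation P_F(W) = P_R(-W) exp(W - dG)
#' exactly, so the generator's `true_dg` is the analytic ground truth for
#' [barEstimate()].
#'
#' @param trueDg ground-truth free-energy difference (kT).
#' @param sigma work fluctuation (kT), > 0.
#' @param nForward,nReverse sample sizes (> 0).
#' @param seed integer seed.
#' @return list with `forward`, `reverse` (kT) and `true_dg`.
#' @export
sampleCrooksWork <- function(trueDg, sigma, nForward, nReverse = nForward,
                             seed = 1L) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (nForward <= 0 || nReverse <= 0)
    stop("sample sizes must be positive", call. = FALSE)
  set.seed(seed)
  list(forward = stats::rnorm(nForward, trueDg + sigma^2 / 2, sigma),
       reverse = stats::rnorm(nReverse, -trueDg + sigma^2 / 2, sigma),
       true_dg = trueDg)
}

#' Matched reduced/PTMed ensemble fixture with known redistribution truth
#'
#' Samples the reduced replicas from a base correlation recipe and the
#' PTMed replicas from a perturbed recipe over the identical residue set.
#' Because the recipe correlations are the exact target DCCM, the
#' ground-truth redistribution score per residue is computed directly on
#' the two generative correlation matrices.
#'
#' @param base list with `corr` (n x n correlation matrix) and optional
#'   `sds` (default 0.1 nm).
#' @param perturb perturbed correlation matrix for the PTMed state
#'   (default: identical to `base$corr`).
#' @param nFrames frames per replica.
#' @param seed integer seed (replica seeds are derived from it).
#' @param replicas replicas per state (default 1).
#' @param threshold strong-correlation threshold used for the ground truth
#'   (default 0.2).
#' @return list with `pair` ([StatePair-class]), `truth`
#'   (data.frame(label, score, sign)), `corrReduced`, `corrPtm`.
#' @export
makeStatePairFixture <- function(base, perturb = NULL, nFrames = 1000L,
                                 seed = 1L, replicas = 1L,
                                 threshold = 0.2) {
  corrR <- as.matrix(base$corr)
  corrP <- if (is.null(perturb)) corrR else as.matrix(perturb)
  if (!all(dim(corrP) == dim(corrR)))
    stop("base and perturbation recipes must cover identical residue sets",
         call. = FALSE)
  n <- nrow(corrR)
  sds <- base$sds %||% 0.1
  cas <- makeCASystem(n)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * replicas)
  sampleState <- function(corr, seedOffset) {
    lapply(seq_len(replicas), function(r) {
      m <- fluctuationModel(cas$reference, sds = sds, corr = corr,
                            seed = seeds[seedOffset + r])
      sampleFluctuationTrajectory(m, nFrames, cas$system)
    })
  }
  pair <- new("StatePair",
              reduced = sampleState(corrR, 0L),
              ptm = sampleState(corrP, replicas),
              selection = "")
  labs <- .residueLabel("A", seq_len(n))
  dimnames(corrR) <- dimnames(corrP) <- list(labs, labs)
  truthScore <- redistributionScore(newDCCMatrix(corrR),
                                    newDCCMatrix(corrP), threshold)
  list(pair = pair,
       truth = data.frame(label = truthScore$label,
                          score = truthScore$score,
                          sign = sign(truthScore$score),
                          stringsAsFactors = FALSE),
       corrReduced = corrR, corrPtm = corrP)
}
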
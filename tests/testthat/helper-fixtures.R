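# Fixture builders shared across test files. Everything is generated in
# code; no binary data.

# minimal 4-atom / 2-residue topology table
toyAtomTable <- function() {
  data.frame(
    atom_id = 1:4,
    name = c("CA", "CB", "CA", "CB"),
    element = c("C", "C", "C", "C"),
    chain = "A",
    resid = c(1L, 1L, 2L, 2L),
    resname = c("ALA", "ALA", "SER", "SER"),
    charge = c(0.1, -0.1, 0.2, -0.2),
    sigma_nm = 0.34,
    epsilon_kcal = 0.1,
    mass = 12.011,
    stringsAsFactors = FALSE)
}

writeToyTopology <- function(path = tempfile(fileext = ".tsv")) {
  utils::write.table(toyAtomTable(), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# a gate/H-bond capable system: ASP33 (acceptor OD1) and ARG243
# (donor NH1 with hydrogen HH1) in one chain, plus CA atoms
gateHbondSystem <- function(chain = "A") {
  atoms <- data.frame(
    atom_id = 1:5,
    name = c("CA", "OD1", "CA", "NH1", "HH1"),
    element = c("C", "O", "C", "N", "H"),
    chain = chain,
    resid = c(33L, 33L, 243L, 243L, 243L),
    resname = c("ASP", "ASP", "ARG", "ARG", "ARG"),
    charge = c(0, -0.5, 0, 0.5, 0.3),
    sigma_nm = c(0.34, 0.30, 0.34, 0.32, 0.1),
    epsilon_kcal = 0.1,
    mass = c(12, 16, 12, 14, 1),
    stringsAsFactors = FALSE)
  newMolecularSystem(atoms)
}

# frames with a prescribed OD1-NH1 separation; HH1 sits on the N->O axis
# 0.1 nm from NH1 (perfectly linear donor geometry), CA atoms parked away
gateHbondTrajectory <- function(dists, system = gateHbondSystem()) {
  nf <- length(dists)
  co <- array(0, c(nf, 5L, 3L))
  for (f in seq_len(nf)) {
    d <- dists[f]
    co[f, 1, ] <- c(-0.5, 0.5, 0)        # CA of 33
    co[f, 2, ] <- c(0, 0, 0)             # OD1
    co[f, 3, ] <- c(d + 0.5, 0.5, 0)     # CA of 243
    co[f, 4, ] <- c(d, 0, 0)             # NH1
    co[f, 5, ] <- c(d - 0.1, 0, 0)       # HH1, toward OD1
  }
  newTrajectory(system, co)
}

# Metropolis chain on 3 states with stationary vector pi
metropolisTransition <- function(pi) {
  k <- length(pi)
  P <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    P[i, j] <- 0.5 * min(1, pi[j] / pi[i])
  diag(P) <- 1 - rowSums(P)
  P
}

# independent oracle: stationary distribution by brute-force power iteration
powerStationary <- function(P, iters = 10000L) {
  v <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(iters)) v <- as.numeric(v %*% P)
  v / sum(v)
}

# brute-force rigid-fit oracle: minimize RMSD over rotations (Euler angles)
# with multi-start Nelder-Mead, independent of the Kabsch construction
bruteForceFitRMSD <- function(mobile, reference) {
  rotmat <- function(a) {
    cx <- cos(a[1]); sx <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cz <- cos(a[3]); sz <- sin(a[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  obj <- function(a) sqrt(mean(rowSums((P %*% rotmat(a) - Q)^2)))
  best <- Inf
  set.seed(11)
  starts <- rbind(c(0, 0, 0),
                  matrix(stats::runif(3 * 20, -pi, pi), ncol = 3))
  for (s in seq_len(nrow(starts))) {
    o <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# donor at the origin, hydrogen 0.1 nm away at `devDeg` degrees off the
# donor->acceptor axis, acceptor at `dda` nm along x
hbFrame <- function(dda, devDeg) {
  th <- devDeg * pi / 180
  rbind(c(0, 0, 0),
        0.1 * c(cos(th), sin(th), 0),
        c(dda, 0, 0))
}

# a two-chain system: one "regulator" residue (chain O) plus enzyme
# residues including gate residues 33/241 in chain A
networkSystem <- function() {
  atoms <- data.frame(
    atom_id = 1:6,
    name = "CB",
    element = c("C", "N", "C", "O", "N", "C"),
    chain = c("O", "A", "A", "A", "A", "A"),
    resid = c(400L, 38L, 87L, 33L, 241L, 300L),
    resname = c("GLU", "LYS", "GLN", "ASP", "ARG", "ALA"),
    charge = c(-1, 1, 0, -1, 1, 0),
    sigma_nm = 0, epsilon_kcal = 0, mass = 12,
    stringsAsFactors = FALSE)
  newMolecularSystem(atoms)
}

# random rigid motion applied to every frame of a trajectory
contaminateRigid <- function(traj, seed = 99) {
  set.seed(seed)
  co <- trajCoords(traj)
  for (f in seq_len(dim(co)[1])) {
    a <- stats::runif(3, -pi, pi)
    cx <- cos(a[1]); sx <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cz <- cos(a[3]); sz <- sin(a[3])
    R <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    shift <- stats::runif(3, -2, 2)
    co[f, , ] <- sweep(matrix(co[f, , ], ncol = 3) %*% R, 2, shift, "+")
  }
  newTrajectory(trajSystem(traj), co, frameTimes(traj))
}
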
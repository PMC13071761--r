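#' Kabsch rigid-body superposition
#'
#' Least-squares superposition of one coordinate frame onto a reference by
#' translation plus a proper rotation (SVD construction with determinant
#' correction, so reflections are never introduced). The fit is computed on
#' `fitIdx` and applied to all atoms.
#'
#' @param mobile n x 3 matrix (nm).
#' @param reference n x 3 matrix (nm).
#' @param fitIdx atom indices used for the fit (default: all). At least 3
#'   non-collinear atoms are required.
#' @return list with `aligned` (n x 3), `rmsd` (nm, over the fit atoms),
#'   `rotation` (3 x 3, det +1) and `translation`.
#' @export
kabschSuperpose <- function(mobile, reference, fitIdx = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(fitIdx)) fitIdx <- seq_len(nrow(mobile))
  if (length(fitIdx) < 3L)
    stop("superposition needs at least 3 fit atoms", call. = FALSE)
  P <- mobile[fitIdx, , drop = FALSE]
  Q <- reference[fitIdx, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(Pc)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-30))
    stop("degenerate geometry: fit atoms are collinear", call. = FALSE)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  aligned <- sweep(sweep(mobile, 2, cp) %*% R, 2, cq, "+")
  rmsd <- sqrt(mean(rowSums((aligned[fitIdx, , drop = FALSE] - Q)^2)))
  list(aligned = aligned, rmsd = rmsd, rotation = R,
       translation = cq - c(cp %*% R))
}

# Iterative mean alignment of flat frames (frames x 3m): align to the
# first frame, recompute the mean, re-align, and repeat until the mean
# structure stabilizes. Converging (rather than a fixed pass count) makes
# the result independent of frame order up to a global rigid motion.
.iterativeMeanAlign <- function(X, tol = 1e-12, maxPasses = 50L) {
  alignTo <- function(X, refFlat) {
    ref <- .unflatFrame(refFlat)
    t(apply(X, 1, function(v)
      as.vector(t(kabschSuperpose(.unflatFrame(v), ref)$aligned))))
  }
  ref <- X[1, ]
  for (i in seq_len(maxPasses)) {
    X <- alignTo(X, ref)
    newRef <- colMeans(X)
    if (max(abs(newRef - ref)) < tol) { ref <- newRef; break }
    ref <- newRef
  }
  alignTo(X, ref)
}

# Aligned, pooled flat Calpha coordinates for a list of trajectories over a
# selection; each replica is aligned to its own iterated mean when fit=TRUE.
# Returns list(X, residues, frameCounts).
.pooledFluctCoords <- function(trajectories, selection = "", fit = TRUE) {
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  residues <- .selectionResidues(trajectories[[1]]@system, selection)
  if (!nrow(residues)) stop("empty selection", call. = FALSE)
  mats <- lapply(trajectories, function(tr) {
    idx <- .caIndices(tr@system, .selectionResidues(tr@system, selection))
    X <- .flatCoords(tr, idx)
    if (fit && nrow(X) > 1L && nrow(residues) >= 3L) X <- .iterativeMeanAlign(X)
    X
  })
  # bring every replica into the first replica's frame so pooling is
  # meaningful: rigid-fit each replica's mean structure onto the first's
  if (fit && length(mats) > 1L && nrow(residues) >= 3L) {
    ref <- .unflatFrame(colMeans(mats[[1]]))
    for (r in seq_along(mats)[-1L]) {
      f <- kabschSuperpose(.unflatFrame(colMeans(mats[[r]])), ref)
      mats[[r]] <- t(apply(mats[[r]], 1, function(v)
        as.vector(t(sweep(.unflatFrame(v) %*% f$rotation, 2, f$translation,
                          "+")))))
    }
  }
  list(X = do.call(rbind, mats), residues = residues,
       frameCounts = vapply(mats, nrow, integer(1)))
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2) of the Calpha positions, after
#' optional per-replica superposition to the iterated mean structure;
#' replicas are pooled after alignment and fluctuation is measured about the
#' pooled mean.
#'
#' @param trajectories a [Trajectory-class] or list of replicas.
#' @param selection selection label or residue keys ("" = all residues).
#' @param fit superpose frames before measuring (default TRUE).
#' @return data.frame(chain, resid, label, rmsf) in nm.
#' @export
rmsf <- function(trajectories, selection = "", fit = TRUE) {
  pooled <- .pooledFluctCoords(trajectories, selection, fit)
  X <- pooled$X
  if (nrow(X) < 2L) stop("RMSF needs at least 2 frames", call. = FALSE)
  D <- sweep(X, 2, colMeans(X))
  m <- nrow(pooled$residues)
  val <- vapply(seq_len(m), function(i) {
    cols <- (3L * (i - 1L) + 1L):(3L * i)
    sqrt(mean(rowSums(D[, cols, drop = FALSE]^2)))
  }, numeric(1))
  cbind(pooled$residues, rmsf = val)
}

#' Radius of gyration
#'
#' Rg = sqrt(sum_i w_i |r_i - r_com|^2 / sum_i w_i) with w the atomic mass
#' when `massWeighted`, else 1, over all atoms of the selected residues.
#'
#' @param traj a [Trajectory-class].
#' @param selection selection label or residue keys ("" = all residues).
#' @param massWeighted logical (default TRUE).
#' @return numeric vector, one Rg (nm) per frame.
#' @export
radiusOfGyration <- function(traj, selection = "", massWeighted = TRUE) {
  residues <- .selectionResidues(traj@system, selection)
  rows <- unlist(lapply(residues$label, .residueAtomRows,
                        system = traj@system))
  rows <- sort(unique(rows))
  if (!length(rows)) stop("empty selection", call. = FALSE)
  w <- if (massWeighted) traj@system@atoms$mass[rows] else rep(1, length(rows))
  if (sum(w) <= 0) stop("zero total mass", call. = FALSE)
  vapply(seq_len(nFrames(traj)), function(f) {
    xyz <- matrix(traj@coords[f, rows, ], ncol = 3L)
    com <- colSums(xyz * w) / sum(w)
    sqrt(sum(w * rowSums(sweep(xyz, 2, com)^2)) / sum(w))
  }, numeric(1))
}
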
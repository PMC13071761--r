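#' Common-eigenspace principal component analysis of a state pair
#'
#' Trajectories from both conditions are concatenated after structural
#' alignment (per-replica two-pass iterated-mean superposition, then a joint
#' alignment of the pooled frames to the combined mean), mean-centered, and
#' used to construct a single Calpha covariance matrix. The eigenvectors of
#' this combined ensemble form a common reference subspace onto which every
#' individual reduced and PTMed trajectory is projected, so centroid shifts
#' between states are measured in one coordinate system.
#'
#' Eigenvalues are clipped at zero; each eigenvector's largest-magnitude
#' component is made positive so projections are reproducible.
#'
#' @param pair a [StatePair-class].
#' @param selection selection label or residue keys ("" = all residues);
#'   overrides the pair's own selection when non-NULL.
#' @param nModes number of modes to keep projections for (default: all).
#' @return a [PCAResult-class].
#' @export
combinedPCA <- function(pair, selection = NULL, nModes = NULL) {
  if (is.null(selection)) selection <- pair@selection
  trajs <- c(pair@reduced, pair@ptm)
  states <- rep(c("reduced", "ptm"),
                c(length(pair@reduced), length(pair@ptm)))
  replicas <- c(seq_along(pair@reduced), seq_along(pair@ptm))

  resRef <- .selectionResidues(trajs[[1]]@system, selection)
  mats <- lapply(trajs, function(tr) {
    res <- .selectionResidues(tr@system, selection)
    if (nrow(res) != nrow(resRef))
      stop("mismatched selections across states", call. = FALSE)
    X <- .flatCoords(tr, .caIndices(tr@system, res))
    if (nrow(X) > 1L && nrow(res) >= 3L) X <- .iterativeMeanAlign(X)
    X
  })
  X <- do.call(rbind, mats)
  if (nrow(X) < 2L) stop("combined PCA needs at least 2 frames", call. = FALSE)
  if (nrow(resRef) >= 3L) X <- .iterativeMeanAlign(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  covm <- crossprod(Xc) / (nrow(Xc) - 1L)
  eg <- eigen(covm, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors
  for (j in seq_len(ncol(vecs))) {            # deterministic sign convention
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  tr <- sum(diag(covm))
  if (is.null(nModes)) nModes <- length(vals)
  nModes <- min(nModes, length(vals))

  frameCounts <- vapply(mats, nrow, integer(1))
  ends <- cumsum(frameCounts); starts <- c(1L, head(ends, -1L) + 1L)
  srcNames <- paste0(states, "_rep", replicas)
  projections <- lapply(seq_along(mats), function(i)
    Xc[starts[i]:ends[i], , drop = FALSE] %*% vecs[, seq_len(nModes), drop = FALSE])
  names(projections) <- srcNames
  sources <- data.frame(source = srcNames, state = states, replica = replicas,
                        group = "all", stringsAsFactors = FALSE)
  new("PCAResult", values = vals, vectors = vecs,
      varianceFractions = if (sum(vals) > 0) vals / sum(vals) else
        rep(0, length(vals)),
      trace = tr, projections = projections, sources = sources,
      residues = resRef, center = ctr)
}

#' Per-residue contribution of a principal mode
#'
#' The contribution of residue i to a mode is the Euclidean norm of its
#' (x, y, z) eigenvector components, normalized so contributions sum to 1
#' (the normalized per-residue Calpha displacement magnitude). The top set is
#' the minimal prefix of the descending-sorted residues whose cumulative
#' contribution reaches `fraction`; ties at the boundary are broken toward
#' the lower residue index.
#'
#' @param result a [PCAResult-class].
#' @param mode mode index (1 = PC1).
#' @param fraction cumulative-contribution target for the top set
#'   (default 0.5).
#' @return list with `mode`, `contributions` (data.frame(chain, resid,
#'   label, contribution)) and `topSet` (residue labels).
#' @export
modeResidueContributions <- function(result, mode = 1L, fraction = 0.5) {
  if (mode > ncol(result@vectors)) stop("mode out of range", call. = FALSE)
  v <- result@vectors[, mode]
  m <- nrow(result@residues)
  mag <- vapply(seq_len(m), function(i)
    sqrt(sum(v[(3L * (i - 1L) + 1L):(3L * i)]^2)), numeric(1))
  contrib <- mag / sum(mag)
  ord <- order(-contrib, seq_len(m))
  cum <- cumsum(contrib[ord])
  k <- which(cum >= fraction - 1e-12)[1]
  list(mode = mode,
       contributions = cbind(result@residues, contribution = contrib),
       topSet = result@residues$label[sort(ord[seq_len(k)])])
}

#' Project a trajectory onto the common eigenvectors
#'
#' Frames are superposed onto the PCA mean structure and projected onto the
#' shared modes. With `chains` given, the eigenvectors are masked to the
#' residues of those chains (subunit-level analyses reuse the complex-level
#' eigenvectors by masking rather than re-diagonalizing).
#'
#' @param result a [PCAResult-class].
#' @param traj a [Trajectory-class] over the same selection.
#' @param selection selection used to build `result`.
#' @param chains optional chain IDs to mask to.
#' @param nModes number of modes (default: ncol of stored projections).
#' @return frames x nModes projection matrix (nm).
#' @export
projectTrajectory <- function(result, traj, selection = "", chains = NULL,
                              nModes = NULL) {
  res <- .selectionResidues(traj@system, selection)
  if (nrow(res) != nrow(result@residues))
    stop("selection does not match the PCA residue set", call. = FALSE)
  X <- .flatCoords(traj, .caIndices(traj@system, res))
  ref <- .unflatFrame(result@center)
  X <- t(apply(X, 1, function(v)
    as.vector(t(kabschSuperpose(.unflatFrame(v), ref)$aligned))))
  Xc <- sweep(X, 2, result@center)
  if (is.null(nModes)) nModes <- ncol(result@projections[[1]])
  V <- result@vectors[, seq_len(nModes), drop = FALSE]
  if (!is.null(chains)) {
    mask <- rep(result@residues$chain %in% chains, each = 3L)
    V <- V * mask
  }
  Xc %*% V
}

#' Centroid shifts in principal-component space
#'
#' For each group of projection sources, the shift is the mean PTMed
#' projection minus the mean reduced projection, per mode, pooling frames
#' over the group's replicas.
#'
#' @param result a [PCAResult-class].
#' @param groups optional named character vector mapping source labels to
#'   group names; defaults to the groups stored in the result.
#' @param nModes number of modes to report (default: all stored).
#' @return matrix groups x modes of shifts (nm).
#' @export
centroidShift <- function(result, groups = NULL, nModes = NULL) {
  src <- result@sources
  if (!is.null(groups)) {
    if (!all(src$source %in% names(groups)))
      stop("groups must cover every projection source", call. = FALSE)
    src$group <- unname(groups[src$source])
  }
  if (is.null(nModes)) nModes <- ncol(result@projections[[1]])
  glabs <- unique(src$group)
  out <- matrix(NA_real_, length(glabs), nModes,
                dimnames = list(glabs, paste0("PC", seq_len(nModes))))
  for (g in glabs) {
    for (st in c("reduced", "ptm")) {
      keep <- src$source[src$group == g & src$state == st]
      if (!length(keep))
        stop("group '", g, "' has no ", st, " sources", call. = FALSE)
    }
    mean_state <- function(st) {
      keep <- src$source[src$group == g & src$state == st]
      colMeans(do.call(rbind, result@projections[keep]))[seq_len(nModes)]
    }
    out[g, ] <- mean_state("ptm") - mean_state("reduced")
  }
  out
}
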
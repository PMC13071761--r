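# Internal helpers: residue identity, selections, coordinate reshaping.
#
# A residue is identified by (chain, resid). A residue *key* is either
# "chain:resid" ("A:33") or a bare index ("33"), the latter matching the
# residue in every chain that has it. Bare keys are what the gate definitions
# use (residue 33 of each G6PDH subunit); chain-qualified keys disambiguate
# when a single residue of one chain is meant.

.residueLabel <- function(chain, resid) paste0(chain, ":", resid)

.parseResidueKey <- function(key) {
  key <- as.character(key)
  if (grepl(":", key, fixed = TRUE)) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    list(chain = parts[1], resid = as.integer(parts[2]))
  } else {
    list(chain = NA_character_, resid = as.integer(key))
  }
}

# atom row indices for one residue key (possibly across chains)
.residueAtomRows <- function(system, key) {
  k <- .parseResidueKey(key)
  a <- system@atoms
  hit <- a$resid == k$resid
  if (!is.na(k$chain)) hit <- hit & a$chain == k$chain
  which(hit)
}

# residue table (chain, resid, label) for a selection, in atom order.
# selection: "" or NULL -> all residues; a selection label of the system;
# or a vector of residue keys.
.selectionResidues <- function(system, selection = "") {
  a <- system@atoms
  all_res <- unique(a[, c("chain", "resid")])
  all_res$label <- .residueLabel(all_res$chain, all_res$resid)
  rownames(all_res) <- NULL
  if (is.null(selection) || identical(selection, "") || !length(selection))
    return(all_res)
  if (length(selection) == 1L && selection %in% names(system@selections))
    selection <- system@selections[[selection]]
  keep <- rep(FALSE, nrow(all_res))
  for (key in as.character(selection)) {
    k <- .parseResidueKey(key)
    hit <- all_res$resid == k$resid
    if (!is.na(k$chain)) hit <- hit & all_res$chain == k$chain
    if (!any(hit))
      stop("selection references unknown residue: ", key, call. = FALSE)
    keep <- keep | hit
  }
  res <- all_res[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# one representative atom per residue for fluctuation analyses: the Calpha,
# or the residue's single atom for coarse one-bead fixtures
.caIndices <- function(system, residues) {
  a <- system@atoms
  vapply(seq_len(nrow(residues)), function(i) {
    rows <- which(a$chain == residues$chain[i] & a$resid == residues$resid[i])
    ca <- rows[a$name[rows] == "CA"]
    if (length(ca)) return(ca[1])
    if (length(rows) == 1L) return(rows)
    stop("residue ", residues$label[i], " has no CA atom", call. = FALSE)
  }, integer(1))
}

# frames x 3m matrix (x1,y1,z1,x2,...) for the given atom indices
.flatCoords <- function(traj, atomIdx) {
  co <- traj@coords[, atomIdx, , drop = FALSE]
  nf <- dim(co)[1]; m <- dim(co)[2]
  out <- matrix(0, nf, 3L * m)
  for (k in 1:3) out[, seq(k, 3L * m, by = 3L)] <- co[, , k]
  out
}

.unflatFrame <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

.assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(name, " must be a single finite number", call. = FALSE)
}

# heavy atoms = everything that is not hydrogen
.isHeavy <- function(atoms) toupper(atoms$element) != "H"

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "HA")

#' Access the atom table of a system
#'
#' @param system a [MolecularSystem-class].
#' @return data.frame of atoms (one row per atom, topology order).
#' @export
systemAtoms <- function(system) system@atoms

#' Named residue selections of a system
#' @param system a [MolecularSystem-class].
#' @return named list of residue-key vectors.
#' @export
systemSelections <- function(system) system@selections

#' Residue table of a system
#'
#' @param system a [MolecularSystem-class].
#' @param selection optional selection label or residue-key vector.
#' @return data.frame(chain, resid, label), atom order.
#' @export
systemResidues <- function(system, selection = "") {
  .selectionResidues(system, selection)
}

#' Number of frames in a trajectory
#' @param traj a [Trajectory-class].
#' @return integer frame count.
#' @export
nFrames <- function(traj) dim(traj@coords)[1]

#' Coordinate array of a trajectory
#' @param traj a [Trajectory-class].
#' @return frames x atoms x 3 array (nm).
#' @export
trajCoords <- function(traj) traj@coords

#' Frame times of a trajectory
#' @param traj a [Trajectory-class].
#' @return numeric vector (ps).
#' @export
frameTimes <- function(traj) traj@times

#' Topology of a trajectory
#' @param traj a [Trajectory-class].
#' @return the [MolecularSystem-class] the trajectory references.
#' @export
trajSystem <- function(traj) traj@system

#' Values of a dynamic cross-correlation matrix
#' @param x a [DCCMatrix-class].
#' @return symmetric numeric matrix with residue labels.
#' @export
dccmValues <- function(x) x@values

#' Residues flagged as zero-fluctuation in a DCCM
#' @param x a [DCCMatrix-class].
#' @return character vector of residue labels.
#' @export
dccmZeroFluctuation <- function(x) x@zeroFluctuation

#' Eigenvalues of a PCA result
#' @param x a [PCAResult-class].
#' @return numeric vector (nm^2), descending.
#' @export
pcaEigenvalues <- function(x) x@values

#' Eigenvectors of a PCA result
#' @param x a [PCAResult-class].
#' @return 3m x k orthonormal matrix.
#' @export
pcaEigenvectors <- function(x) x@vectors

#' Variance fractions of a PCA result
#' @param x a [PCAResult-class].
#' @return numeric vector summing to 1.
#' @export
pcaVarianceFractions <- function(x) x@varianceFractions

#' Per-source projections of a PCA result
#' @param x a [PCAResult-class].
#' @return list of frames x k matrices (nm), described by [pcaSources()].
#' @export
pcaProjections <- function(x) x@projections

#' Source descriptions of a PCA result
#' @param x a [PCAResult-class].
#' @return data.frame(source, state, replica, group).
#' @export
pcaSources <- function(x) x@sources
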
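#' @import methods
NULL

REQUIRED_TOPOLOGY_COLUMNS <- c("atom_id", "name", "element", "chain", "resid",
                               "resname", "charge", "sigma_nm", "epsilon_kcal",
                               "mass")

#' MolecularSystem: topology container
#'
#' Holds the per-atom topology of a molecular system: atom identity, residue
#' and chain assignment, partial charges (e), Lennard-Jones parameters
#' (sigma in nm, epsilon in kcal/mol) and masses (Da), together with named
#' residue selections. Residue numbering is 1-based per chain and mirrors the
#' topology file; no renumbering is performed on load.
#'
#' @slot atoms data.frame with columns atom_id, name, element, chain, resid,
#'   resname, charge, sigma_nm, epsilon_kcal, mass (one row per atom, file
#'   order preserved).
#' @slot selections named list; each element is a character vector of residue
#'   keys, either bare residue indices ("33", matched in every chain) or
#'   chain-qualified ("A:33").
#' @exportClass MolecularSystem
setClass("MolecularSystem",
         representation(atoms = "data.frame", selections = "list"))

setValidity("MolecularSystem", function(object) {
  a <- object@atoms
  msgs <- character()
  missing <- setdiff(REQUIRED_TOPOLOGY_COLUMNS, names(a))
  if (length(missing))
    return(paste0("missing topology column(s): ", paste(missing, collapse = ", ")))
  if (anyDuplicated(a$atom_id))
    msgs <- c(msgs, paste0("duplicated atom_id: ",
                           paste(unique(a$atom_id[duplicated(a$atom_id)]), collapse = ", ")))
  if (any(!is.finite(a$charge))) msgs <- c(msgs, "non-finite charge")
  if (any(a$sigma_nm < 0)) msgs <- c(msgs, "negative lj sigma")
  if (any(a$epsilon_kcal < 0)) msgs <- c(msgs, "negative lj epsilon")
  if (any(a$mass <= 0)) msgs <- c(msgs, "non-positive mass")
  for (lab in names(object@selections)) {
    bad <- vapply(object@selections[[lab]], function(k)
      length(.residueAtomRows(object, k)) == 0L, logical(1))
    if (any(bad))
      msgs <- c(msgs, paste0("selection '", lab, "' references unknown residue(s): ",
                             paste(object@selections[[lab]][bad], collapse = ", ")))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Trajectory: coordinate ensemble tied to one topology
#'
#' Frames-by-atoms-by-3 coordinate array in nm with strictly increasing frame
#' times in ps. PDB input is converted from Angstrom at the I/O boundary; all
#' internal lengths are nm.
#'
#' @slot system a [MolecularSystem-class].
#' @slot coords numeric array, dim = c(n_frames, n_atoms, 3), nm.
#' @slot times numeric, ps, strictly increasing, length n_frames.
#' @exportClass Trajectory
setClass("Trajectory",
         representation(system = "MolecularSystem", coords = "array",
                        times = "numeric"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    return("coords must be a frames x atoms x 3 array")
  if (d[2] != nrow(object@system@atoms))
    return(sprintf("coords has %d atoms but the topology has %d",
                   d[2], nrow(object@system@atoms)))
  if (any(!is.finite(object@coords)))
    return("non-finite coordinates")
  if (length(object@times) != d[1])
    return("times length must equal frame count")
  if (d[1] > 1L && any(diff(object@times) <= 0))
    return("frame times must be strictly increasing")
  TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' StatePair: matched reduced / PTMed trajectory replica sets
#'
#' The unit of every comparative analysis: replica trajectories of the fully
#' reduced complex and of the PTMed complex over an identical residue
#' selection.
#'
#' @slot reduced list of [Trajectory-class] replicas (reduced state).
#' @slot ptm list of [Trajectory-class] replicas (PTMed state).
#' @slot selection character(1), a selection label shared by all topologies,
#'   or "" for all residues.
#' @exportClass StatePair
setClass("StatePair",
         representation(reduced = "list", ptm = "list", selection = "character"))

setValidity("StatePair", function(object) {
  trjs <- c(object@reduced, object@ptm)
  if (!length(object@reduced) || !length(object@ptm))
    return("both states need at least one trajectory")
  if (!all(vapply(trjs, is, logical(1), "Trajectory")))
    return("reduced and ptm must be lists of Trajectory objects")
  counts <- vapply(trjs, function(t)
    nrow(.selectionResidues(t@system, object@selection)), integer(1))
  if (length(unique(counts)) != 1L)
    return("trajectories disagree on the shared selection size")
  TRUE
})

#' DCCMatrix: residue-residue dynamic cross-correlation matrix
#'
#' Symmetric matrix of normalized cross-correlation coefficients of Calpha
#' positional fluctuations, values in [-1, 1], unit diagonal. Residues with
#' zero fluctuation get 0-valued off-diagonal rows/columns and are flagged.
#'
#' @slot values symmetric numeric matrix with residue labels as dimnames.
#' @slot zeroFluctuation character vector of residue labels whose fluctuation
#'   was numerically zero.
#' @exportClass DCCMatrix
setClass("DCCMatrix",
         representation(values = "matrix", zeroFluctuation = "character"))

setValidity("DCCMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (max(abs(v - t(v))) > 1e-9) return("matrix must be symmetric within 1e-9")
  if (max(abs(diag(v) - 1)) > 1e-9 &&
      !all(rownames(v)[abs(diag(v) - 1) > 1e-9] %in% object@zeroFluctuation))
    return("diagonal must be 1 within 1e-9 (except flagged residues)")
  if (any(v < -1 - 1e-9 | v > 1 + 1e-9)) return("values must lie in [-1, 1]")
  TRUE
})

#' PCAResult: common-eigenspace principal component analysis
#'
#' Eigen decomposition of the covariance of concatenated, aligned,
#' mean-centered Calpha coordinates of both states, plus per-source
#' projections against the shared eigenvectors.
#'
#' @slot values eigenvalues (nm^2), descending, clipped at 0.
#' @slot vectors orthonormal eigenvectors, 3m x k (m selected residues).
#' @slot varianceFractions eigenvalue / total trace (all eigenvalues).
#' @slot trace total positional variance (nm^2).
#' @slot projections list of frames x k matrices (nm), one per source.
#' @slot sources data.frame(source, state, replica, group) describing each
#'   projection.
#' @slot residues data.frame(chain, resid, label) of the m selected residues.
#' @slot center the 3m-vector mean structure used for centering (nm).
#' @exportClass PCAResult
setClass("PCAResult",
         representation(values = "numeric", vectors = "matrix",
                        varianceFractions = "numeric", trace = "numeric",
                        projections = "list", sources = "data.frame",
                        residues = "data.frame", center = "numeric"))

setValidity("PCAResult", function(object) {
  if (any(object@values < -1e-10)) return("eigenvalues must be >= -1e-10")
  vfSum <- sum(object@varianceFractions)
  degenerate <- sum(object@values) == 0 && vfSum == 0
  if (abs(vfSum - 1) > 1e-9 && !degenerate)
    return("variance fractions must sum to 1 within 1e-9")
  g <- crossprod(object@vectors)
  if (max(abs(g - diag(ncol(g)))) > 1e-9)
    return("eigenvectors must be orthonormal within 1e-9")
  TRUE
})

setMethod("show", "MolecularSystem", function(object) {
  a <- object@atoms
  cat("MolecularSystem:", nrow(a), "atoms,",
      nrow(unique(a[, c("chain", "resid")])), "residues,",
      length(unique(a$chain)), "chain(s)\n")
  if (length(object@selections))
    cat("  selections:", paste(names(object@selections), collapse = ", "), "\n")
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat("Trajectory:", d[1], "frames x", d[2], "atoms (nm);",
      "t =", object@times[1], "...", object@times[d[1]], "ps\n")
})

setMethod("show", "StatePair", function(object) {
  cat("StatePair: ", length(object@reduced), " reduced / ",
      length(object@ptm), " ptm replica(s); selection = '",
      object@selection, "'\n", sep = "")
})

setMethod("show", "DCCMatrix", function(object) {
  cat("DCCMatrix:", nrow(object@values), "x", ncol(object@values), "residues")
  if (length(object@zeroFluctuation))
    cat(";", length(object@zeroFluctuation), "zero-fluctuation residue(s) flagged")
  cat("\n")
})

setMethod("show", "PCAResult", function(object) {
  k <- min(3L, length(object@values))
  cat("PCAResult:", length(object@values), "modes over",
      nrow(object@residues), "residues\n")
  cat("  variance fractions:",
      paste(sprintf("PC%d %.1f%%", seq_len(k),
                    100 * object@varianceFractions[seq_len(k)]), collapse = ", "),
      "\n")
})
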
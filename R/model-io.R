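#' Read a topology table into a MolecularSystem
#'
#' Accepts the tab-separated topology format (header columns `atom_id, name,
#' element, chain, resid, resname, charge, sigma_nm, epsilon_kcal, mass`) or
#' an equivalent JSON document with an `atoms` record array and an optional
#' `selections` object. Residue indices are taken verbatim (1-based per
#' chain); lengths are nm, energies kcal/mol, charges e, masses Da.
#'
#' @param path topology file (.tsv/.txt or .json).
#' @param selections optional path to a selections JSON
#'   (`{label: [residue keys]}`) merged into the system, or a named list.
#' @return a validated [MolecularSystem-class].
#' @export
loadTopology <- function(path, selections = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    atoms <- as.data.frame(doc$atoms, stringsAsFactors = FALSE)
    sel <- lapply(doc$selections, as.character)
  } else {
    atoms <- utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE, comment.char = "#")
    sel <- list()
  }
  missing <- setdiff(REQUIRED_TOPOLOGY_COLUMNS, names(atoms))
  if (length(missing))
    stop("topology is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  atoms <- atoms[, REQUIRED_TOPOLOGY_COLUMNS]
  atoms$atom_id <- as.integer(atoms$atom_id)
  atoms$resid <- as.integer(atoms$resid)
  atoms$chain <- as.character(atoms$chain)
  if (!is.null(selections)) {
    extra <- if (is.character(selections) && length(selections) == 1L)
      lapply(jsonlite::fromJSON(selections), as.character)
    else lapply(selections, as.character)
    sel[names(extra)] <- extra
  }
  newMolecularSystem(atoms, sel)
}

#' Construct a MolecularSystem from an atom table
#'
#' @param atoms data.frame with the topology columns (see [loadTopology()]).
#' @param selections named list of residue-key vectors.
#' @return a validated [MolecularSystem-class].
#' @export
newMolecularSystem <- function(atoms, selections = list()) {
  new("MolecularSystem", atoms = as.data.frame(atoms),
      selections = as.list(selections))
}

#' Write a topology table
#'
#' @param system a [MolecularSystem-class].
#' @param path output TSV path.
#' @param selectionsPath optional path for a selections JSON.
#' @return `path`, invisibly.
#' @export
writeTopology <- function(system, path, selectionsPath = NULL) {
  utils::write.table(system@atoms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(selectionsPath))
    jsonlite::write_json(system@selections, selectionsPath)
  invisible(path)
}

#' Construct a Trajectory from a coordinate array
#'
#' @param system a [MolecularSystem-class].
#' @param coords frames x atoms x 3 array (nm).
#' @param times frame times in ps; defaults to 0, 1, 2, ...
#' @return a validated [Trajectory-class].
#' @export
newTrajectory <- function(system, coords, times = NULL) {
  if (is.null(times)) times <- seq_len(dim(coords)[1]) - 1
  new("Trajectory", system = system, coords = coords, times = as.numeric(times))
}

#' Load a coordinate ensemble (multi-model PDB or XYZ)
#'
#' Multi-model PDB (MODEL/ENDMDL) is the canonical interchange format; XYZ is
#' accepted as an equivalent plain-text encoding. Both store Angstrom and are
#' converted to nm on load. Frames keep file order; in the absence of time
#' stamps frames are assigned 0, 1, 2, ... ps.
#'
#' @param path trajectory file.
#' @param system the [MolecularSystem-class] the coordinates belong to.
#' @param format "auto" (by extension), "pdb" or "xyz".
#' @return a [Trajectory-class] with coordinates in nm.
#' @export
loadTrajectory <- function(path, system, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  natoms <- nrow(system@atoms)
  co <- if (format == "pdb") .readPDBCoords(path, natoms) else
    .readXYZCoords(path, natoms)
  if (dim(co)[1] == 0L) stop("trajectory has zero frames: ", path, call. = FALSE)
  newTrajectory(system, co / 10)  # Angstrom -> nm
}

# Per-model atom counts from the raw PDB text, so mismatches are reported
# with the offending frame; bio3d does the actual record parsing.
.readPDBCoords <- function(path, natoms) {
  lines <- readLines(path)
  isAtom <- grepl("^(ATOM  |HETATM)", lines)
  starts <- grep("^MODEL", lines)
  if (length(starts)) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(starts))
      stop("unbalanced MODEL/ENDMDL records in ", path, call. = FALSE)
    counts <- mapply(function(s, e) sum(isAtom[s:e]), starts, ends)
  } else counts <- sum(isAtom)
  if (!length(counts) || all(counts == 0))
    stop("trajectory has zero frames: ", path, call. = FALSE)
  bad <- which(counts != natoms)
  if (length(bad))
    stop(sprintf("frame %d has %d atoms but the topology has %d",
                 bad[1], counts[bad[1]], natoms), call. = FALSE)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  co <- array(0, c(nf, natoms, 3L))
  for (k in 1:3) co[, , k] <- xyz[, seq(k, 3L * natoms, by = 3L), drop = FALSE]
  co
}

.readXYZCoords <- function(path, natoms) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  frames <- list(); i <- 1L; frame <- 0L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    frame <- frame + 1L
    if (is.na(n)) stop("malformed XYZ atom count at frame ", frame, call. = FALSE)
    if (n != natoms)
      stop(sprintf("frame %d has %d atoms but the topology has %d",
                   frame, n, natoms), call. = FALSE)
    block <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(block), "\\s+")
    frames[[frame]] <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    i <- i + 2L + n
  }
  if (!length(frames)) stop("trajectory has zero frames: ", path, call. = FALSE)
  co <- array(0, c(length(frames), natoms, 3L))
  for (f in seq_along(frames)) co[f, , ] <- frames[[f]]
  co
}

#' Write a trajectory as multi-model PDB
#'
#' Coordinates are converted nm -> Angstrom on output.
#'
#' @param traj a [Trajectory-class].
#' @param path output path.
#' @param bfactor optional per-atom vector written into the B-factor column
#'   (e.g. a per-residue score expanded to atoms, for structure mapping).
#' @return `path`, invisibly.
#' @export
writeTrajectoryPDB <- function(traj, path, bfactor = NULL) {
  a <- traj@system@atoms
  if (is.null(bfactor)) bfactor <- rep(0, nrow(a))
  con <- file(path, "w"); on.exit(close(con))
  nf <- nFrames(traj)
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj@coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    nm4 <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                  sprintf(" %-3s", a$name))
    writeLines(sprintf(
      "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$atom_id %% 100000L, nm4, substr(a$resname, 1, 3), a$chain, a$resid,
      xyz[, 1] * 10, xyz[, 2] * 10, xyz[, 3] * 10, 1, bfactor,
      toupper(a$element)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a trajectory in XYZ format
#'
#' @param traj a [Trajectory-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrajectoryXYZ <- function(traj, path) {
  a <- traj@system@atoms
  con <- file(path, "w"); on.exit(close(con))
  for (f in seq_len(nFrames(traj))) {
    xyz <- traj@coords[f, , , drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    writeLines(c(sprintf("%d", nrow(a)), sprintf("frame %d", f)), con)
    writeLines(sprintf("%-2s %14.6f %14.6f %14.6f", toupper(a$element),
                       xyz[, 1] * 10, xyz[, 2] * 10, xyz[, 3] * 10), con)
  }
  invisible(path)
}

SINGLE_SITE_PTM_TYPES <- c("sulfenylated", "nitrosylated", "glutathionylated")

#' Enumerate the PTM simulation plan
#'
#' One system per (cysteine site x PTM type) plus one fully reduced baseline,
#' each expanded over replicas (replicas expand last; the baseline counts as
#' one system regardless of replica count). With 11 cysteines, 3 PTM types
#' and 1 replica this yields the 34-system plan; with 3 replicas, 102 cases.
#'
#' @param system a [MolecularSystem-class]; cysteine sites are residues with
#'   resname "CYS".
#' @param ptmTypes character subset of
#'   `c("sulfenylated", "nitrosylated", "glutathionylated")`. Disulfide
#'   systems pair two sites and are specified explicitly, not enumerated.
#' @param replicas integer >= 1.
#' @return data.frame(site, chain, ptm_type, replica); the reduced baseline
#'   has `site = NA` and `ptm_type = "reduced"`.
#' @export
enumeratePtmSystems <- function(system, ptmTypes = SINGLE_SITE_PTM_TYPES,
                                replicas = 1L) {
  ptmTypes <- unique(setdiff(ptmTypes, "reduced"))
  if (!length(ptmTypes)) stop("ptmTypes must be non-empty", call. = FALSE)
  bad <- setdiff(ptmTypes, SINGLE_SITE_PTM_TYPES)
  if (length(bad))
    stop("unsupported ptm type(s) for enumeration: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (replicas < 1L) stop("replicas must be >= 1", call. = FALSE)
  a <- system@atoms
  cys <- unique(a[a$resname == "CYS", c("chain", "resid")])
  base <- data.frame(site = NA_integer_, chain = NA_character_,
                     ptm_type = "reduced", stringsAsFactors = FALSE)
  if (nrow(cys) == 0L) {
    warning("system has no cysteines; plan contains the reduced baseline only")
    plan <- base
  } else {
    mods <- expand.grid(i = seq_len(nrow(cys)), ptm_type = ptmTypes,
                        stringsAsFactors = FALSE)
    plan <- rbind(data.frame(site = cys$resid[mods$i], chain = cys$chain[mods$i],
                             ptm_type = mods$ptm_type, stringsAsFactors = FALSE),
                  base)
  }
  out <- plan[rep(seq_len(nrow(plan)), each = replicas), ]
  out$replica <- rep(seq_len(replicas), times = nrow(plan))
  rownames(out) <- NULL
  out
}

#' Production-run plan for the binary-complex comparison
#'
#' The comparative design: per condition (reduced, PTMed), a number of
#' independent replicas of a given production length.
#'
#' @param states condition labels.
#' @param replicas replicas per condition (default 3).
#' @param lengthNs production length per replica in ns (default 500).
#' @return data.frame(state, replica, length_ns).
#' @export
productionPlan <- function(states = c("reduced", "ptm"), replicas = 3L,
                           lengthNs = 500) {
  data.frame(state = rep(states, each = replicas),
             replica = rep(seq_len(replicas), times = length(states)),
             length_ns = lengthNs, stringsAsFactors = FALSE)
}

#' The 13-value coupling-parameter schedule
#'
#' The alchemical decoupling schedule used per stage: lambda from 0.00 to
#' 1.00 over 13 windows, dense near the endpoints.
#'
#' @return numeric vector of 13 lambda values.
#' @export
defaultLambdaSchedule <- function() {
  c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 1)
}

#' Enumerate alchemical lambda windows across decoupling stages
#'
#' Electrostatic contributions are decoupled first, then van der Waals,
#' masses and bonded terms; each stage runs the full lambda schedule, so a
#' 13-value schedule over the two stages yields 26 windows.
#'
#' @param schedule strictly increasing lambda values from 0.0 to 1.0.
#' @param stages ordered character vector of stage names; if
#'   "electrostatics" is present it is forced first.
#' @return data.frame(stage, lambda_value), electrostatics first.
#' @export
enumerateTiWindows <- function(schedule = defaultLambdaSchedule(),
                               stages = c("electrostatics", "vdw_bonded")) {
  if (length(schedule) < 2L || schedule[1] != 0 ||
      schedule[length(schedule)] != 1 || any(diff(schedule) <= 0))
    stop("schedule must be strictly increasing from 0.0 to 1.0", call. = FALSE)
  if (!length(stages)) stop("at least one stage is required", call. = FALSE)
  if ("electrostatics" %in% stages)
    stages <- c("electrostatics", setdiff(stages, "electrostatics"))
  data.frame(stage = rep(stages, each = length(schedule)),
             lambda_value = rep(schedule, times = length(stages)),
             stringsAsFactors = FALSE)
}
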
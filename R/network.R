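COULOMB_KCAL_A <- 332.0636  # kcal * Angstrom / (mol * e^2)

NEGATIVE_RESIDUES <- c("ASP", "GLU")
POSITIVE_RESIDUES <- c("ARG", "LYS")

# atom rows for a chain-qualified residue key; errors if ambiguous
.uniqueResidueRows <- function(system, key) {
  rows <- .residueAtomRows(system, key)
  if (!length(rows))
    stop("cannot resolve residue '", key, "'", call. = FALSE)
  a <- system@atoms[rows, ]
  if (length(unique(a$chain)) > 1L)
    stop("residue key '", key, "' is ambiguous across chains; ",
         "qualify it as 'chain:resid'", call. = FALSE)
  rows
}

#' Frame-averaged residue-residue nonbonded interaction energy
#'
#' Sums, over all atom pairs between two residues, the Coulomb energy
#' k_e q_a q_b / (eps r) (k_e = 332.0636 kcal A / (mol e^2)) and the
#' Lennard-Jones energy 4 eps_ab ((sigma_ab/r)^12 - (sigma_ab/r)^6) with
#' Lorentz-Berthelot combination, then averages over the pooled frames of
#' all supplied trajectories. No distance cutoff is applied by default.
#'
#' @param system a [MolecularSystem-class] carrying charges and LJ
#'   parameters.
#' @param trajectories a [Trajectory-class] or list of replicas.
#' @param residueI,residueJ chain-qualified residue keys.
#' @param dielectric relative dielectric constant (default 1).
#' @param cutoff optional pair-distance cutoff in nm (pairs beyond it
#'   contribute 0 in that frame).
#' @return data.frame(residue_i, residue_j, coulomb, lj, total, n_frames)
#'   in kcal/mol.
#' @export
pairNonbondedEnergy <- function(system, trajectories, residueI, residueJ,
                                dielectric = 1, cutoff = NULL) {
  if (identical(residueI, residueJ))
    stop("residues must be distinct", call. = FALSE)
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  ri <- .uniqueResidueRows(system, residueI)
  rj <- .uniqueResidueRows(system, residueJ)
  if (length(intersect(ri, rj)))
    stop("residues must be distinct", call. = FALSE)
  a <- system@atoms
  for (r in c(ri, rj))
    if (!is.finite(a$charge[r]) || !is.finite(a$sigma_nm[r]) ||
        !is.finite(a$epsilon_kcal[r]))
      stop("missing nonbonded parameters for atom ", a$atom_id[r],
           call. = FALSE)
  coul <- 0; lj <- 0; nf <- 0L
  for (tr in trajectories) {
    co <- tr@coords
    for (i in ri) for (j in rj) {
      r2 <- (co[, i, 1] - co[, j, 1])^2 + (co[, i, 2] - co[, j, 2])^2 +
        (co[, i, 3] - co[, j, 3])^2
      r <- sqrt(r2)
      keep <- if (is.null(cutoff)) rep(TRUE, length(r)) else r <= cutoff
      qq <- a$charge[i] * a$charge[j]
      ec <- ifelse(keep, COULOMB_KCAL_A * qq / (dielectric * 10 * r), 0)
      sij <- (a$sigma_nm[i] + a$sigma_nm[j]) / 2
      eij <- sqrt(a$epsilon_kcal[i] * a$epsilon_kcal[j])
      el <- if (sij > 0 && eij > 0) {
        sr6 <- (sij / r)^6
        ifelse(keep, 4 * eij * (sr6^2 - sr6), 0)
      } else 0
      coul <- coul + sum(ec)
      lj <- lj + sum(el)
    }
    nf <- nf + nFrames(tr)
  }
  data.frame(residue_i = residueI, residue_j = residueJ,
             coulomb = coul / nf, lj = lj / nf,
             total = (coul + lj) / nf, n_frames = nf,
             stringsAsFactors = FALSE)
}

#' Pairwise nonbonded energy table between two residue sets
#'
#' @param system a [MolecularSystem-class].
#' @param trajectories a [Trajectory-class] or list of replicas.
#' @param setA,setB character vectors of chain-qualified residue keys.
#' @param ... passed to [pairNonbondedEnergy()].
#' @return data.frame, one [pairNonbondedEnergy()] row per (A, B) pair.
#' @export
energyTable <- function(system, trajectories, setA, setB, ...) {
  rows <- list()
  for (i in setA) for (j in setB)
    if (!identical(i, j))
      rows[[length(rows) + 1L]] <-
        pairNonbondedEnergy(system, trajectories, i, j, ...)
  do.call(rbind, rows)
}

#' Select strongly interacting residue pairs
#'
#' Keeps pairs whose frame-averaged total energy is strictly above
#' `threshold` or strictly below `-threshold` kcal/mol.
#'
#' @param energies data.frame with a `total` column (kcal/mol).
#' @param threshold positive energy threshold (default 10).
#' @return the filtered data.frame.
#' @export
strongInteractions <- function(energies, threshold = 10) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  energies[energies$total > threshold | energies$total < -threshold, ,
           drop = FALSE]
}

#' Charge category of a residue-pair interaction
#'
#' ASP/GLU are negative, ARG/LYS positive; HIS is polar/uncharged by
#' default. Two same-sign residues give "like_charged", opposite signs
#' "oppositely_charged", exactly one charged partner "polar_charged", and
#' neither charged "other".
#'
#' @param resnameI,resnameJ 3-letter residue names.
#' @param hisPositive treat HIS as positively charged (default FALSE).
#' @return category string.
#' @export
classifyEdge <- function(resnameI, resnameJ, hisPositive = FALSE) {
  pos <- POSITIVE_RESIDUES
  if (hisPositive) pos <- c(pos, "HIS")
  sgn <- function(rn) {
    rn <- toupper(rn)
    ifelse(rn %in% NEGATIVE_RESIDUES, -1L, ifelse(rn %in% pos, 1L, 0L))
  }
  si <- sgn(resnameI); sj <- sgn(resnameJ)
  ifelse(si != 0L & sj != 0L,
         ifelse(si == sj, "like_charged", "oppositely_charged"),
         ifelse(xor(si != 0L, sj != 0L), "polar_charged", "other"))
}

.resnameOf <- function(system, key) {
  rows <- .residueAtomRows(system, key)
  system@atoms$resname[rows[1]]
}

.chainOf <- function(system, key) {
  rows <- .residueAtomRows(system, key)
  unique(system@atoms$chain[rows])[1]
}

#' Build layered interaction flow graphs grouped by gate state
#'
#' Constructs, per gate-state group, a layered directed graph tracing how
#' strong nonbonded interactions propagate from regulator (OpcA) regions
#' through intermediate enzyme residues to the gate residues. Intermediate
#' nodes are enzyme residues that interact strongly with a gate residue;
#' when they also interact strongly with a regulator region the
#' regulator-to-intermediate edge is included, otherwise the path has
#' limited regulator involvement and starts at the intermediate. Edges are
#' labeled with their mean energy and charge category; every edge passes
#' the strong-interaction threshold by construction.
#'
#' Gate-state groups collapse the per-subunit classification labels:
#' "open_closed" and "closed" keep their own group, "open" and "wide_open"
#' share the "open_or_wide" group.
#'
#' @param system a [MolecularSystem-class].
#' @param opcaEdges strong-interaction data.frame (regulator residue in
#'   `residue_i`, enzyme residue in `residue_j`), e.g. filtered
#'   [energyTable()] output.
#' @param gateEdges strong-interaction data.frame (enzyme residue in
#'   `residue_i`, gate residue in `residue_j`).
#' @param gateStates named character vector: chain -> gate label from
#'   [classifyGate()].
#' @param opcaRegion optional named character vector mapping regulator
#'   residue keys to region names (stored as a node attribute).
#' @return named list of igraph objects, one per gate-state group present.
#' @export
buildFlowGraph <- function(system, opcaEdges, gateEdges, gateStates,
                           opcaRegion = NULL) {
  groupOf <- function(label) {
    switch(label, open = "open_or_wide", wide_open = "open_or_wide", label)
  }
  edgeSets <- list(); gateNodes <- list(); midNodes <- list()
  for (chain in names(gateStates)) {
    grp <- groupOf(gateStates[[chain]])
    ge <- gateEdges[vapply(gateEdges$residue_j, .chainOf, "",
                           system = system) == chain, , drop = FALSE]
    if (!nrow(ge)) next
    intermediates <- unique(ge$residue_i)
    oe <- opcaEdges[opcaEdges$residue_j %in% intermediates, , drop = FALSE]
    edges <- rbind(
      if (nrow(oe)) data.frame(from = oe$residue_i, to = oe$residue_j,
                               energy = oe$total, stringsAsFactors = FALSE),
      data.frame(from = ge$residue_i, to = ge$residue_j, energy = ge$total,
                 stringsAsFactors = FALSE))
    edgeSets[[grp]] <- rbind(edgeSets[[grp]], edges)
    gateNodes[[grp]] <- union(gateNodes[[grp]], ge$residue_j)
    midNodes[[grp]] <- union(midNodes[[grp]], intermediates)
  }
  graphs <- list()
  for (grp in names(edgeSets)) {
    edges <- unique(edgeSets[[grp]])
    edges$category <- mapply(function(i, j)
      classifyEdge(.resnameOf(system, i), .resnameOf(system, j)),
      edges$from, edges$to)
    g <- igraph::graph_from_data_frame(edges, directed = TRUE)
    igraph::V(g)$layer <-
      ifelse(igraph::V(g)$name %in% gateNodes[[grp]], "gate",
             ifelse(igraph::V(g)$name %in% midNodes[[grp]],
                    "g6pdh_intermediate", "opca_region"))
    if (!is.null(opcaRegion)) {
      reg <- rep(NA_character_, igraph::vcount(g))
      hit <- igraph::V(g)$name %in% names(opcaRegion)
      reg[hit] <- opcaRegion[igraph::V(g)$name[hit]]
      igraph::V(g)$region <- reg
    }
    graphs[[grp]] <- g
  }
  graphs
}

#' Write flow graphs as GraphML and a layered JSON description
#'
#' @param graphs named list from [buildFlowGraph()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeFlowGraphs <- function(graphs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  desc <- lapply(names(graphs), function(grp) {
    g <- graphs[[grp]]
    p <- file.path(dir, paste0("flow_", grp, ".graphml"))
    igraph::write_graph(g, p, format = "graphml")
    paths[[length(paths) + 1L]] <<- p
    ed <- igraph::as_data_frame(g, what = "edges")
    list(group = grp,
         nodes = data.frame(name = igraph::V(g)$name,
                            layer = igraph::V(g)$layer,
                            stringsAsFactors = FALSE),
         edges = ed)
  })
  jp <- file.path(dir, "flow_graphs.json")
  jsonlite::write_json(desc, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}
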
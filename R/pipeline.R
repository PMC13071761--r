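REPORT_SCHEMA_VERSION <- "1.0"

#' Default analysis configuration
#'
#' Every threshold defaults to the study's stated value: strong-correlation
#' threshold 0.2, strong-interaction threshold 10 kcal/mol, gate bands at
#' 0.4 and 0.7 nm, hydrogen-bond cutoffs 0.35 nm and 30 degrees, gate
#' residues 33/37 (lower) and 241/243 (upper). The configuration echo is
#' written verbatim into every report; nothing is silent.
#'
#' @return nested list of defaults, to be merged with user configuration.
#' @export
defaultAnalysisConfig <- function() {
  list(
    thresholds = list(correlation = 0.2, energy = 10,
                      gate_bands = c(0.4, 0.7),
                      hbond = list(distance = 0.35, angle = 30)),
    gate = list(lower = c(33, 37), upper = c(241, 243),
                mode = "min_sidechain_heavy"),
    pca = list(n_modes = 2L),
    selection = "",
    seed = 1L,
    trajectory_format = "auto"
  )
}

.mergeConfig <- function(defaults, user) {
  named <- function(x) is.list(x) && length(x) > 0 &&
    !is.null(names(x)) && all(nzchar(names(x)))
  for (k in names(user)) {
    if (named(user[[k]]) && named(defaults[[k]]))
      defaults[[k]] <- .mergeConfig(defaults[[k]], user[[k]])
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

.stageLog <- function(stage, quiet) {
  if (!quiet) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), stage))
}

.runStage <- function(stage, quiet, expr) {
  .stageLog(stage, quiet)
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Generate a complete synthetic fixture bundle
#'
#' Writes a CLI-consumable fixture emulating the comparative study at desk
#' scale: a one-bead topology with a gate pair, reduced and PTMed replica
#' ensembles (Gaussian fluctuations with state-specific correlation
#' recipes, plus Markov gate dynamics embedded in the gate pair), and a
#' ground-truth JSON echoing the generative parameters.
#'
#' The default conditions mirror the study design: 3 replicas per state;
#' the PTM perturbation strengthens the coupling of a gate block and flips
#' one peripheral block, and the gate process shifts occupancy from a
#' closed-dominated to an open-dominated stationary law.
#'
#' @param spec optional list overriding elements of the default fixture
#'   spec (`n_res`, `n_frames`, `replicas`, `seed`, `sds`,
#'   `blocks_reduced`, `blocks_ptm`, `gate` with means/sds/transitions).
#' @param outDir output directory.
#' @return invisibly, the ground-truth list (also written as JSON).
#' @export
runSimulate <- function(spec = list(), outDir) {
  defaults <- list(
    n_res = 20L, n_frames = 400L, replicas = 3L, seed = 20260927L,
    sds = 0.08,
    blocks_reduced = list(list(members = c(3L, 4L), rho = 0.6),
                          list(members = c(11L, 12L), rho = 0.6)),
    blocks_ptm = list(list(members = c(3L, 4L), rho = 0.6),
                      list(members = c(11L, 12L), rho = -0.6),
                      list(members = c(7L, 8L), rho = 0.5)),
    gate = list(
      pair = c(5L, 15L),
      means = c(closed = 0.30, open = 0.55, wide_open = 0.80),
      sds = 0.03,
      transition_reduced = matrix(c(0.95, 0.04, 0.01,
                                    0.08, 0.90, 0.02,
                                    0.02, 0.03, 0.95),
                                  3, 3, byrow = TRUE),
      transition_ptm = matrix(c(0.85, 0.14, 0.01,
                                0.02, 0.96, 0.02,
                                0.02, 0.08, 0.90),
                              3, 3, byrow = TRUE)))
  spec <- .mergeConfig(defaults, spec)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  n <- spec$n_res
  corrR <- corrMatrixFromBlocks(n, spec$blocks_reduced)
  corrP <- corrMatrixFromBlocks(n, spec$blocks_ptm)
  fx <- makeStatePairFixture(list(corr = corrR, sds = spec$sds),
                             perturb = corrP, nFrames = spec$n_frames,
                             seed = spec$seed, replicas = spec$replicas)
  sys <- fx$pair@reduced[[1]]@system
  writeTopology(sys, file.path(outDir, "topology.tsv"),
                file.path(outDir, "selections.json"))

  gateTruth <- list()
  set.seed(spec$seed)
  gateSeeds <- sample.int(.Machine$integer.max - 1L, 2L * spec$replicas)
  writeState <- function(state, trajs, transition, seedOffset) {
    paths <- character(length(trajs))
    occ <- vector("list", length(trajs))
    for (r in seq_along(trajs)) {
      gs <- sampleGateSeries(spec$gate$means, spec$gate$sds, transition,
                             nFrames(trajs[[r]]),
                             seed = gateSeeds[seedOffset + r])
      tr <- embedGateInStructure(trajs[[r]], spec$gate$pair, gs$distance)
      paths[r] <- file.path(outDir, sprintf("%s_rep%d.pdb", state, r))
      writeTrajectoryPDB(tr, paths[r])
      occ[[r]] <- as.list(table(gs$state) / length(gs$state))
    }
    gateTruth[[state]] <<- list(
      stationary = as.list(stats::setNames(
        .stationaryDistribution(transition), names(spec$gate$means))),
      replica_state_fractions = occ)
    paths
  }
  redPaths <- writeState("reduced", fx$pair@reduced,
                         spec$gate$transition_reduced, 0L)
  ptmPaths <- writeState("ptm", fx$pair@ptm,
                         spec$gate$transition_ptm, spec$replicas)

  truth <- list(schema_version = REPORT_SCHEMA_VERSION,
                spec = spec,
                redistribution = fx$truth,
                gate = gateTruth,
                files = list(topology = "topology.tsv",
                             reduced = basename(redPaths),
                             ptm = basename(ptmPaths)))
  jsonlite::write_json(truth, file.path(outDir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(truth)
}

#' Run the full reduced-versus-PTMed comparison
#'
#' Executes the comparative pipeline on a configuration: per-residue RMSF
#' and radius of gyration per state, DCC matrices and strong-coupling
#' fractions, the redistribution score, combined-eigenspace PCA with mode
#' contributions and centroid shifts, gate series / classification / band
#' occupancy per subunit, hydrogen-bond occupancies, and (when regions are
#' configured) interaction-energy tables with flow graphs. Every stage's
#' output is written under `outDir` and collected into a versioned report
#' JSON together with the verbatim configuration echo. The run is
#' deterministic given the configuration.
#'
#' @param config list or path to a JSON configuration. Required fields:
#'   `topology`, `trajectories$reduced`, `trajectories$ptm` (file paths).
#'   Optional: `selections` (JSON path), `selection`, `gate` (+`chains`),
#'   `hbond_pairs` (list of residue-key pairs), `regions` (named list of
#'   chain-qualified OpcA residue keys), `gate_targets` (chain-qualified
#'   gate residue keys for the energy analysis), thresholds, `pca$n_modes`.
#' @param outDir output directory.
#' @param quiet suppress stage logging.
#' @return the report, invisibly (also written as `report.json`).
#' @export
runCompare <- function(config, outDir, quiet = FALSE) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = TRUE)
  cfg <- .mergeConfig(defaultAnalysisConfig(), config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(schema_version = REPORT_SCHEMA_VERSION, config = cfg)

  sys <- .runStage("load topology", quiet,
                   loadTopology(cfg$topology, cfg$selections))
  loadSet <- function(paths) lapply(paths, loadTrajectory, system = sys,
                                    format = cfg$trajectory_format)
  red <- .runStage("load reduced trajectories", quiet,
                   loadSet(cfg$trajectories$reduced))
  ptm <- .runStage("load ptm trajectories", quiet,
                   loadSet(cfg$trajectories$ptm))
  nf <- sum(vapply(red, nFrames, integer(1)))
  if (nf < 100L) warning("fewer than 100 pooled frames per state; ",
                         "statistics may be under-sampled")
  pair <- new("StatePair", reduced = red, ptm = ptm,
              selection = as.character(cfg$selection))
  sel <- cfg$selection

  # fluctuation statistics
  fl <- .runStage("rmsf/rg", quiet, {
    rr <- rmsf(red, sel); rp <- rmsf(ptm, sel)
    tab <- data.frame(rr[, c("chain", "resid", "label")],
                      rmsf_reduced = rr$rmsf, rmsf_ptm = rp$rmsf)
    utils::write.csv(tab, file.path(outDir, "rmsf.csv"), row.names = FALSE)
    rg <- data.frame(
      state = rep(c("reduced", "ptm"), c(length(red), length(ptm))),
      replica = c(seq_along(red), seq_along(ptm)),
      rg_mean = vapply(c(red, ptm), function(t)
        mean(radiusOfGyration(t, sel)), numeric(1)))
    utils::write.csv(rg, file.path(outDir, "rg.csv"), row.names = FALSE)
    list(rmsf = tab, rg = rg)
  })
  report$rg <- fl$rg

  # correlation block
  thr <- cfg$thresholds$correlation
  corr <- .runStage("dccm/redistribution", quiet, {
    dR <- dccMatrix(red, sel); dP <- dccMatrix(ptm, sel)
    writeDCCM(dR, file.path(outDir, "dccm_reduced.csv"),
              file.path(outDir, "dccm_reduced_long.tsv"))
    writeDCCM(dP, file.path(outDir, "dccm_ptm.csv"),
              file.path(outDir, "dccm_ptm_long.tsv"))
    sc <- redistributionScore(dR, dP, thr)
    utils::write.csv(sc, file.path(outDir, "redistribution_score.csv"),
                     row.names = FALSE)
    list(reduced = dR, ptm = dP, score = sc)
  })
  report$redistribution <- corr$score

  # combined PCA
  pca <- .runStage("combined PCA", quiet, {
    p <- combinedPCA(pair, nModes = cfg$pca$n_modes)
    utils::write.csv(
      data.frame(mode = seq_along(p@values), eigenvalue = p@values,
                 variance_fraction = p@varianceFractions),
      file.path(outDir, "pca_eigenvalues.csv"), row.names = FALSE)
    proj <- do.call(rbind, lapply(names(p@projections), function(s) {
      m <- p@projections[[s]]
      data.frame(source = s, frame = seq_len(nrow(m)),
                 stats::setNames(as.data.frame(m),
                                 paste0("PC", seq_len(ncol(m)))))
    }))
    utils::write.csv(proj, file.path(outDir, "pca_projections.csv"),
                     row.names = FALSE)
    k <- min(cfg$pca$n_modes, length(p@values))
    contrib <- lapply(seq_len(k), modeResidueContributions, result = p)
    ctab <- do.call(rbind, lapply(contrib, function(cc)
      cbind(mode = cc$mode, cc$contributions)))
    utils::write.csv(ctab, file.path(outDir, "pca_contributions.csv"),
                     row.names = FALSE)
    list(result = p, contrib = contrib,
         shift = centroidShift(p, nModes = k))
  })
  report$pca <- list(
    variance_fractions = pca$result@varianceFractions[seq_len(
      min(cfg$pca$n_modes, length(pca$result@values)))],
    top_sets = lapply(pca$contrib, `[[`, "topSet"),
    centroid_shift = as.data.frame(pca$shift))

  # gate analyses
  if (!is.null(cfg$gate$chains)) {
    gateRes <- .runStage("gate classification", quiet, {
      gd <- gateDefinition(cfg$gate$lower, cfg$gate$upper, cfg$gate$mode)
      bands <- cfg$thresholds$gate_bands
      out <- list(); seriesTab <- list()
      for (st in c("reduced", "ptm")) {
        trs <- if (st == "reduced") red else ptm
        for (chain in cfg$gate$chains) {
          series <- unlist(lapply(trs, gateDistanceSeries, gate = gd,
                                  chain = chain))
          cl <- classifyGate(series, bands)
          occ <- cl$occupancy
          out[[paste(st, chain, sep = "_")]] <- list(
            state = st, chain = chain, label = cl$label,
            occupancy = as.list(occ),
            open_or_wide = attr(occ, "open_or_wide"),
            distance_mode = gd$mode)
          seriesTab[[paste(st, chain, sep = "_")]] <-
            data.frame(state = st, chain = chain,
                       frame = seq_along(series), distance_nm = series)
        }
      }
      utils::write.csv(do.call(rbind, seriesTab),
                       file.path(outDir, "gate_series.csv"),
                       row.names = FALSE)
      jsonlite::write_json(out, file.path(outDir, "gate_classification.json"),
                           auto_unbox = TRUE, digits = NA)
      out
    })
    report$gate <- gateRes
  }

  # hydrogen bonds
  if (!is.null(cfg$hbond_pairs)) {
    hb <- .runStage("hbond occupancy", quiet, {
      crit <- hbondCriteria(cfg$thresholds$hbond$distance,
                            cfg$thresholds$hbond$angle)
      rows <- lapply(cfg$hbond_pairs, function(p) {
        data.frame(residue_i = p[1], residue_j = p[2],
                   occupancy_reduced = hbondOccupancy(p, red, crit),
                   occupancy_ptm = hbondOccupancy(p, ptm, crit),
                   stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      utils::write.csv(tab, file.path(outDir, "hbond_occupancy.csv"),
                       row.names = FALSE)
      tab
    })
    report$hbond <- hb
  }

  # interaction energies and flow graphs
  if (!is.null(cfg$regions) && !is.null(cfg$gate_targets)) {
    net <- .runStage("interaction network", quiet, {
      regionKeys <- unlist(cfg$regions, use.names = FALSE)
      regionOf <- stats::setNames(
        rep(names(cfg$regions), lengths(cfg$regions)), regionKeys)
      g6pdh <- setdiff(
        .residueLabel(sys@atoms$chain, sys@atoms$resid),
        c(regionKeys))
      g6pdh <- unique(g6pdh[!g6pdh %in% regionKeys])
      mkTable <- function(trs) {
        oe <- energyTable(sys, trs, regionKeys, unique(g6pdh))
        ge <- energyTable(sys, trs,
                          setdiff(unique(g6pdh), cfg$gate_targets),
                          cfg$gate_targets)
        list(opca = oe, gate = ge)
      }
      states <- list(reduced = red, ptm = ptm)
      out <- list()
      for (st in names(states)) {
        tabs <- mkTable(states[[st]])
        full <- rbind(tabs$opca, tabs$gate)
        utils::write.table(full,
                           file.path(outDir, paste0("energies_", st, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        thrE <- cfg$thresholds$energy
        gateStates <- if (!is.null(report$gate))
          stats::setNames(
            vapply(Filter(function(x) x$state == st, report$gate),
                   `[[`, "", "label"),
            vapply(Filter(function(x) x$state == st, report$gate),
                   `[[`, "", "chain"))
        else stats::setNames("open_closed", sys@atoms$chain[1])
        graphs <- buildFlowGraph(sys,
                                 strongInteractions(tabs$opca, thrE),
                                 strongInteractions(tabs$gate, thrE),
                                 gateStates, opcaRegion = regionOf)
        writeFlowGraphs(graphs, file.path(outDir, paste0("flow_", st)))
        out[[st]] <- list(
          n_pairs = nrow(full),
          n_strong = nrow(strongInteractions(full, thrE)),
          groups = names(graphs))
      }
      out
    })
    report$network <- net
  }

  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

#' Free-energy workflow: windows, chaining, RBFE
#'
#' Estimates every lambda window of the protein and water work tables with
#' [barEstimate()], chains them across the two-stage schedule, and reports
#' the relative binding free energy (protein minus water).
#'
#' @param proteinCsv,waterCsv work CSVs (see [readWorkCSV()]).
#' @param kT thermal energy unit for the outputs (default 1 = kT units).
#' @param site,ptmType annotations carried into the RBFE row.
#' @param outPath optional JSON report path.
#' @return list with `windows_protein`, `windows_water`, `total_protein`,
#'   `total_water`, `rbfe`.
#' @export
runFreeEnergy <- function(proteinCsv, waterCsv, kT = 1, site = NA,
                          ptmType = NA_character_, outPath = NULL) {
  wp <- estimateWindows(readWorkCSV(proteinCsv), kT)
  ww <- estimateWindows(readWorkCSV(waterCsv), kT)
  tp <- chainWindows(wp); tw <- chainWindows(ww)
  res <- rbfe(tp$dg, tw$dg, tp$stderr, tw$stderr, site, ptmType)
  out <- list(windows_protein = wp, windows_water = ww,
              total_protein = tp, total_water = tw, rbfe = res)
  if (!is.null(outPath))
    jsonlite::write_json(out, outPath, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  out
}
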
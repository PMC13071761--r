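test_that("topology loads with counts, and invariant violations are caught", {
  path <- writeToyTopology()
  sys <- loadTopology(path)
  expect_s4_class(sys, "MolecularSystem")
  expect_equal(nrow(systemAtoms(sys)), 4L)
  expect_equal(nrow(systemResidues(sys)), 2L)

  bad <- toyAtomTable(); bad$atom_id[2] <- 3L
  badPath <- tempfile(fileext = ".tsv")
  utils::write.table(bad, badPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(loadTopology(badPath), "duplicated atom_id")

  noCol <- toyAtomTable(); noCol$charge <- NULL
  ncPath <- tempfile(fileext = ".tsv")
  utils::write.table(noCol, ncPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(loadTopology(ncPath), "charge")
})

test_that("topology and selections round-trip through writer and reader", {
  sys <- newMolecularSystem(toyAtomTable(),
                            list(gate_lower = c("1"), both = c("1", "2")))
  tsv <- tempfile(fileext = ".tsv"); selJson <- tempfile(fileext = ".json")
  writeTopology(sys, tsv, selJson)
  back <- loadTopology(tsv, selJson)
  expect_identical(systemAtoms(back)$atom_id, systemAtoms(sys)$atom_id)
  expect_equal(systemAtoms(back), systemAtoms(sys))
  expect_equal(lapply(systemSelections(back), as.character),
               lapply(systemSelections(sys), as.character))
  expect_equal(nrow(systemResidues(back, "gate_lower")), 1L)
})

test_that("PDB loading converts Angstrom to nm and keeps frame order", {
  sys <- newMolecularSystem(toyAtomTable())
  co <- array(0, c(3, 4, 3))
  for (f in 1:3) co[f, , ] <- matrix(f + seq_len(12) / 10, 4, 3) / 10
  traj <- newTrajectory(sys, co)
  pdb <- tempfile(fileext = ".pdb")
  writeTrajectoryPDB(traj, pdb)
  back <- loadTrajectory(pdb, sys)
  expect_equal(nFrames(back), 3L)
  expect_equal(trajCoords(back), co, tolerance = 1e-6)

  one <- newTrajectory(sys, co[1, , , drop = FALSE])
  p1 <- tempfile(fileext = ".pdb")
  writeTrajectoryPDB(one, p1)
  b1 <- loadTrajectory(p1, sys)
  expect_equal(nFrames(b1), 1L)
  expect_equal(max(abs(trajCoords(b1) - co[1, , , drop = FALSE])), 0,
               tolerance = 1e-6)
})

test_that("XYZ and PDB encodings agree; count mismatches name the frame", {
  sys <- newMolecularSystem(toyAtomTable())
  set.seed(4)
  # coordinates on the 0.001-Angstrom grid both formats can represent
  co <- round(array(stats::rnorm(2 * 4 * 3, sd = 0.3), c(2, 4, 3)), 4)
  traj <- newTrajectory(sys, co)
  pdb <- tempfile(fileext = ".pdb"); xyz <- tempfile(fileext = ".xyz")
  writeTrajectoryPDB(traj, pdb); writeTrajectoryXYZ(traj, xyz)
  fromPdb <- loadTrajectory(pdb, sys)
  fromXyz <- loadTrajectory(xyz, sys)
  expect_lt(max(abs(trajCoords(fromPdb) - trajCoords(fromXyz))), 1e-6)

  small <- makeCASystem(3)$system
  expect_error(loadTrajectory(pdb, small), "frame 1")
  lines <- readLines(pdb)
  writeLines(lines[!grepl("ATOM  ", lines)], pdb)
  expect_error(loadTrajectory(pdb, sys), "zero frames")
})

test_that("PDB reader agrees with an independent PDB implementation", {
  sys <- newMolecularSystem(toyAtomTable())
  set.seed(5)
  co <- array(stats::rnorm(2 * 4 * 3, sd = 0.2) + 1, c(2, 4, 3))
  pdb <- tempfile(fileext = ".pdb")
  writeTrajectoryPDB(newTrajectory(sys, co), pdb)
  ours <- trajCoords(loadTrajectory(pdb, sys))
  ref <- suppressWarnings(bio3d::read.pdb(pdb, multi = TRUE,
                                          verbose = FALSE))$xyz
  for (f in 1:2)
    expect_equal(as.numeric(t(matrix(ours[f, , ] * 10, ncol = 3))),
                 as.numeric(ref[f, ]), tolerance = 1e-6)
})

test_that("PTM system plan reproduces the study arithmetic", {
  sys <- makeCASystem(30, resname = c(rep("ALA", 19), rep("CYS", 11)))$system
  expect_equal(nrow(enumeratePtmSystems(sys, replicas = 1)), 34L)
  expect_equal(nrow(enumeratePtmSystems(sys, replicas = 3)), 102L)
  noCys <- makeCASystem(5)$system
  expect_warning(plan <- enumeratePtmSystems(noCys, replicas = 1),
                 "baseline")
  expect_equal(nrow(plan), 1L)
  expect_equal(plan$ptm_type, "reduced")
})

test_that("plan count matches brute-force enumeration over a grid", {
  for (nCys in c(0L, 2L, 5L)) for (nTypes in 1:3) for (reps in c(1L, 2L, 4L)) {
    resnames <- c(rep("ALA", 6), rep("CYS", nCys))
    sys <- makeCASystem(length(resnames), resname = resnames)$system
    types <- c("sulfenylated", "nitrosylated",
               "glutathionylated")[seq_len(nTypes)]
    plan <- suppressWarnings(enumeratePtmSystems(sys, types, reps))
    # oracle: enumerate explicitly
    expected <- 0L
    for (s in seq_len(nCys)) for (tp in types) for (r in seq_len(reps))
      expected <- expected + 1L
    expected <- expected + reps  # reduced baseline per replica
    expect_equal(nrow(plan), expected)
    expect_equal(sum(plan$ptm_type == "reduced"), reps)
  }
})

test_that("TI window enumeration follows the two-stage schedule", {
  w <- enumerateTiWindows()
  expect_equal(nrow(w), 26L)
  expect_equal(unique(w$stage), c("electrostatics", "vdw_bonded"))
  expect_equal(w$stage[1], "electrostatics")
  expect_equal(nrow(enumerateTiWindows(c(0, 1), "vdw_bonded")), 2L)
  expect_error(enumerateTiWindows(c(0, 0.5, 0.5, 1)), "increasing")
  expect_error(enumerateTiWindows(c(0.1, 0.5, 1)), "increasing")
})

test_that("production plan totals the per-condition sampling", {
  plan <- productionPlan()
  perCondition <- tapply(plan$length_ns, plan$state, sum)
  expect_true(all(perCondition == 1500))
})
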
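test_that("Coulomb and LJ pair terms match closed forms", {
  cas <- makeCASystem(2)
  a <- systemAtoms(cas$system)
  a$charge <- c(1, -1); a$sigma_nm <- 0; a$epsilon_kcal <- 0
  sys <- newMolecularSystem(a)
  co <- array(0, c(1, 2, 3)); co[1, 2, 1] <- 1.0
  e <- pairNonbondedEnergy(sys, newTrajectory(sys, co), "A:1", "A:2")
  expect_equal(e$coulomb, -33.20636, tolerance = 1e-6)
  expect_equal(e$total, e$coulomb + e$lj, tolerance = 1e-12)

  a$charge <- c(0, 0)
  zero <- pairNonbondedEnergy(newMolecularSystem(a),
                              newTrajectory(newMolecularSystem(a), co),
                              "A:1", "A:2")
  expect_equal(zero$total, 0)

  # LJ at the minimum r = 2^(1/6) sigma gives exactly -epsilon
  a$sigma_nm <- 0.3; a$epsilon_kcal <- 0.2
  co2 <- array(0, c(1, 2, 3)); co2[1, 2, 1] <- 2^(1 / 6) * 0.3
  lj <- pairNonbondedEnergy(newMolecularSystem(a),
                            newTrajectory(newMolecularSystem(a), co2),
                            "A:1", "A:2")
  expect_equal(lj$lj, -0.2, tolerance = 1e-12)
})

test_that("multi-atom residue energies equal the brute-force double loop", {
  atoms <- data.frame(
    atom_id = 1:6,
    name = c("CA", "CB", "OD1", "CA", "CB", "NH1"),
    element = c("C", "C", "O", "C", "C", "N"),
    chain = "A", resid = c(1L, 1L, 1L, 2L, 2L, 2L),
    resname = c(rep("ASP", 3), rep("ARG", 3)),
    charge = c(0.2, -0.3, -0.6, 0.1, 0.25, 0.5),
    sigma_nm = c(0.34, 0.32, 0.30, 0.34, 0.32, 0.33),
    epsilon_kcal = c(0.1, 0.12, 0.2, 0.1, 0.12, 0.17),
    mass = 12, stringsAsFactors = FALSE)
  sys <- newMolecularSystem(atoms)
  set.seed(7)
  co <- array(stats::rnorm(3 * 6 * 3, sd = 0.5) + 1, c(3, 6, 3))
  tr <- newTrajectory(sys, co)
  got <- pairNonbondedEnergy(sys, tr, "A:1", "A:2")

  # oracle: explicit loops over frames and atom pairs
  ke <- 332.0636
  coul <- 0; lj <- 0
  for (f in 1:3) for (i in 1:3) for (j in 4:6) {
    r <- sqrt(sum((co[f, i, ] - co[f, j, ])^2))
    coul <- coul + ke * atoms$charge[i] * atoms$charge[j] / (10 * r)
    sij <- (atoms$sigma_nm[i] + atoms$sigma_nm[j]) / 2
    eij <- sqrt(atoms$epsilon_kcal[i] * atoms$epsilon_kcal[j])
    lj <- lj + 4 * eij * ((sij / r)^12 - (sij / r)^6)
  }
  expect_equal(got$coulomb, coul / 3, tolerance = 1e-9)
  expect_equal(got$lj, lj / 3, tolerance = 1e-9)

  # symmetry
  rev <- pairNonbondedEnergy(sys, tr, "A:2", "A:1")
  expect_identical(got$total, rev$total)

  # doubling all charges quadruples the Coulomb term
  doubled <- atoms; doubled$charge <- 2 * doubled$charge
  sys2 <- newMolecularSystem(doubled)
  got2 <- pairNonbondedEnergy(sys2, newTrajectory(sys2, co), "A:1", "A:2")
  expect_equal(got2$coulomb, 4 * got$coulomb, tolerance = 1e-9)
  expect_equal(got2$lj, got$lj, tolerance = 1e-12)

  expect_error(pairNonbondedEnergy(sys, tr, "A:1", "A:1"), "distinct")
})

test_that("strong-interaction selection is strict at the +/-10 kcal/mol threshold", {
  tab <- data.frame(residue_i = "x", residue_j = letters[1:4],
                    total = c(-12, -5, 11, 9.9))
  kept <- strongInteractions(tab)
  expect_equal(kept$total, c(-12, 11))

  boundary <- data.frame(residue_i = "x", residue_j = "y", total = 10.0)
  expect_equal(nrow(strongInteractions(boundary)), 0L)
  expect_equal(nrow(strongInteractions(tab[0, ])), 0L)
  expect_error(strongInteractions(tab, threshold = -1), "positive")
})

test_that("edge categories follow the charge classification", {
  expect_equal(classifyEdge("ASP", "ARG"), "oppositely_charged")
  expect_equal(classifyEdge("LYS", "ARG"), "like_charged")
  expect_equal(classifyEdge("ASP", "GLU"), "like_charged")
  expect_equal(classifyEdge("ASN", "GLU"), "polar_charged")
  expect_equal(classifyEdge("ALA", "SER"), "other")
  expect_equal(classifyEdge("HIS", "ASP"), "polar_charged")
  expect_equal(classifyEdge("HIS", "ASP", hisPositive = TRUE),
               "oppositely_charged")
})

test_that("flow graphs assemble layered paths from strong edges only", {
  sys <- networkSystem()
  opca <- data.frame(residue_i = "O:400", residue_j = "A:38", total = -15,
                     stringsAsFactors = FALSE)
  gate <- data.frame(residue_i = "A:38", residue_j = "A:33", total = -12,
                     stringsAsFactors = FALSE)
  graphs <- buildFlowGraph(sys, opca, gate,
                           gateStates = c(A = "open_closed"),
                           opcaRegion = c("O:400" = "region1"))
  expect_equal(names(graphs), "open_closed")
  g <- graphs$open_closed
  expect_equal(igraph::ecount(g), 2L)
  path <- igraph::shortest_paths(g, "O:400", "A:33")$vpath[[1]]
  expect_equal(length(path), 3L)
  layers <- igraph::V(g)$layer[match(c("O:400", "A:38", "A:33"),
                                     igraph::V(g)$name)]
  expect_equal(layers, c("opca_region", "g6pdh_intermediate", "gate"))
  ed <- igraph::as_data_frame(g)
  expect_true(all(ed$category %in% c("oppositely_charged", "like_charged",
                                     "polar_charged")))

  # below-threshold tables give no graph at all
  weak <- buildFlowGraph(sys, opca[0, ], gate[0, ],
                         gateStates = c(A = "closed"))
  expect_equal(length(weak), 0L)

  # an intermediate touching two gate residues has out-degree 2, and every
  # graph edge is a member of the strong set
  gate2 <- rbind(gate,
                 data.frame(residue_i = "A:38", residue_j = "A:241",
                            total = -11))
  g2 <- buildFlowGraph(sys, opca, gate2,
                       gateStates = c(A = "open"))$open_or_wide
  expect_equal(unname(igraph::degree(g2, "A:38", mode = "out")), 2)
  ed2 <- igraph::as_data_frame(g2)
  strong <- rbind(opca, gate2)
  for (r in seq_len(nrow(ed2)))
    expect_true(any(strong$residue_i == ed2$from[r] &
                      strong$residue_j == ed2$to[r]))

  # intermediates without a regulator edge still appear (limited
  # regulator involvement)
  lone <- buildFlowGraph(sys, opca[0, ],
                         data.frame(residue_i = "A:87", residue_j = "A:33",
                                    total = 12),
                         gateStates = c(A = "closed"))$closed
  expect_true("A:87" %in% igraph::V(lone)$name)
  expect_equal(igraph::ecount(lone), 1L)
})

test_that("flow graphs serialize to GraphML and layered JSON", {
  sys <- networkSystem()
  graphs <- buildFlowGraph(
    sys,
    data.frame(residue_i = "O:400", residue_j = "A:38", total = -15),
    data.frame(residue_i = "A:38", residue_j = "A:33", total = -12),
    gateStates = c(A = "open_closed"))
  dir <- tempfile()
  paths <- writeFlowGraphs(graphs, dir)
  expect_true(file.exists(file.path(dir, "flow_open_closed.graphml")))
  doc <- jsonlite::fromJSON(file.path(dir, "flow_graphs.json"),
                            simplifyVector = FALSE)
  expect_equal(doc[[1]]$group, "open_closed")
  expect_equal(length(doc[[1]]$edges), 2L)
})
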
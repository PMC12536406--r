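test_that("topology of the worked-case stack: 316 beads, 308 bonds", {
  sys <- build_cg_topology(hetero4())
  expect_equal(sys$n, 4 * 42 + 4 * 37)
  expect_equal(nrow(sys$bonds), 4 * 41 + 4 * 36)
  expect_true(all(sys$bond_r0 == 3.8))
  expect_true(all(sys$mass > 0))
})

test_that("harmonic energies match closed forms", {
  # two beads, one restraint r0 = 3, k = 1, separation 5 -> E = 0.5*1*2^2 = 2
  atoms <- data.frame(resid = 1L, resname = "ALA", elety = "CA",
                      x = 0, y = 0, z = 0)
  atoms2 <- atoms; atoms2$x <- 5
  m <- new_fibril_model(list(new_chain("A", atoms, molecule = "OTHER"),
                             new_chain("B", atoms2, molecule = "OTHER")))
  sys <- build_cg_topology(m)
  rs <- data.frame(category = "beta", chain_i = "A", resid_i = 1L,
                   atom_i = "CA", chain_j = "B", resid_j = 1L, atom_j = "CA",
                   r0 = 3, k = 1, stringsAsFactors = FALSE)
  e <- potential_energy(sys, sys$coords, rs)
  expect_equal(e$components[["beta"]], 2.0, tolerance = 1e-12)
  expect_equal(e$total, sum(e$components), tolerance = 1e-12)
  # sterics: two nonbonded beads at distance 3 < 4 -> k_rep*(4-3)^2 = 10
  expect_equal(potential_energy(sys, matrix(c(0, 0, 0, 3, 0, 0), 2,
                                            byrow = TRUE))$components[["sterics"]],
               10, tolerance = 1e-12)
})

test_that("minimizer recovers the analytic two-bead minimum to 1e-3 A", {
  atoms <- data.frame(resid = 1L, resname = "ALA", elety = "CA",
                      x = 0, y = 0, z = 0)
  atoms2 <- atoms; atoms2$x <- 9
  m <- new_fibril_model(list(new_chain("A", atoms, molecule = "OTHER"),
                             new_chain("B", atoms2, molecule = "OTHER")))
  sys <- build_cg_topology(m)
  rs <- data.frame(category = "beta", chain_i = "A", resid_i = 1L,
                   atom_i = "CA", chain_j = "B", resid_j = 1L, atom_j = "CA",
                   r0 = 4.8, k = 5, stringsAsFactors = FALSE)
  mn <- minimize(sys, sys$coords, rs, f_tol = 1e-5)
  expect_true(mn$converged)
  d <- sqrt(sum((mn$coords[1, ] - mn$coords[2, ])^2))
  expect_equal(d, 4.8, tolerance = 1e-3)
  # energy trace is non-increasing
  expect_true(all(diff(mn$trace) <= 1e-12))
})

test_that("the ideal stack is a fixed point of minimization", {
  stk <- hetero4()
  sys <- build_cg_topology(stk)
  al <- junction_alignment()
  sch <- shape_schedule(1, stk)
  rset <- restraint_set(beta_sheet_restraints(stk, al),
                        shape_restraints(stk, sch, stk), sch)
  e0 <- potential_energy(sys, sys$coords, rset)
  expect_lt(e0$components[["sterics"]], 1e-9)
  expect_lt(e0$components[["beta"]], 1e-9)
  expect_lt(e0$components[["shape"]], 1e-9)
  mn <- minimize(sys, sys$coords, rset, max_steps = 300)
  expect_lt(max(sqrt(rowSums((mn$coords - sys$coords)^2))), 0.05)
})

test_that("junction register reforms after a 6 A axial displacement", {
  stk <- hetero4()
  sys <- build_cg_topology(stk)
  al <- junction_alignment()
  sch <- shape_schedule(2, stk)
  rset <- restraint_set(beta_sheet_restraints(stk, al),
                        shape_restraints(stk, sch, stk), sch)
  x <- sys$coords
  x[sys$chain %in% c("E", "F", "G", "H"), 3] <-
    x[sys$chain %in% c("E", "F", "G", "H"), 3] + 6
  mn <- minimize(sys, x, rset, max_steps = 2000, f_tol = 1e-4)
  jr <- rset$beta[rset$beta$category == "junction", ]
  bead <- function(ch, res) which(sys$chain == ch & sys$resid == res)
  d <- mapply(function(ri, rj)
    sqrt(sum((mn$coords[bead("D", ri), ] - mn$coords[bead("E", rj), ])^2)),
    jr$resid_i, jr$resid_j)
  expect_true(all(abs(d - 4.8) <= 0.2))
})

test_that("Langevin runs are bitwise reproducible for a fixed seed", {
  sys <- build_cg_topology(small_fibril())
  rs <- beta_sheet_restraints(small_fibril())
  t1 <- langevin_run(sys, sys$coords, rs, n_steps = 50, seed = 123, stride = 10)
  t2 <- langevin_run(sys, sys$coords, rs, n_steps = 50, seed = 123, stride = 10)
  expect_identical(t1$coords, t2$coords)
  t3 <- langevin_run(sys, sys$coords, rs, n_steps = 50, seed = 124, stride = 10)
  expect_false(identical(t3$coords[[2]], t1$coords[[2]]))
  expect_equal(t1$metadata$seed, 123)
})

test_that("langevin_run does not disturb the caller's RNG state", {
  set.seed(99)
  before <- .Random.seed
  sys <- build_cg_topology(small_fibril())
  invisible(langevin_run(sys, sys$coords, NULL, n_steps = 10, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("equipartition: kinetic temperature within 3 SE of the target", {
  stk <- hetero4()
  sys <- build_cg_topology(stk)
  al <- junction_alignment()
  sch <- shape_schedule(1, stk)
  rset <- restraint_set(beta_sheet_restraints(stk, al),
                        shape_restraints(stk, sch, stk), sch)
  target <- 300
  tr <- langevin_run(sys, sys$coords, rset, n_steps = 600,
                     temperature = target, seed = 2024, stride = 20)
  temps <- tr$metadata$kinetic_temperature
  # discard the first half as equilibration from the zero-velocity-free start
  temps <- temps[-seq_len(length(temps) %/% 2)]
  se <- stats::sd(temps) / sqrt(length(temps))
  expect_lt(abs(mean(temps) - target), 3 * se + 0.05 * target)
})

test_that("zero-temperature dynamics relaxes toward the minimum", {
  atoms <- data.frame(resid = 1L, resname = "ALA", elety = "CA",
                      x = 0, y = 0, z = 0)
  atoms2 <- atoms; atoms2$x <- 7
  m <- new_fibril_model(list(new_chain("A", atoms, molecule = "OTHER"),
                             new_chain("B", atoms2, molecule = "OTHER")))
  sys <- build_cg_topology(m)
  rs <- data.frame(category = "beta", chain_i = "A", resid_i = 1L,
                   atom_i = "CA", chain_j = "B", resid_j = 1L, atom_j = "CA",
                   r0 = 4.8, k = 5, stringsAsFactors = FALSE)
  tr <- langevin_run(sys, sys$coords, rs, n_steps = 3000, temperature = 0,
                     friction = 5, stride = 3000)
  xf <- tr$coords[[n_frames(tr)]]
  expect_equal(sqrt(sum((xf[1, ] - xf[2, ])^2)), 4.8, tolerance = 1e-2)
})

test_that("zero-temperature dynamics conserves the center of mass", {
  sys <- build_cg_topology(small_fibril())
  rs <- beta_sheet_restraints(small_fibril())
  tr <- langevin_run(sys, sys$coords, rs, n_steps = 200, temperature = 0,
                     stride = 50)
  com0 <- colSums(sys$coords * sys$mass) / sum(sys$mass)
  comf <- colSums(tr$coords[[n_frames(tr)]] * sys$mass) / sum(sys$mass)
  expect_lt(max(abs(comf - com0)), 1e-6)
})

test_that("backmapping translates whole residues with their CA", {
  m <- small_fibril(n_chains = 2, n_residues = 5)
  sys <- build_cg_topology(m)
  x1 <- sys$coords + rep(c(1, 2, 3), each = sys$n)  # rigid translation
  tr <- structure(list(
    atom_table = data.frame(chain = sys$chain, resid = sys$resid,
                            elety = "CA", stringsAsFactors = FALSE),
    coords = list(sys$coords, x1), times = c(0, 1), metadata = list()),
    class = "Trajectory")
  full <- backmap_trajectory(tr, m)
  tab <- model_atom_table(m)
  expect_equal(full$coords[[2]],
               as.matrix(tab[, c("x", "y", "z")]) + rep(c(1, 2, 3), each = nrow(tab)),
               ignore_attr = TRUE)
})

test_that("instability raises a numerical error", {
  sys <- build_cg_topology(small_fibril())
  expect_error(
    langevin_run(sys, sys$coords, NULL, n_steps = 200, dt = 50,
                 temperature = 300),
    "instability|finite")
})
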
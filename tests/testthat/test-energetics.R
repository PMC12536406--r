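test_that("the shipped parameter table is well-formed and neutral per residue", {
  par <- energy_params()
  expect_true(all(c("resname", "variant", "elety", "charge",
                    "epsilon", "sigma", "rborn") %in% names(par)))
  expect_true(all(par$epsilon >= 0))
  expect_true(all(par$sigma > 0))
  expect_true(all(par$rborn > 0))
  # a standard backbone+CB residue is net neutral
  std <- par[par$resname == "*" & par$variant == "std", ]
  net <- sum(std$charge[std$elety %in% c("N", "H", "CA", "HA", "C", "O", "CB")])
  expect_equal(net, 0, tolerance = 1e-12)
  # GLY with its own CA/HA1/HA2 rows is also neutral
  g <- par[par$resname == "GLY", ]
  gly <- sum(g$charge) +
    sum(std$charge[std$elety %in% c("N", "H", "C", "O")])
  expect_equal(gly, 0, tolerance = 1e-12)
})

test_that("parameter assignment dispatches variants and flags unknowns", {
  stk <- make_abeta_iapp_stack(n_chains = 1)
  pt <- assign_parameters(stk, energy_params())
  expect_equal(nrow(pt), nrow(model_atom_table(stk)))
  # IAPP disulfide cysteines get the disulfide CB charge
  cys <- pt[pt$chain == "B" & pt$resid %in% c(2, 7) & pt$elety == "CB", ]
  expect_equal(unique(cys$charge), 0.08)
  # amide cap atoms resolved through the amide variant
  nt <- pt[pt$chain == "B" & pt$elety == "NT", ]
  expect_equal(nrow(nt), 1)
  expect_equal(nt$charge, -0.62)

  bad <- stk
  bad$chains[[1]]$atoms$elety[3] <- "QQ"
  expect_error(assign_parameters(bad, energy_params()), "parameter error")
})

test_that("Coulomb closed form: unit charges at 3.320636 A give 100 kcal/mol", {
  atoms <- data.frame(resid = 1L, resname = "ALA", elety = "CA",
                      x = 0, y = 0, z = 0)
  atoms2 <- atoms; atoms2$x <- 3.320636
  m <- new_fibril_model(list(new_chain("A", atoms, molecule = "OTHER"),
                             new_chain("B", atoms2, molecule = "OTHER")))
  par <- data.frame(resname = "*", variant = "std", elety = "CA",
                    charge = 1, epsilon = 0, sigma = 1, rborn = 1,
                    stringsAsFactors = FALSE)
  pt <- assign_parameters(m, par)
  xyz <- as.matrix(pt[, c("x", "y", "z")])
  # eps_w = eps_p removes all GB screening -> bare Coulomb
  e <- pair_interaction(pt, list(chain = "A", resid = 1),
                        list(chain = "B", resid = 1), xyz,
                        born = c(1, 1), eps_p = 1, eps_w = 1, gamma = 0)
  expect_equal(unname(e["polar"]), 100, tolerance = 1e-9)
  expect_equal(unname(e["nonpolar"]), 0, tolerance = 1e-12)
})

test_that("LJ closed form: minimum of -epsilon at r = 2^(1/6) sigma", {
  sig <- 3.5; eps <- 0.2
  atoms <- data.frame(resid = 1L, resname = "ALA", elety = "CA",
                      x = 0, y = 0, z = 0)
  atoms2 <- atoms; atoms2$x <- 2^(1 / 6) * sig
  m <- new_fibril_model(list(new_chain("A", atoms, molecule = "OTHER"),
                             new_chain("B", atoms2, molecule = "OTHER")))
  par <- data.frame(resname = "*", variant = "std", elety = "CA",
                    charge = 0, epsilon = eps, sigma = sig, rborn = 1,
                    stringsAsFactors = FALSE)
  pt <- assign_parameters(m, par)
  xyz <- as.matrix(pt[, c("x", "y", "z")])
  e <- pair_interaction(pt, list(chain = "A", resid = 1),
                        list(chain = "B", resid = 1), xyz,
                        born = c(1, 1), gamma = 0)
  expect_equal(unname(e["nonpolar"]), -eps, tolerance = 1e-9)
})

test_that("GB cross term limits", {
  # eps_w -> eps_p: screening vanishes
  expect_equal(gb_cross_term(1, 1, 3, 2, 2, eps_p = 1, eps_w = 1), 0)
  # small Born radii: f_GB -> r, recovering the plain screening limit
  want <- -0.5 * (1 - 1 / 80) * 332.0636 * (1 * -1) / 3
  expect_equal(gb_cross_term(1, -1, 3, 1e-6, 1e-6), want, tolerance = 1e-6)
  # r -> 0 with equal radii: f_GB -> R (Born self-term scale), finite
  expect_true(is.finite(gb_cross_term(1, 1, 0, 2, 2)))
})

test_that("Born radii are positive, finite, and bounded below by ~r_vdw", {
  stk <- make_abeta_iapp_stack(n_chains = 1)
  pt <- assign_parameters(stk, energy_params())
  xyz <- as.matrix(pt[, c("x", "y", "z")])
  born <- born_radii(pt, xyz)
  expect_true(all(is.finite(born) & born > 0))
  # descreening can only increase the effective radius
  expect_true(all(born >= pt$rborn - 0.09 - 1e-9))
})

test_that("decomposition closure: residue-pair sums equal the atomwise total", {
  stk <- make_abeta_iapp_stack(n_chains = 1)
  pt <- assign_parameters(stk, energy_params())
  xyz <- as.matrix(pt[, c("x", "y", "z")])
  born <- born_radii(pt, xyz)
  traj <- static_trajectory(stk, n = 1)
  maps <- interaction_map(traj, stk, c("A", "B"))
  mapped <- sum(unclass(maps$polar)) + sum(unclass(maps$nonpolar))

  # naive atomwise oracle over all A x B atom pairs
  ai <- which(pt$chain == "A"); aj <- which(pt$chain == "B")
  tot <- 0
  for (i in ai) for (j in aj) {
    r <- max(sqrt(sum((xyz[i, ] - xyz[j, ])^2)), 0.1)
    qq <- pt$charge[i] * pt$charge[j]
    pol <- 332.0636 * qq / r + gb_cross_term(pt$charge[i], pt$charge[j], r,
                                             born[i], born[j])
    sig <- (pt$sigma[i] + pt$sigma[j]) / 2
    eps <- sqrt(pt$epsilon[i] * pt$epsilon[j])
    lj <- min(4 * eps * ((sig / r)^12 - (sig / r)^6), 100)
    # buried-lens SASA term
    R1 <- pt$rborn[i] + 1.4; R2 <- pt$rborn[j] + 1.4
    bur <- 0
    if (r < R1 + R2) {
      if (r <= abs(R1 - R2)) {
        bur <- 4 * pi * min(R1, R2)^2
      } else {
        h1 <- (R2^2 - (r - R1)^2) / (2 * r)
        h2 <- (R1^2 - (r - R2)^2) / (2 * r)
        bur <- 2 * pi * (R1 * h1 + R2 * h2)
      }
    }
    tot <- tot + pol + lj - 0.0072 * bur
  }
  expect_equal(mapped, tot, tolerance = 1e-6)
})

test_that("energetics maps are invariant under rigid motion", {
  stk <- small_fibril(n_chains = 2, n_residues = 5,
                      sequence = "AKDLG", molecule = "OTHER")
  traj <- static_trajectory(stk)
  traj2 <- rigid_transform_traj(traj, random_rotation(4), c(-2, 6, 1))
  m1 <- interaction_map(traj, stk, c("A", "B"))
  m2 <- interaction_map(traj2, stk, c("A", "B"))
  expect_equal(unclass(m1$polar), unclass(m2$polar),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(unclass(m1$nonpolar), unclass(m2$nonpolar),
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("pair_interaction rejects same-chain residue pairs", {
  stk <- small_fibril(n_chains = 2, n_residues = 4)
  pt <- assign_parameters(stk, energy_params())
  expect_error(pair_interaction(pt, list(chain = "A", resid = 1),
                                list(chain = "A", resid = 3)),
               "different chains")
})

test_that("chain energy summary normalizes by residue count", {
  stk <- make_abeta_iapp_stack(n_chains = 2)  # chains A B C D
  traj <- static_trajectory(stk)
  par <- energy_params()
  maps <- list(
    "A:B" = interaction_map(traj, stk, c("A", "B"), params = par),
    "B:C" = interaction_map(traj, stk, c("B", "C"), params = par),
    "C:D" = interaction_map(traj, stk, c("C", "D"), params = par))
  summ <- chain_energy_summary(maps, stk, exclude_edges = TRUE)
  expect_equal(summ$chain, c("B", "C"))
  expect_equal(summ$total, summ$polar + summ$nonpolar)
  eb <- residue_normalized_energy(maps, stk, "B")
  expect_equal(summ$polar[1], unname(eb["polar"]))
  # oracle: the sums divided by residue counts
  want <- (sum(unclass(maps[["A:B"]]$polar)) +
             sum(unclass(maps[["B:C"]]$polar))) / 42
  expect_equal(unname(eb["polar"]), want, tolerance = 1e-9)
  expect_error(residue_normalized_energy(maps["A:B"], stk, "B"), "coverage")
})
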
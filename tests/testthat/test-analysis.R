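test_that("ideal stack has 100% H-bond occupancy for all aligned pairs", {
  stk <- hetero4()
  traj <- static_trajectory(stk, n = 3)
  occ <- hbond_occupancy(traj, stk, c("D", "E"))
  expect_s3_class(occ, "PairMatrix")
  expect_true(all(occ >= 0 & occ <= 100))
  al <- gapless_align(c(12L, 42L), c(7L, 37L))
  vals <- mapply(function(a, b) occ[as.character(a), as.character(b)],
                 al$residA, al$residB)
  expect_true(all(vals == 100))
})

test_that("occupancy counts frames: bond in half the frames -> 50%", {
  stk <- small_fibril(n_chains = 2, n_residues = 6)
  traj <- static_trajectory(stk, n = 4)
  # destroy chain separation in frames 3 and 4
  for (f in 3:4) {
    x <- traj$coords[[f]]
    rows <- traj$atom_table$chain == "B"
    x[rows, 3] <- x[rows, 3] + 50
    traj$coords[[f]] <- x
  }
  occ <- hbond_occupancy(traj, stk, c("A", "B"))
  expect_true(all(occ %in% c(0, 50)))
  expect_true(any(occ == 50))
  # with burn-in discarding the first half, occupancy falls to 0
  occ2 <- hbond_occupancy(traj, stk, c("A", "B"), burn_in = 0.5)
  expect_true(all(occ2 == 0))
})

test_that("occupancy errors on an absent chain pair", {
  stk <- small_fibril(n_chains = 2)
  traj <- static_trajectory(stk)
  expect_error(hbond_occupancy(traj, stk, c("X", "Y")), "empty-selection")
})

test_that("contact probability matches a brute-force oracle", {
  stk <- small_fibril(n_chains = 2, n_residues = 5)
  traj <- static_trajectory(stk, n = 2)
  traj$coords[[2]] <- traj$coords[[2]] +
    matrix(stats::rnorm(length(traj$coords[[2]]), sd = 0.3),
           ncol = 3)
  d_cut <- 4.5
  got <- contact_probability(traj, stk, c("A", "B"), d_cut = d_cut)
  tab <- traj$atom_table
  heavy <- !grepl("^H", tab$elety)
  r1 <- sort(unique(tab$resid[tab$chain == "A"]))
  r2 <- sort(unique(tab$resid[tab$chain == "B"]))
  oracle <- matrix(0, length(r1), length(r2))
  for (f in 1:2) {
    xyz <- traj$coords[[f]]
    for (i in seq_along(r1)) for (j in seq_along(r2)) {
      ai <- which(tab$chain == "A" & tab$resid == r1[i] & heavy)
      aj <- which(tab$chain == "B" & tab$resid == r2[j] & heavy)
      dm <- sqrt(outer(rowSums(xyz[ai, , drop = FALSE]^2), rep(1, length(aj))) +
                   outer(rep(1, length(ai)), rowSums(xyz[aj, , drop = FALSE]^2)) -
                   2 * xyz[ai, , drop = FALSE] %*% t(xyz[aj, , drop = FALSE]))
      if (any(dm <= d_cut)) oracle[i, j] <- oracle[i, j] + 1
    }
  }
  oracle <- oracle / 2 * 100
  expect_equal(unclass(got), oracle, ignore_attr = TRUE)
})

test_that("contact probability is monotone in the cutoff", {
  stk <- small_fibril(n_chains = 2, n_residues = 6)
  traj <- static_trajectory(stk)
  a <- contact_probability(traj, stk, c("A", "B"), d_cut = 3.5)
  b <- contact_probability(traj, stk, c("A", "B"), d_cut = 5.5)
  expect_true(all(unclass(b) >= unclass(a)))
})

test_that("H-bonds imply contacts at a comparable cutoff", {
  stk <- hetero4()
  traj <- static_trajectory(stk)
  occ <- hbond_occupancy(traj, stk, c("D", "E"))
  con <- contact_probability(traj, stk, c("D", "E"), d_cut = 4.5)
  expect_true(all(unclass(con)[unclass(occ) > 0] > 0))
})

test_that("beta content is 1 on the ideal parallel-beta fixture", {
  stk <- hetero4()
  traj <- static_trajectory(stk)
  bc <- beta_content(traj, stk, c("D", "E"))
  expect_equal(bc$interface, 1.0, tolerance = 1e-12)
  expect_true(all(stats::na.omit(bc$per_residue$beta_fraction) == 1))
})

test_that("beta content is 0 on a helical fixture", {
  hel <- make_ideal_fibril(fibril_recipe(n_chains = 2, n_residues = 12,
                                         phi = -57, psi = -47))
  traj <- static_trajectory(hel)
  bc <- beta_content(traj, hel, c("A", "B"))
  expect_equal(bc$interface, 0.0)
})

test_that("beta content needs the H-bond ladder, not dihedrals alone", {
  stk <- small_fibril(n_chains = 2, n_residues = 8)
  traj <- static_trajectory(stk)
  # separate the chains: dihedrals stay ideal, ladder breaks
  rows <- traj$atom_table$chain == "B"
  for (f in seq_along(traj$coords)) traj$coords[[f]][rows, 3] <-
      traj$coords[[f]][rows, 3] + 30
  bc <- beta_content(traj, stk, c("A", "B"))
  expect_equal(bc$interface, 0.0)
})

test_that("QT clustering handles the trivial cases", {
  stk <- small_fibril(n_chains = 3, n_residues = 6)
  traj <- static_trajectory(stk, n = 4)
  cl <- qt_cluster(traj, cutoff = 3.5)
  expect_equal(length(cl$populations), 1)
  expect_equal(unname(cl$populations), 1)
  expect_equal(sum(cl$populations), 1)

  # four frames, two far-apart conformations -> two equal clusters
  for (f in 3:4) traj$coords[[f]] <- traj$coords[[f]] +
      matrix(stats::rnorm(length(traj$coords[[f]]), sd = 6), ncol = 3)
  cl2 <- qt_cluster(traj, cutoff = 1.0)
  expect_gte(length(cl2$populations), 2)
  expect_equal(sum(cl2$populations), 1)
})

test_that("QT clustering matches an exhaustive greedy oracle", {
  stk <- small_fibril(n_chains = 3, n_residues = 4)
  set.seed(17)
  nf <- 12
  tab <- model_atom_table(stk)
  base <- as.matrix(tab[, c("x", "y", "z")])
  frames <- lapply(seq_len(nf), function(f)
    base + matrix(stats::rnorm(length(base), sd = stats::runif(1, 0, 2)),
                  ncol = 3))
  traj <- new_trajectory(tab, frames, times = seq_len(nf) - 1)
  sel <- atom_selection(tab, elety = c("N", "CA", "C"))
  cutoff <- 1.5
  got <- qt_cluster(traj, selection = sel, cutoff = cutoff)

  # oracle: full pairwise superposed-RMSD matrix, then greedy extraction
  M <- matrix(0, nf, nf)
  for (i in 1:(nf - 1)) for (j in (i + 1):nf) {
    M[i, j] <- M[j, i] <- superpose(frames[[i]][sel, ], frames[[j]][sel, ])$rmsd
  }
  labels <- rep(NA_integer_, nf); cl <- 0L
  centers <- integer()
  while (anyNA(labels)) {
    un <- which(is.na(labels))
    counts <- vapply(un, function(i) sum(M[i, un] <= cutoff), integer(1))
    pick <- un[which.max(counts)]
    cl <- cl + 1L
    labels[un[M[pick, un] <= cutoff]] <- cl
    centers[cl] <- pick
  }
  expect_equal(got$labels, labels)
  expect_equal(unname(got$centers), centers)
  # invariants: exhaustive, disjoint, members within cutoff of center
  expect_false(anyNA(got$labels))
  for (k in seq_along(got$centers)) {
    mem <- which(got$labels == k)
    expect_true(all(M[got$centers[[k]], mem] <= cutoff))
  }
})

test_that("rmsd_series is zero for a static trajectory and matches oracle", {
  stk <- small_fibril()
  traj <- static_trajectory(stk, n = 3)
  rs <- rmsd_series(traj)
  expect_equal(rs$rmsd, rep(0, 3), tolerance = 1e-9)

  traj$coords[[3]] <- traj$coords[[3]] +
    matrix(stats::rnorm(length(traj$coords[[3]]), sd = 0.5), ncol = 3)
  rs2 <- rmsd_series(traj)
  sel <- atom_selection(traj$atom_table, elety = c("N", "CA", "C"))
  oracle <- superpose(traj$coords[[1]][sel, ], traj$coords[[3]][sel, ])$rmsd
  expect_equal(rs2$rmsd[3], oracle, tolerance = 1e-9)
})

test_that("analysis maps are invariant under rigid motion of every frame", {
  stk <- small_fibril(n_chains = 2, n_residues = 6)
  traj <- static_trajectory(stk, n = 2)
  R <- random_rotation(8); t <- c(3, -7, 11)
  traj2 <- rigid_transform_traj(traj, R, t)
  expect_equal(unclass(hbond_occupancy(traj2, stk, c("A", "B"))),
               unclass(hbond_occupancy(traj, stk, c("A", "B"))),
               ignore_attr = TRUE)
  expect_equal(unclass(contact_probability(traj2, stk, c("A", "B"))),
               unclass(contact_probability(traj, stk, c("A", "B"))),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(beta_content(traj2, stk, c("A", "B"))$interface,
               beta_content(traj, stk, c("A", "B"))$interface)
  expect_equal(rmsd_series(traj2)$rmsd, rmsd_series(traj)$rmsd,
               tolerance = 1e-9)
})

test_that("polymorph comparison is 0 for identical models, positive otherwise", {
  stk <- small_fibril(n_chains = 4, n_residues = 10)
  expect_lt(compare_polymorphs(stk, c(2L, 9L), stk, c(2L, 9L), n_chains = 2),
            1e-9)
  other <- perturb(stk, 0.7, seed = 9)
  v <- compare_polymorphs(stk, c(2L, 9L), other, c(2L, 9L), n_chains = 2)
  expect_gt(v, 0)
  # minimum over windows: never larger than the first-window RMSD
  first <- superpose(
    do.call(rbind, lapply(stk$chains[1:2], chain_coords, resids = 2:9)),
    do.call(rbind, lapply(other$chains[1:2], chain_coords, resids = 2:9)))$rmsd
  expect_lte(v, first + 1e-9)
})

test_that("pair matrices write valid TSV", {
  stk <- small_fibril(n_chains = 2, n_residues = 5)
  occ <- hbond_occupancy(static_trajectory(stk), stk, c("A", "B"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pair_matrix(occ, path)
  got <- utils::read.delim(path, check.names = FALSE)
  expect_equal(nrow(got), nrow(occ))
})
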
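# Shared fixtures for the test suite. Built once per test run; all
# generators are deterministic for a given seed.

hetero4 <- function() make_abeta_iapp_stack(n_chains = 4)

junction_alignment <- function() gapless_align(c(9L, 42L), c(4L, 37L))

# small poly-ALA fibril for fast engine/analysis tests
small_fibril <- function(n_chains = 3, n_residues = 8, ...) {
  make_ideal_fibril(fibril_recipe(n_chains = n_chains,
                                  n_residues = n_residues, ...))
}

# a Trajectory holding the given coordinate frames of `model`
static_trajectory <- function(model, n = 2) {
  tab <- model_atom_table(model)
  xyz <- as.matrix(tab[, c("x", "y", "z")])
  new_trajectory(tab, rep(list(xyz), n), times = seq_len(n) - 1)
}

# brute-force RMSD after optimal superposition, via a fine rotation grid
# (test oracle for Kabsch; only usable for tiny point sets)
grid_rmsd <- function(ref, mob, n_grid = 60) {
  best <- Inf
  angs <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  half <- seq(0, pi, length.out = n_grid %/% 2 + 1)
  refc <- sweep(ref, 2, colMeans(ref))
  mobc <- sweep(mob, 2, colMeans(mob))
  for (a in angs) for (b in half) for (g in angs) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
    Rz2 <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3, byrow = TRUE)
    R <- Rz1 %*% Ry %*% Rz2
    d <- refc - mobc %*% t(R)
    best <- min(best, sqrt(mean(rowSums(d^2))))
  }
  best
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_transform_traj <- function(traj, R, t) {
  traj$coords <- lapply(traj$coords, function(x) x %*% t(R) + rep(t, each = nrow(x)))
  traj
}
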
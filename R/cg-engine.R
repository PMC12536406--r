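# unit constants: kcal/mol, Angstrom, ps, amu
KB_KCAL <- 0.0019872041          # Boltzmann constant, kcal/mol/K
ACC_CONV <- 418.4                # (kcal/mol/A)/amu -> A/ps^2

# average residue masses, amu
RES_MASS <- c(ALA = 71.08, ARG = 156.19, ASN = 114.10, ASP = 115.09,
              CYS = 103.14, GLN = 128.13, GLU = 129.12, GLY = 57.05,
              HIS = 137.14, ILE = 113.16, LEU = 113.16, LYS = 128.17,
              MET = 131.19, PHE = 147.18, PRO = 97.12, SER = 87.08,
              THR = 101.10, TRP = 186.21, TYR = 163.18, VAL = 99.13)

#' Build a coarse-grained topology from a fibril model
#'
#' One bead per residue at the CA position; consecutive residues within a
#' chain are joined by pseudo-bonds with equilibrium length 3.8 A (the
#' trans CA-CA virtual bond). Bonded pairs are excluded from sterics.
#'
#' @param model a `FibrilModel`; every residue must have a CA atom.
#' @param bond_k pseudo-bond force constant, kcal/mol/A^2.
#' @param bead_radius soft-sphere radius per bead, Angstrom.
#' @return A `CGSystem`.
#' @export
build_cg_topology <- function(model, bond_k = 20, bead_radius = 2.0) {
  chain <- character(); resid <- integer(); resname <- character()
  xyz <- list()
  for (ch in model$chains) {
    resids <- chain_resids(ch)
    for (r in resids) {
      ca <- atom_xyz(ch, r, "CA")
      if (is.null(ca))
        stop("malformed chain ", ch$id, ": residue ", r, " lacks CA")
      chain <- c(chain, ch$id); resid <- c(resid, r)
      resname <- c(resname, ch$atoms$resname[match(r, ch$atoms$resid)])
      xyz[[length(xyz) + 1]] <- ca
    }
  }
  n <- length(resid)
  bonds <- NULL
  for (cid in unique(chain)) {
    idx <- which(chain == cid)
    consec <- which(diff(resid[idx]) == 1L)
    if (length(consec))
      bonds <- rbind(bonds, cbind(idx[consec], idx[consec + 1L]))
  }
  if (is.null(bonds)) bonds <- matrix(integer(), ncol = 2)
  mass <- unname(RES_MASS[resname]); mass[is.na(mass)] <- 110
  structure(list(n = n, chain = chain, resid = resid, resname = resname,
                 mass = mass, radius = rep(bead_radius, n),
                 bonds = bonds, bond_r0 = 3.8, bond_k = bond_k,
                 coords = do.call(rbind, xyz)),
            class = "CGSystem")
}

#' @export
print.CGSystem <- function(x, ...) {
  cat(sprintf("CGSystem: %d beads, %d pseudo-bonds (r0 %.1f A)\n",
              x$n, nrow(x$bonds), x$bond_r0))
  invisible(x)
}

# map a restraint table onto bead index pairs; the CG engine applies every
# restraint at the residue bead regardless of the named atom
.restraint_pairs <- function(system, restraints) {
  df <- if (inherits(restraints, "RestraintSet"))
    rbind(restraints$beta, restraints$shape) else restraints
  if (is.null(df) || !nrow(df))
    return(data.frame(i = integer(), j = integer(), r0 = numeric(),
                      k = numeric(), category = character()))
  key <- paste(system$chain, system$resid)
  i <- match(paste(df$chain_i, df$resid_i), key)
  j <- match(paste(df$chain_j, df$resid_j), key)
  if (anyNA(i) || anyNA(j))
    stop("restraint references residue(s) absent from the CG system")
  data.frame(i = i, j = j, r0 = df$r0, k = df$k, category = df$category,
             stringsAsFactors = FALSE)
}

.pair_dist <- function(coords, i, j) {
  d <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
  sqrt(rowSums(d * d))
}

# steric candidate pairs: all nonbonded pairs closer than the contact sum
.steric_pairs <- function(system) {
  n <- system$n
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  excl <- paste(system$bonds[, 1], system$bonds[, 2])
  keep <- !(paste(ij[, 1], ij[, 2]) %in% excl)
  ij[keep, , drop = FALSE]
}

#' Potential energy of a CG configuration
#'
#' Total = pseudo-bond harmonics + purely repulsive soft-sphere sterics +
#' harmonic restraint terms `0.5 k (r - r0)^2`, with components reported
#' separately.
#'
#' @param system a `CGSystem`.
#' @param coords N x 3 bead coordinates.
#' @param restraints a `RestraintSet`, restraint data.frame, or `NULL`.
#' @param k_rep steric penalty stiffness, kcal/mol/A^2.
#' @return list with `total` and named `components` (bonds, sterics, beta,
#'   shape), kcal/mol.
#' @export
potential_energy <- function(system, coords, restraints = NULL, k_rep = 10) {
  rp <- .restraint_pairs(system, restraints)
  st <- .steric_pairs(system)
  comp <- .cg_energy(system, coords, rp, st, k_rep)
  list(total = sum(comp), components = comp)
}

.cg_energy <- function(system, coords, rp, st, k_rep) {
  e_bond <- 0
  if (nrow(system$bonds)) {
    r <- .pair_dist(coords, system$bonds[, 1], system$bonds[, 2])
    e_bond <- sum(0.5 * system$bond_k * (r - system$bond_r0)^2)
  }
  e_ster <- 0
  if (nrow(st)) {
    r <- .pair_dist(coords, st[, 1], st[, 2])
    d0 <- system$radius[st[, 1]] + system$radius[st[, 2]]
    ov <- pmax(d0 - r, 0)
    e_ster <- sum(k_rep * ov^2)
  }
  e_beta <- e_shape <- 0
  if (nrow(rp)) {
    r <- .pair_dist(coords, rp$i, rp$j)
    e <- 0.5 * rp$k * (r - rp$r0)^2
    e_beta <- sum(e[rp$category != "shape"])
    e_shape <- sum(e[rp$category == "shape"])
  }
  c(bonds = e_bond, sterics = e_ster, beta = e_beta, shape = e_shape)
}

.cg_forces <- function(system, coords, rp, st, k_rep) {
  f <- matrix(0, system$n, 3)
  # bonds
  if (nrow(system$bonds)) {
    i <- system$bonds[, 1]; j <- system$bonds[, 2]
    d <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
    r <- sqrt(rowSums(d * d)); r[r < 1e-12] <- 1e-12
    g <- (system$bond_k * (r - system$bond_r0) / r) * d
    f <- .scatter_forces(f, i, j, g)
  }
  # sterics
  if (nrow(st)) {
    i <- st[, 1]; j <- st[, 2]
    d <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
    r <- sqrt(rowSums(d * d)); r[r < 1e-12] <- 1e-12
    d0 <- system$radius[i] + system$radius[j]
    dEdr <- ifelse(r < d0, -2 * k_rep * (d0 - r), 0)
    g <- (dEdr / r) * d
    f <- .scatter_forces(f, i, j, g)
  }
  # restraints
  if (nrow(rp)) {
    i <- rp$i; j <- rp$j
    d <- coords[i, , drop = FALSE] - coords[j, , drop = FALSE]
    r <- sqrt(rowSums(d * d)); r[r < 1e-12] <- 1e-12
    g <- (rp$k * (r - rp$r0) / r) * d
    f <- .scatter_forces(f, i, j, g)
  }
  f
}

# accumulate -gradient contributions of pair vectors g (dE/dx_i rowwise)
.scatter_forces <- function(f, i, j, g) {
  for (ax in 1:3) {
    f[, ax] <- f[, ax] - .group_sum(g[, ax], i, nrow(f)) + .group_sum(g[, ax], j, nrow(f))
  }
  f
}

.group_sum <- function(v, idx, n) {
  out <- numeric(n)
  s <- tapply(v, idx, sum)
  out[as.integer(names(s))] <- s
  out
}

#' Restrained energy minimization
#'
#' Steepest descent with a backtracking line search; the energy trace is
#' nonincreasing by construction. Terminates when the largest per-bead
#' force norm falls below `f_tol` or after `max_steps` accepted steps.
#'
#' @param system a `CGSystem`.
#' @param coords starting N x 3 coordinates.
#' @param restraints restraints as in [potential_energy()].
#' @param max_steps maximum accepted steps.
#' @param f_tol force tolerance, kcal/mol/A.
#' @param k_rep steric stiffness.
#' @return list with `coords`, `trace` (energy after each accepted step,
#'   starting at the initial energy) and `converged`.
#' @export
minimize <- function(system, coords, restraints = NULL, max_steps = 2000,
                     f_tol = 1e-3, k_rep = 10) {
  rp <- .restraint_pairs(system, restraints)
  st <- .steric_pairs(system)
  x <- as.matrix(coords)
  e <- sum(.cg_energy(system, x, rp, st, k_rep))
  trace <- e
  alpha <- 0.1
  for (step in seq_len(max_steps)) {
    f <- .cg_forces(system, x, rp, st, k_rep)
    fmax <- sqrt(max(rowSums(f * f)))
    if (fmax <= f_tol) break
    dir <- f / fmax                     # normalized steepest descent
    accepted <- FALSE
    for (try in 1:40) {
      x2 <- x + alpha * dir
      e2 <- sum(.cg_energy(system, x2, rp, st, k_rep))
      if (e2 <= e + 1e-12) { accepted <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!accepted) break                # line search exhausted: at a minimum
    x <- x2
    if (e2 > e + 1e-6)
      stop("numerical error: energy increased during minimization")
    e <- e2
    trace <- c(trace, e)
    alpha <- min(alpha * 1.25, 1.0)
  }
  list(coords = x, trace = trace,
       converged = sqrt(max(rowSums(.cg_forces(system, x, rp, st, k_rep)^2))) <= f_tol)
}

#' Langevin dynamics on the CG system
#'
#' BAOAB-splitting Langevin integrator. Stable provided
#' `dt < 2 / sqrt(k_max_eff * ACC / m_min)` for the stiffest force constant
#' `k_max_eff` (with the defaults, dt = 0.01 ps is well inside the bound).
#' Bitwise reproducible for identical seed and inputs; the seed is recorded
#' in the trajectory metadata.
#'
#' @param system a `CGSystem`.
#' @param coords starting N x 3 coordinates.
#' @param restraints restraints as in [potential_energy()].
#' @param n_steps number of integration steps.
#' @param dt timestep, ps.
#' @param temperature Kelvin.
#' @param friction collision frequency, 1/ps.
#' @param seed integer RNG seed for this run.
#' @param stride emit a frame every `stride` steps (frame 0 always emitted).
#' @param k_rep steric stiffness.
#' @return A `Trajectory` of CA beads; `metadata` records the run
#'   parameters and the per-emitted-frame instantaneous kinetic temperature
#'   (`kinetic_temperature`, Kelvin).
#' @export
langevin_run <- function(system, coords, restraints = NULL, n_steps = 1000,
                         dt = 0.01, temperature = 300, friction = 1,
                         seed = 1, stride = 10, k_rep = 10) {
  rp <- .restraint_pairs(system, restraints)
  st <- .steric_pairs(system)
  x <- as.matrix(coords)
  n <- system$n
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  m <- system$mass
  sig_v <- sqrt(KB_KCAL * temperature * ACC_CONV / m)   # A/ps
  v <- matrix(stats::rnorm(3 * n), n, 3) * sig_v
  if (temperature == 0) v[] <- 0
  c1 <- exp(-friction * dt)
  c2 <- sqrt(1 - c1^2)
  f <- .cg_forces(system, x, rp, st, k_rep)
  kin_t <- function(v) sum(m * rowSums(v * v)) / ACC_CONV / (3 * n * KB_KCAL)
  frames <- list(x); times <- 0; temps <- kin_t(v)
  for (s in seq_len(n_steps)) {
    v <- v + (0.5 * dt * ACC_CONV / m) * f
    x <- x + 0.5 * dt * v
    v <- c1 * v + c2 * sig_v * matrix(stats::rnorm(3 * n), n, 3)
    x <- x + 0.5 * dt * v
    f <- .cg_forces(system, x, rp, st, k_rep)
    v <- v + (0.5 * dt * ACC_CONV / m) * f
    if (!all(is.finite(x)))
      stop("instability error: non-finite coordinates at step ", s)
    if (s %% stride == 0) {
      frames[[length(frames) + 1]] <- x
      times <- c(times, s * dt)
      temps <- c(temps, kin_t(v))
    }
  }
  atom_table <- data.frame(chain = system$chain, resid = system$resid,
                           resname = system$resname, elety = "CA",
                           stringsAsFactors = FALSE)
  new_trajectory(atom_table, frames, times,
                 metadata = list(seed = seed, dt = dt, temperature = temperature,
                                 friction = friction, n_steps = n_steps,
                                 stride = stride,
                                 kinetic_temperature = temps))
}

#' Back-map a CA-bead trajectory onto a full-atom topology
#'
#' Each residue's non-CA atoms follow their CA bead rigidly (per-residue
#' translation), turning a CG trajectory into an all-atom trajectory whose
#' local residue geometry is that of the reference model. Suitable for
#' hydrogen-bond, contact and dihedral analysis of gently restrained runs.
#'
#' @param traj a CA `Trajectory` from [langevin_run()].
#' @param model the full-atom `FibrilModel` the CG system was built from.
#' @return a full-atom `Trajectory`.
#' @export
backmap_trajectory <- function(traj, model) {
  tab <- model_atom_table(model)
  key_atom <- paste(tab$chain, tab$resid)
  key_bead <- paste(traj$atom_table$chain, traj$atom_table$resid)
  bead_of <- match(key_atom, key_bead)
  if (anyNA(bead_of)) stop("model contains residues absent from the CG trajectory")
  ca0 <- as.matrix(tab[tab$elety == "CA", c("x", "y", "z")])
  ref <- as.matrix(tab[, c("x", "y", "z")])
  frames <- lapply(traj$coords, function(xyz) {
    ref + (xyz - ca0)[bead_of, , drop = FALSE]
  })
  new_trajectory(tab, frames, traj$times, traj$metadata)
}
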
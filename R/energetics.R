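COULOMB_K <- 332.0636   # kcal/mol * A / e^2

#' Load the per-atom energy parameter table
#'
#' The shipped table carries CHARMM-style backbone partial charges and
#' Lennard-Jones parameters, with side chains coarse-grained into a CB
#' bead that carries the side-chain formal charge; variant rows cover
#' disulfide-bonded cysteine (no thiol hydrogen) and the amidated
#' C-terminal cap (NT/HT atoms). A `*` resname is a wildcard; specific
#' (resname, variant, elety) rows take precedence.
#'
#' @param path TSV path; default the table shipped with the package.
#' @return data.frame with columns `resname`, `variant`, `elety`, `charge`
#'   (e), `epsilon` (kcal/mol), `sigma` (A), `rborn` (A).
#' @export
energy_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "gb_params.tsv", package = "crossbeta",
                        mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Assign per-atom energy parameters to a model
#'
#' Every atom must be matched by residue/atom name in the parameter table.
#' Cysteines listed in a chain's disulfide pairs use the disulfide variant;
#' NT/HT cap atoms of an amidated C-terminus use the amide variant.
#'
#' @param model a `FibrilModel`.
#' @param param_table table from [energy_params()].
#' @return a `ParamTopology`: the [model_atom_table()] with `charge`,
#'   `epsilon`, `sigma`, `rborn` columns appended.
#' @export
assign_parameters <- function(model, param_table = energy_params()) {
  tab <- model_atom_table(model)
  ss_res <- amide_res <- character()
  for (ch in model$chains) {
    for (p in ch$disulfides) ss_res <- c(ss_res, paste(ch$id, p))
    if (ch$c_term_amidated)
      amide_res <- c(amide_res, paste(ch$id, max(chain_resids(ch))))
  }
  variant <- rep("std", nrow(tab))
  variant[paste(tab$chain, tab$resid) %in% ss_res & tab$resname == "CYS"] <- "disulfide"
  variant[paste(tab$chain, tab$resid) %in% amide_res &
            tab$elety %in% c("NT", "HT1", "HT2")] <- "amide"

  lookup <- function(resname, var, elety) {
    for (key in list(c(resname, var), c(resname, "std"), c("*", var), c("*", "std"))) {
      hit <- which(param_table$resname == key[1] & param_table$variant == key[2] &
                     param_table$elety == elety)
      if (length(hit)) return(hit[1])
    }
    NA_integer_
  }
  rows <- mapply(lookup, tab$resname, variant, tab$elety)
  if (anyNA(rows)) {
    bad <- unique(paste0(tab$resname, ":", tab$elety)[is.na(rows)])
    stop("parameter error: unmatched atom(s) ", paste(bad, collapse = ", "))
  }
  out <- cbind(tab, param_table[rows, c("charge", "epsilon", "sigma", "rborn")])
  rownames(out) <- NULL
  class(out) <- c("ParamTopology", "data.frame")
  out
}

#' Effective Born radii by pairwise HCT descreening
#'
#' Hawkins-Cramer-Truhlar pairwise approximation: each atom's inverse
#' effective radius is its inverse intrinsic radius (less a 0.09 A offset)
#' minus scaled descreening integrals over all other atoms.
#'
#' @param ptop a `ParamTopology`.
#' @param xyz N x 3 coordinates (default the topology's own).
#' @param offset intrinsic-radius offset, A.
#' @param s_hct descreening scale factor.
#' @return numeric vector of effective Born radii, A.
#' @export
born_radii <- function(ptop, xyz = as.matrix(ptop[, c("x", "y", "z")]),
                       offset = 0.09, s_hct = 0.8) {
  n <- nrow(ptop)
  rho <- pmax(ptop$rborn - offset, 0.5)
  sj <- s_hct * rho
  inv <- 1 / rho
  block <- 400L
  for (start in seq(1, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d <- xyz[idx, , drop = FALSE]
    r2 <- outer(rowSums(d * d), rep(1, n)) +
      outer(rep(1, length(idx)), rowSums(xyz * xyz)) - 2 * d %*% t(xyz)
    r <- sqrt(pmax(r2, 0))
    R <- matrix(rho[idx], length(idx), n)
    S <- matrix(sj, length(idx), n, byrow = TRUE)
    U <- r + S
    L <- pmax(abs(r - S), R)
    act <- U > R & r > 1e-9
    I <- matrix(0, length(idx), n)
    rr <- r[act]; LL <- L[act]; UU <- U[act]; SS <- S[act]
    I[act] <- 0.5 * (1 / LL - 1 / UU + rr / 4 * (1 / UU^2 - 1 / LL^2) +
                       1 / (2 * rr) * log(LL / UU) +
                       SS^2 / (4 * rr) * (1 / LL^2 - 1 / UU^2))
    diag_idx <- cbind(seq_along(idx), idx)
    I[diag_idx] <- 0
    inv[idx] <- inv[idx] - rowSums(I)
  }
  1 / pmax(inv, 1e-4)
}

#' Generalized-Born cross (screening) term for a charge pair
#'
#' `-0.5 (1/eps_p - 1/eps_w) K q1 q2 / f_GB` with
#' `f_GB = sqrt(r^2 + R1 R2 exp(-r^2 / (4 R1 R2)))`. At r = 0 with R1 = R2
#' = R this reduces to the Born self-solvation formula; as the radii grow
#' with `eps_w -> eps_p` the screening vanishes and the interaction tends
#' to bare Coulomb.
#'
#' @param q1,q2 charges, e.
#' @param r distance, A.
#' @param R1,R2 effective Born radii, A.
#' @param eps_p,eps_w solute and solvent dielectric constants.
#' @return energy, kcal/mol.
#' @export
gb_cross_term <- function(q1, q2, r, R1, R2, eps_p = 1, eps_w = 80) {
  fgb <- sqrt(r^2 + R1 * R2 * exp(-r^2 / (4 * R1 * R2)))
  -0.5 * (1 / eps_p - 1 / eps_w) * COULOMB_K * q1 * q2 / fgb
}

# atom-pairwise polar/nonpolar energies between two atom index sets;
# returns list(polar, nonpolar) matrices (length(i) x length(j))
.pair_energy_matrices <- function(ptop, xyz, ai, aj, born,
                                  eps_p, eps_w, gamma, probe) {
  A <- xyz[ai, , drop = FALSE]; B <- xyz[aj, , drop = FALSE]
  r2 <- outer(rowSums(A * A), rep(1, length(aj))) +
    outer(rep(1, length(ai)), rowSums(B * B)) - 2 * A %*% t(B)
  r <- sqrt(pmax(r2, 0))
  if (any(r < 0.1)) {
    warning("clash warning: atom pair(s) under 0.1 A; energies capped")
    r[r < 0.1] <- 0.1
  }
  qq <- outer(ptop$charge[ai], ptop$charge[aj])
  coul <- COULOMB_K * qq / (eps_p * r)
  RR <- outer(born[ai], born[aj])
  fgb <- sqrt(r^2 + RR * exp(-r^2 / (4 * RR)))
  gb <- -0.5 * (1 / eps_p - 1 / eps_w) * COULOMB_K * qq / fgb
  eps_ij <- sqrt(outer(ptop$epsilon[ai], ptop$epsilon[aj]))
  sig_ij <- outer(ptop$sigma[ai], ptop$sigma[aj], "+") / 2
  sr6 <- (sig_ij / r)^6
  lj <- 4 * eps_ij * (sr6^2 - sr6)
  lj <- pmin(lj, 100)                      # clash cap
  sasa <- -gamma * .buried_area(r, ptop$rborn[ai] + probe, ptop$rborn[aj] + probe)
  list(polar = coul + gb, nonpolar = lj + sasa)
}

# pairwise sphere-lens buried area between solvent-expanded spheres
.buried_area <- function(r, R1, R2) {
  R1 <- matrix(R1, nrow(r), ncol(r))
  R2 <- matrix(R2, nrow(r), ncol(r), byrow = TRUE)
  area <- matrix(0, nrow(r), ncol(r))
  ov <- r < R1 + R2 & r > abs(R1 - R2)
  if (any(ov)) {
    h1 <- (R2[ov]^2 - (r[ov] - R1[ov])^2) / (2 * r[ov])
    h2 <- (R1[ov]^2 - (r[ov] - R2[ov])^2) / (2 * r[ov])
    area[ov] <- 2 * pi * (R1[ov] * h1 + R2[ov] * h2)
  }
  inc <- r <= abs(R1 - R2)                 # smaller sphere enclosed
  if (any(inc)) area[inc] <- 4 * pi * pmin(R1[inc], R2[inc])^2
  area
}

#' Polar/nonpolar interaction energy of one residue pair
#'
#' Polar = Coulomb at the solute dielectric plus the generalized-Born
#' screening cross term; nonpolar = Lennard-Jones plus a pairwise
#' solvent-accessible-surface burial term (`-gamma * buried area`).
#'
#' @param ptop a `ParamTopology`.
#' @param res_i,res_j `list(chain =, resid =)` on different chains.
#' @param xyz N x 3 coordinates (default the topology's own).
#' @param born effective Born radii (default recomputed via
#'   [born_radii()]).
#' @param eps_p,eps_w solute/solvent dielectrics (1 / 80).
#' @param gamma surface-tension coefficient, kcal/mol/A^2 (0.0072).
#' @param probe solvent probe radius, A (1.4).
#' @return named numeric `c(polar =, nonpolar =)`, kcal/mol.
#' @export
pair_interaction <- function(ptop, res_i, res_j,
                             xyz = as.matrix(ptop[, c("x", "y", "z")]),
                             born = born_radii(ptop, xyz),
                             eps_p = 1, eps_w = 80, gamma = 0.0072,
                             probe = 1.4) {
  if (identical(res_i$chain, res_j$chain))
    stop("pair_interaction is defined for residues on different chains")
  ai <- which(ptop$chain == res_i$chain & ptop$resid == res_i$resid)
  aj <- which(ptop$chain == res_j$chain & ptop$resid == res_j$resid)
  if (!length(ai) || !length(aj)) stop("residue not found in topology")
  m <- .pair_energy_matrices(ptop, xyz, ai, aj, born, eps_p, eps_w, gamma, probe)
  c(polar = sum(m$polar), nonpolar = sum(m$nonpolar))
}

#' Residue-pairwise interaction energy maps for a chain pair
#'
#' Time-averaged polar and nonpolar residue x residue interaction energy
#' maps over sampled frames (Born radii recomputed per frame).
#'
#' @inheritParams hbond_occupancy
#' @param stride sample every `stride`-th frame.
#' @param params parameter table from [energy_params()].
#' @param eps_p,eps_w,gamma,probe see [pair_interaction()].
#' @return list with `polar` and `nonpolar` `PairMatrix` objects (kcal/mol).
#' @export
interaction_map <- function(traj, topology, chain_pair, stride = 1,
                            params = energy_params(), eps_p = 1, eps_w = 80,
                            gamma = 0.0072, probe = 1.4, burn_in = 0) {
  ptop <- assign_parameters(topology, params)
  tab <- traj$atom_table
  if (nrow(tab) != nrow(ptop))
    stop("trajectory and topology atom counts differ")
  frames <- .analysis_frames(traj, burn_in)
  frames <- frames[seq(1, length(frames), by = stride)]
  if (!length(frames)) stop("empty frame set")
  ai <- which(ptop$chain == chain_pair[1])
  aj <- which(ptop$chain == chain_pair[2])
  r1 <- sort(unique(ptop$resid[ai])); r2 <- sort(unique(ptop$resid[aj]))
  M1 <- outer(r1, ptop$resid[ai], "==") * 1
  M2 <- outer(r2, ptop$resid[aj], "==") * 1
  pol <- npl <- matrix(0, length(r1), length(r2), dimnames = list(r1, r2))
  for (f in frames) {
    xyz <- traj$coords[[f]]
    born <- born_radii(ptop, xyz)
    m <- .pair_energy_matrices(ptop, xyz, ai, aj, born, eps_p, eps_w, gamma, probe)
    pol <- pol + M1 %*% m$polar %*% t(M2)
    npl <- npl + M1 %*% m$nonpolar %*% t(M2)
  }
  list(polar = .new_pair_matrix(pol / length(frames), chain_pair, "POLAR_KCAL"),
       nonpolar = .new_pair_matrix(npl / length(frames), chain_pair, "NONPOLAR_KCAL"))
}

#' Residue-normalized interaction energy of one chain
#'
#' Sums a chain's interaction energies with all its stack neighbors and
#' divides by its residue count, giving a size-independent per-chain polar
#' and nonpolar energy (the quantity used to compare junction chains with
#' chains deeper in the homomeric regions).
#'
#' @param maps named list of [interaction_map()] results, one per
#'   interface, named `"X:Y"` for adjacent chain pair (X, Y) in stacking
#'   order.
#' @param model the `FibrilModel` (defines chain adjacency and residue
#'   counts).
#' @param chain_id the chain to summarize.
#' @return named numeric `c(polar =, nonpolar =)`, kcal/mol per residue.
#' @export
residue_normalized_energy <- function(maps, model, chain_id) {
  ids <- names(model$chains)
  k <- match(chain_id, ids)
  if (is.na(k)) stop("unknown chain ", chain_id)
  neighbors <- character()
  if (k > 1) neighbors <- c(neighbors, paste0(ids[k - 1], ":", ids[k]))
  if (k < length(ids)) neighbors <- c(neighbors, paste0(ids[k], ":", ids[k + 1]))
  pol <- npl <- 0
  for (nm in neighbors) {
    if (is.null(maps[[nm]]))
      stop("coverage error: missing interface map ", nm)
    pol <- pol + sum(maps[[nm]]$polar)
    npl <- npl + sum(maps[[nm]]$nonpolar)
  }
  nres <- length(chain_resids(model$chains[[k]]))
  c(polar = pol / nres, nonpolar = npl / nres)
}

#' Residue-normalized energies for all (or inner) chains
#'
#' @inheritParams residue_normalized_energy
#' @param exclude_edges drop the outermost chains (they have a single
#'   neighbor, and edge effects are not of interest).
#' @return a `ChainEnergySummary` data.frame: `chain`, `polar`, `nonpolar`,
#'   `total`, kcal/mol per residue.
#' @export
chain_energy_summary <- function(maps, model, exclude_edges = TRUE) {
  ids <- names(model$chains)
  if (exclude_edges && length(ids) > 2) ids <- ids[-c(1, length(ids))]
  rows <- lapply(ids, function(cid) {
    e <- residue_normalized_energy(maps, model, cid)
    data.frame(chain = cid, polar = e[["polar"]], nonpolar = e[["nonpolar"]],
               total = e[["polar"]] + e[["nonpolar"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ChainEnergySummary", "data.frame")
  out
}
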
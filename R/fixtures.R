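#' Recipe for an idealized cross-beta fibril
#'
#' Describes a parallel in-register stack: every chain is an exact
#' translate of the first along the fibril (z) axis at the given
#' inter-strand rise. The strand is built with ideal peptide-backbone
#' internal coordinates at the given (phi, psi); carbonyl O and amide H
#' atoms are phased along +/- z so that adjacent strands form ideal
#' N-H...O=C hydrogen bonds (N...O 2.9 A, angle 180 deg) -- the geometry
#' the beta-sheet-like restraints bias toward. Side chains are represented
#' by a CB pseudo-atom.
#'
#' @param n_chains chains in the stack.
#' @param sequence one-letter peptide sequence (sets the residue count), or
#'   `NULL` with `n_residues` for a poly-alanine strand.
#' @param n_residues residues per chain when `sequence` is `NULL`.
#' @param rise inter-strand rise, Angstrom (default 4.8, canonical
#'   cross-beta spacing).
#' @param phi,psi backbone dihedrals, degrees (defaults -119/+113, parallel
#'   beta region).
#' @param first_resid resid of the first residue (1-based labels).
#' @param chain_ids chain labels (default consecutive LETTERS).
#' @param molecule molecule tag for the chains.
#' @param parity_offset integer added to the resid before choosing the
#'   hydrogen-bond face (carbonyl up vs down); lets two stacks with a
#'   residue-offset alignment share H-bond phase across their junction.
#' @param c_term_amidated add an `NT` amide cap on the last residue.
#' @param disulfides list of resid pairs recorded as disulfide bridges.
#' @param perturbation i.i.d. Gaussian coordinate noise sd, Angstrom.
#' @param seed RNG seed for the perturbation.
#' @return a `FibrilRecipe` list.
#' @export
fibril_recipe <- function(n_chains = 4, sequence = NULL, n_residues = 20,
                          rise = 4.8, phi = -119, psi = 113,
                          first_resid = 1L, chain_ids = NULL,
                          molecule = "OTHER", parity_offset = 0L,
                          c_term_amidated = FALSE, disulfides = list(),
                          perturbation = 0, seed = 1) {
  stopifnot(rise > 0, perturbation >= 0, n_chains >= 1)
  if (!is.null(sequence)) n_residues <- nchar(sequence)
  if (is.null(chain_ids)) chain_ids <- LETTERS[seq_len(n_chains)]
  structure(list(n_chains = n_chains, sequence = sequence,
                 n_residues = n_residues, rise = rise, phi = phi, psi = psi,
                 first_resid = as.integer(first_resid), chain_ids = chain_ids,
                 molecule = molecule, parity_offset = as.integer(parity_offset),
                 c_term_amidated = c_term_amidated, disulfides = disulfides,
                 perturbation = perturbation, seed = seed),
            class = "FibrilRecipe")
}

# place atom d given a-b-c, bond length r (c-d), angle theta (b-c-d) and
# torsion phi (a-b-c-d), degrees
.nerf <- function(a, b, c, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- r * c(-cos(th), sin(th) * cos(ph), -sin(th) * sin(ph))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# build one strand's backbone (N, CA, C per residue) at constant phi/psi
.build_strand <- function(n_res, phi, psi) {
  N <- matrix(0, n_res, 3); CA <- matrix(0, n_res, 3); C <- matrix(0, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  ang <- 111 * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(cos(pi - ang), sin(pi - ang), 0)
  for (i in seq_len(n_res - 1) + 1) {
    N[i, ]  <- .nerf(N[i - 1, ], CA[i - 1, ], C[i - 1, ], 1.329, 116.7, psi)
    CA[i, ] <- .nerf(CA[i - 1, ], C[i - 1, ], N[i, ], 1.458, 121.9, 180)
    C[i, ]  <- .nerf(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111, phi)
  }
  list(N = N, CA = CA, C = C)
}

# orient a strand: CA axis along x, backbone best-fit plane normal along z
.orient_strand <- function(bb) {
  all_bb <- rbind(bb$N, bb$CA, bb$C)
  ctr <- colMeans(all_bb)
  x <- bb$CA[nrow(bb$CA), ] - bb$CA[1, ]; x <- x / sqrt(sum(x^2))
  pc <- prcomp(sweep(all_bb, 2, ctr), center = FALSE)
  z <- pc$rotation[, 3]
  z <- z - sum(z * x) * x; z <- z / sqrt(sum(z^2))
  # deterministic face: local normal at residue 1 points +z, so congruent
  # strands of any length come out in the same orientation
  v1 <- bb$CA[1, ] - bb$N[1, ]; v2 <- bb$C[1, ] - bb$CA[1, ]
  w <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
         v1[1] * v2[2] - v1[2] * v2[1])
  if (sum(w * z) < 0) z <- -z
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  R <- rbind(x, y, z)
  lapply(bb, function(m) sweep(m, 2, ctr) %*% t(R))
}

#' Build an idealized parallel in-register cross-beta fibril
#'
#' Deterministic for a given recipe. Chain `k` is chain 1 translated by
#' `(k-1) * rise` along z; corresponding CA atoms of adjacent chains are
#' therefore exactly `rise` apart, satisfying beta-sheet-like restraints at
#' `r0 = rise` when unperturbed.
#'
#' @param recipe a [fibril_recipe()].
#' @return a `FibrilModel`.
#' @export
make_ideal_fibril <- function(recipe) {
  n <- recipe$n_residues
  resids <- recipe$first_resid + seq_len(n) - 1L
  seq1 <- if (is.null(recipe$sequence)) strrep("A", n) else recipe$sequence
  resnames <- unname(AA123[strsplit(seq1, "")[[1]]])
  if (anyNA(resnames)) stop("unknown one-letter code in sequence")

  # An odd parity_offset shifts the strand's pleat phase by one residue
  # (build one extra leading residue, orient, then drop it) so that two
  # stacks aligned with an odd residue offset have congruent -- purely
  # translatable -- backbone windows across their junction.
  pad <- recipe$parity_offset %% 2L
  bb <- .orient_strand(.build_strand(n + pad, recipe$phi, recipe$psi))
  if (pad > 0)
    bb <- lapply(bb, function(m) m[-seq_len(pad), , drop = FALSE])
  s <- (-1)^((resids + recipe$parity_offset) %% 2)   # H-bond face per residue
  rows <- list()
  for (i in seq_len(n)) {
    O <- bb$N[i, ] + c(0, 0, s[i] * (recipe$rise - 2.9))
    H <- bb$N[i, ] + c(0, 0, -s[i] * 1.0)
    at <- rbind(N = bb$N[i, ], H = H, CA = bb$CA[i, ], C = bb$C[i, ], O = O)
    if (resnames[i] != "GLY") {
      CB <- .nerf(bb$C[i, ], bb$N[i, ], bb$CA[i, ], 1.53, 110.5, -122.6)
      at <- rbind(at, CB = CB)
    }
    if (i == n && recipe$c_term_amidated) {
      NT <- .nerf(bb$N[i, ], bb$CA[i, ], bb$C[i, ], 1.329, 116.7, recipe$psi)
      at <- rbind(at, NT = NT)
    }
    rows[[i]] <- data.frame(resid = resids[i], resname = resnames[i],
                            elety = rownames(at), x = at[, 1], y = at[, 2],
                            z = at[, 3], stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows); rownames(atoms) <- NULL
  chains <- lapply(seq_len(recipe$n_chains), function(k) {
    a <- atoms
    a$z <- a$z + (k - 1) * recipe$rise
    new_chain(recipe$chain_ids[k], a, molecule = recipe$molecule,
              disulfides = recipe$disulfides,
              c_term_amidated = recipe$c_term_amidated)
  })
  model <- new_fibril_model(chains, provenance = "synthetic ideal cross-beta fibril")
  if (recipe$perturbation > 0)
    model <- perturb(model, recipe$perturbation, recipe$seed)
  model
}

#' Stack two fibrils axially into a heteromeric model
#'
#' Translates model B rigidly so that its first chain sits `axial_gap`
#' above the last chain of model A along z, registered laterally so that
#' aligned residues (identity pairing by default, or an `AlignmentMap`)
#' start in register. Chains are relabeled consecutively (A-D / E-H for two
#' tetramers) and the junction interface is recorded between the stacks.
#'
#' @param modelA,modelB `FibrilModel`s sharing the z stacking convention
#'   (e.g. from [make_ideal_fibril()]). The junction forms between the last
#'   chain of A and the first chain of B.
#' @param axial_gap junction spacing along z, Angstrom.
#' @param align optional `AlignmentMap` (residA in A, residB in B) fixing
#'   the lateral registration; default pairs equal resids.
#' @return a `FibrilModel` with `junction_interface` set.
#' @export
make_hetero_stack <- function(modelA, modelB, axial_gap = 4.8, align = NULL) {
  chA <- modelA$chains[[length(modelA$chains)]]
  chB <- modelB$chains[[1]]
  if (is.null(align)) {
    shared <- intersect(chain_resids(chA), chain_resids(chB))
    if (!length(shared)) stop("no shared resids and no alignment supplied")
    resA <- shared; resB <- shared
  } else {
    resA <- align$residA; resB <- align$residB
  }
  target <- chain_coords(chA, resA, "CA")
  target[, 3] <- target[, 3] + axial_gap
  source <- chain_coords(chB, resB, "CA")
  sup <- superpose(target, source)
  if (length(modelB$chains) >= 2) {
    # A lone strand's CA trace is nearly planar, so when the two windows are
    # not congruent the fitted rotation can flip B's stacking axis downward,
    # into A. Detect that and refit with the second chain of B anchored one
    # B-rise further along +z so the B stack always continues away from A.
    chB2 <- modelB$chains[[2]]
    resB2 <- intersect(resB, chain_resids(chB2))
    src2 <- chain_coords(chB2, resB2, "CA")
    keep <- match(resB2, resB)
    riseB <- mean(sqrt(rowSums((src2 - source[keep, , drop = FALSE])^2)))
    up <- colMeans(apply_superposition(sup, src2)) -
      colMeans(apply_superposition(sup, source[keep, , drop = FALSE]))
    if (up[3] <= 0) {
      tgt2 <- target[keep, , drop = FALSE]
      tgt2[, 3] <- tgt2[, 3] + riseB
      sup <- superpose(rbind(target, tgt2), rbind(source, src2))
    }
  }
  nA <- length(modelA$chains)
  ids <- LETTERS[seq_len(nA + length(modelB$chains))]
  chains <- list()
  for (i in seq_len(nA)) {
    ch <- modelA$chains[[i]]; ch$id <- ids[i]
    chains[[i]] <- ch
  }
  for (i in seq_along(modelB$chains)) {
    ch <- modelB$chains[[i]]
    ch$atoms[, c("x", "y", "z")] <-
      apply_superposition(sup, as.matrix(ch$atoms[, c("x", "y", "z")]))
    ch$id <- ids[nA + i]
    chains[[nA + i]] <- ch
  }
  new_fibril_model(chains, junction_interface = nA,
                   provenance = "synthetic heteromeric stack")
}

#' Apply i.i.d. Gaussian coordinate noise to a model
#'
#' @param model a `FibrilModel`.
#' @param amplitude per-coordinate Gaussian sd, Angstrom; 0 returns the
#'   model unchanged.
#' @param seed RNG seed; identical seeds give identical output.
#' @return the perturbed `FibrilModel`.
#' @export
perturb <- function(model, amplitude, seed = 1) {
  stopifnot(amplitude >= 0)
  if (amplitude == 0) return(model)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  for (i in seq_along(model$chains)) {
    m <- as.matrix(model$chains[[i]]$atoms[, c("x", "y", "z")])
    m <- m + matrix(stats::rnorm(length(m), sd = amplitude), nrow(m), 3)
    model$chains[[i]]$atoms[, c("x", "y", "z")] <- m
  }
  model
}

#' Idealized amyloid-beta / IAPP heteromeric fixture
#'
#' Convenience wrapper building the worked case: a 4-chain amyloid-beta
#' (1-42) fibril stacked on a 4-chain IAPP (1-37) fibril (chains A-D /
#' E-H), with the IAPP stack's hydrogen-bond face phased to match the
#' 9-42 vs 4-37 junction alignment, IAPP disulfide 2-7 recorded and its
#' C-terminus amidated.
#'
#' @param n_chains chains per molecule.
#' @param rise inter-strand rise, Angstrom.
#' @param axial_gap junction gap along z (default `rise`).
#' @param perturbation,seed noise applied to the final stack.
#' @return a `FibrilModel` with the junction between chains D and E.
#' @export
make_abeta_iapp_stack <- function(n_chains = 4, rise = 4.8, axial_gap = rise,
                                  perturbation = 0, seed = 1) {
  align <- gapless_align(region_spec("restraint")$ABETA42,
                         region_spec("restraint")$IAPP)
  abeta <- make_ideal_fibril(fibril_recipe(
    n_chains = n_chains, sequence = abeta42_sequence(), rise = rise,
    molecule = "ABETA42"))
  iapp <- make_ideal_fibril(fibril_recipe(
    n_chains = n_chains, sequence = iapp_sequence(), rise = rise,
    molecule = "IAPP", parity_offset = attr(align, "offset") %% 2L,
    c_term_amidated = TRUE, disulfides = list(c(2L, 7L))))
  model <- make_hetero_stack(abeta, iapp, axial_gap = axial_gap, align = align)
  if (perturbation > 0) model <- perturb(model, perturbation, seed)
  model
}
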
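#' Select atom rows from a trajectory or model atom table
#'
#' @param atom_table data.frame with `chain`, `resid`, `elety` columns (a
#'   `Trajectory$atom_table` or [model_atom_table()]).
#' @param chains chain ids to keep (default all).
#' @param elety atom names to keep (default all).
#' @param resids residue ids to keep (default all).
#' @return integer row indices.
#' @export
atom_selection <- function(atom_table, chains = NULL, elety = NULL, resids = NULL) {
  keep <- rep(TRUE, nrow(atom_table))
  if (!is.null(chains)) keep <- keep & atom_table$chain %in% chains
  if (!is.null(elety)) keep <- keep & atom_table$elety %in% elety
  if (!is.null(resids)) keep <- keep & atom_table$resid %in% resids
  which(keep)
}

.new_pair_matrix <- function(values, chain_pair, semantics) {
  structure(values, chain_pair = chain_pair, semantics = semantics,
            class = c("PairMatrix", class(values)))
}

#' @export
print.PairMatrix <- function(x, ...) {
  cp <- attr(x, "chain_pair")
  cat(sprintf("PairMatrix [%s x %s] %s: %d x %d residues\n",
              cp[1], cp[2], attr(x, "semantics"), nrow(x), ncol(x)))
  invisible(x)
}

#' Write a residue-pair matrix as TSV (resid headers)
#' @param pm a `PairMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pair_matrix <- function(pm, path) {
  df <- data.frame(resid = rownames(pm), as.data.frame(unclass(pm)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# dihedral angle (degrees) for rowwise point quadruples
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  m1 <- cr(n1, b2 / sqrt(rowSums(b2 * b2)))
  atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi
}

# backbone amide donor table for selected chains: N index, explicit-H index
# (NA when the H must be built), preceding C and own CA for H construction
.donor_table <- function(tab, chains) {
  rows <- which(tab$chain %in% chains & tab$elety %in% c("N", "NT") &
                  !(tab$resname == "PRO" & tab$elety == "N"))
  out <- lapply(rows, function(i) {
    r <- tab$resid[i]; ch <- tab$chain[i]
    if (tab$elety[i] == "N") {
      h <- which(tab$chain == ch & tab$resid == r & tab$elety %in% c("H", "HN"))
      cprev <- which(tab$chain == ch & tab$resid == r - 1L & tab$elety == "C")
      ca <- which(tab$chain == ch & tab$resid == r & tab$elety == "CA")
    } else {                      # NT amide cap: treat like a backbone amide
      h <- which(tab$chain == ch & tab$resid == r & tab$elety %in% c("HT1", "HT2"))
      cprev <- which(tab$chain == ch & tab$resid == r & tab$elety == "C")
      ca <- which(tab$chain == ch & tab$resid == r & tab$elety == "CA")
    }
    if (!length(h) && (!length(cprev) || !length(ca))) return(NULL)
    data.frame(d = i, h = if (length(h)) h[1] else NA_integer_,
               cprev = if (length(cprev)) cprev[1] else NA_integer_,
               ca = ca[1], chain = ch, resid = r, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# hydrogen coordinates for a donor table in one frame: explicit where
# available, otherwise built on the C(prev)/CA bisector in the peptide
# plane at N-H 1.0 A
.donor_h <- function(xyz, dt) {
  H <- matrix(NA_real_, nrow(dt), 3)
  has <- !is.na(dt$h)
  H[has, ] <- xyz[dt$h[has], , drop = FALSE]
  build <- which(!has)
  if (length(build)) {
    N <- xyz[dt$d[build], , drop = FALSE]
    u1 <- N - xyz[dt$cprev[build], , drop = FALSE]
    u2 <- N - xyz[dt$ca[build], , drop = FALSE]
    u1 <- u1 / sqrt(rowSums(u1 * u1)); u2 <- u2 / sqrt(rowSums(u2 * u2))
    b <- u1 + u2; b <- b / sqrt(rowSums(b * b))
    H[build, ] <- N + b
  }
  H
}

# qualifying donor->acceptor hydrogen bonds in one frame; returns
# data.frame(res_d, res_a) of residue ids (donor side, acceptor side)
.frame_hbonds <- function(xyz, dt, acc_rows, acc_resid, d_cut, angle_cut) {
  if (is.null(dt) || !nrow(dt) || !length(acc_rows))
    return(data.frame(res_d = integer(), res_a = integer()))
  D <- xyz[dt$d, , drop = FALSE]
  A <- xyz[acc_rows, , drop = FALSE]
  H <- .donor_h(xyz, dt)
  dm2 <- outer(rowSums(D * D), rep(1, nrow(A))) +
    outer(rep(1, nrow(D)), rowSums(A * A)) - 2 * D %*% t(A)
  hits <- which(dm2 <= d_cut^2, arr.ind = TRUE)
  if (!nrow(hits)) return(data.frame(res_d = integer(), res_a = integer()))
  hd <- H[hits[, 1], , drop = FALSE]
  v1 <- D[hits[, 1], , drop = FALSE] - hd
  v2 <- A[hits[, 2], , drop = FALSE] - hd
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1 * v1)) * sqrt(rowSums(v2 * v2)))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  ok <- ang >= angle_cut
  data.frame(res_d = dt$resid[hits[ok, 1]], res_a = acc_resid[hits[ok, 2]])
}

#' Inter-chain hydrogen-bond occupancy map
#'
#' Entry (i, j) is the percentage of frames in which at least one
#' qualifying hydrogen bond links residue i of the first chain and residue
#' j of the second, in either donor/acceptor direction. A bond qualifies
#' when the donor-acceptor heavy-atom distance is at most `d_cut` and the
#' donor-H-acceptor angle is at least `angle_cut`. Missing backbone amide
#' hydrogens are constructed geometrically (N-H 1.0 A in the peptide
#' plane); with `backbone_only = FALSE`, side-chain N/O donors are used
#' when an explicit hydrogen lies within 1.2 A, and side-chain oxygens
#' accept.
#'
#' @param traj a `Trajectory` (full-atom).
#' @param topology the `FibrilModel` the trajectory lives on (residue
#'   chemistry; atom order must match).
#' @param chain_pair character vector of two chain ids.
#' @param d_cut donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle_cut donor-H-acceptor angle cutoff, degrees (default 150).
#' @param backbone_only restrict to backbone amides and carbonyls.
#' @param burn_in fraction of initial frames discarded as equilibration.
#' @return a `PairMatrix` (percent, residues of chain 1 x chain 2).
#' @export
hbond_occupancy <- function(traj, topology, chain_pair, d_cut = 3.5,
                            angle_cut = 150, backbone_only = TRUE,
                            burn_in = 0) {
  tab <- traj$atom_table
  frames <- .analysis_frames(traj, burn_in)
  r1 <- sort(unique(tab$resid[tab$chain == chain_pair[1]]))
  r2 <- sort(unique(tab$resid[tab$chain == chain_pair[2]]))
  if (!length(r1) || !length(r2))
    stop("empty-selection error: chain pair not present in trajectory")
  don <- lapply(chain_pair, function(ch) .donor_table(tab, ch))
  acc <- lapply(chain_pair, function(ch) {
    rows <- which(tab$chain == ch &
                    (tab$elety == "O" | tab$elety == "OXT" |
                       (!backbone_only & grepl("^O", tab$elety))))
    rows
  })
  if (!backbone_only) {
    don <- lapply(seq_along(chain_pair), function(k)
      rbind(don[[k]], .sidechain_donors(tab, traj$coords[[frames[1]]], chain_pair[k])))
  }
  if ((is.null(don[[1]]) && is.null(don[[2]])) ||
      (!length(acc[[1]]) && !length(acc[[2]])))
    stop("empty-selection error: no donors/acceptors in selection")
  counts <- matrix(0, length(r1), length(r2), dimnames = list(r1, r2))
  for (f in frames) {
    xyz <- traj$coords[[f]]
    hit <- matrix(FALSE, length(r1), length(r2))
    hb1 <- .frame_hbonds(xyz, don[[1]], acc[[2]], tab$resid[acc[[2]]], d_cut, angle_cut)
    if (nrow(hb1))
      hit[cbind(match(hb1$res_d, r1), match(hb1$res_a, r2))] <- TRUE
    hb2 <- .frame_hbonds(xyz, don[[2]], acc[[1]], tab$resid[acc[[1]]], d_cut, angle_cut)
    if (nrow(hb2))
      hit[cbind(match(hb2$res_a, r1), match(hb2$res_d, r2))] <- TRUE
    counts <- counts + hit
  }
  .new_pair_matrix(100 * counts / length(frames), chain_pair, "HBOND_PCT")
}

# side-chain donors: N/O atoms (beyond the backbone set) with an explicit
# hydrogen within 1.2 A in the reference frame
.sidechain_donors <- function(tab, xyz, ch) {
  cand <- which(tab$chain == ch & grepl("^[NO]", tab$elety) &
                  !tab$elety %in% c("N", "O", "OXT", "NT"))
  hyd <- which(tab$chain == ch & grepl("^H", tab$elety))
  out <- lapply(cand, function(i) {
    hr <- hyd[tab$resid[hyd] == tab$resid[i]]
    if (!length(hr)) return(NULL)
    d <- sqrt(rowSums((xyz[hr, , drop = FALSE] -
                         matrix(xyz[i, ], length(hr), 3, byrow = TRUE))^2))
    if (min(d) > 1.2) return(NULL)
    data.frame(d = i, h = hr[which.min(d)], cprev = NA_integer_,
               ca = NA_integer_, chain = ch, resid = tab$resid[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.analysis_frames <- function(traj, burn_in) {
  nf <- n_frames(traj)
  first <- min(nf, floor(burn_in * nf) + 1L)
  seq(first, nf)
}

#' Inter-chain residue contact probability map
#'
#' Entry (i, j) is the percentage of frames in which any heavy-atom pair
#' between residue i of the first chain and residue j of the second lies
#' within `d_cut`.
#'
#' @inheritParams hbond_occupancy
#' @param d_cut heavy-atom distance cutoff, Angstrom (default 4.5).
#' @return a `PairMatrix` (percent).
#' @export
contact_probability <- function(traj, topology, chain_pair, d_cut = 4.5,
                                burn_in = 0) {
  tab <- traj$atom_table
  frames <- .analysis_frames(traj, burn_in)
  sel <- lapply(chain_pair, function(ch)
    which(tab$chain == ch & !grepl("^H", tab$elety)))
  if (!length(sel[[1]]) || !length(sel[[2]]))
    stop("empty-selection error: chain pair not present in trajectory")
  r1 <- sort(unique(tab$resid[sel[[1]]]))
  r2 <- sort(unique(tab$resid[sel[[2]]]))
  M1 <- outer(r1, tab$resid[sel[[1]]], "==") * 1   # res x atom indicators
  M2 <- outer(r2, tab$resid[sel[[2]]], "==") * 1
  counts <- matrix(0, length(r1), length(r2), dimnames = list(r1, r2))
  for (f in frames) {
    A <- traj$coords[[f]][sel[[1]], , drop = FALSE]
    B <- traj$coords[[f]][sel[[2]], , drop = FALSE]
    d2 <- outer(rowSums(A * A), rep(1, nrow(B))) +
      outer(rep(1, nrow(A)), rowSums(B * B)) - 2 * A %*% t(B)
    counts <- counts + ((M1 %*% (d2 <= d_cut^2) %*% t(M2)) > 0)
  }
  .new_pair_matrix(100 * counts / length(frames), chain_pair, "CONTACT_PCT")
}

.in_beta_region <- function(phi, psi) {
  !is.na(phi) & !is.na(psi) &
    phi >= -180 & phi <= -45 &
    ((psi >= 45 & psi <= 180) | (psi >= -180 & psi <= -170))
}

# phi/psi for all residues of one chain in one frame (NA at termini)
.chain_dihedrals <- function(xyz, tab, ch) {
  rows <- function(r, e) {
    i <- which(tab$chain == ch & tab$resid == r & tab$elety == e)
    if (length(i)) i[1] else NA_integer_
  }
  resids <- sort(unique(tab$resid[tab$chain == ch]))
  N <- vapply(resids, rows, integer(1), e = "N")
  CA <- vapply(resids, rows, integer(1), e = "CA")
  C <- vapply(resids, rows, integer(1), e = "C")
  n <- length(resids)
  phi <- psi <- rep(NA_real_, n)
  prev_ok <- c(FALSE, diff(resids) == 1L)        # residue i-1 is sequential
  next_ok <- c(diff(resids) == 1L, FALSE)        # residue i+1 is sequential
  bb_ok <- !is.na(N) & !is.na(CA) & !is.na(C)
  ok_phi <- which(bb_ok & prev_ok & c(FALSE, !is.na(C[-n])))
  if (length(ok_phi))
    phi[ok_phi] <- .dihedral(xyz[C[ok_phi - 1], , drop = FALSE],
                             xyz[N[ok_phi], , drop = FALSE],
                             xyz[CA[ok_phi], , drop = FALSE],
                             xyz[C[ok_phi], , drop = FALSE])
  ok_psi <- which(bb_ok & next_ok & c(!is.na(N[-1]), FALSE))
  if (length(ok_psi))
    psi[ok_psi] <- .dihedral(xyz[N[ok_psi], , drop = FALSE],
                             xyz[CA[ok_psi], , drop = FALSE],
                             xyz[C[ok_psi], , drop = FALSE],
                             xyz[N[ok_psi + 1], , drop = FALSE])
  data.frame(resid = resids, phi = phi, psi = psi)
}

#' Beta-sheet content across a chain interface
#'
#' A residue counts as beta in a frame iff its (phi, psi) falls in the
#' beta region (phi in \[-180, -45\], psi in \[45, 180\] or \[-180, -170\])
#' AND it participates in at least one inter-chain backbone hydrogen-bond
#' ladder (with any other chain of the topology -- a junction chain's
#' residues outside the aligned overlap ladder with its homomeric
#' neighbor). Chain termini lacking phi or psi are excluded from the
#' summary, not errored.
#'
#' @inheritParams hbond_occupancy
#' @return list with `per_residue` (data.frame: chain, resid,
#'   beta_fraction) and `interface` (mean beta fraction over residues with
#'   defined dihedrals).
#' @export
beta_content <- function(traj, topology, chain_pair, d_cut = 3.5,
                         angle_cut = 150, burn_in = 0) {
  tab <- traj$atom_table
  frames <- .analysis_frames(traj, burn_in)
  don <- lapply(chain_pair, function(ch) .donor_table(tab, ch))
  all_chains <- unique(tab$chain)
  don_other <- lapply(chain_pair, function(ch) {
    dt <- lapply(setdiff(all_chains, ch), .donor_table, tab = tab)
    do.call(rbind, dt[!vapply(dt, is.null, logical(1))])
  })
  acc_self <- lapply(chain_pair, function(ch)
    which(tab$chain == ch & tab$elety %in% c("O", "OXT")))
  acc_other <- lapply(chain_pair, function(ch)
    which(tab$chain != ch & tab$elety %in% c("O", "OXT")))
  res <- lapply(chain_pair, function(ch)
    sort(unique(tab$resid[tab$chain == ch])))
  beta_n <- lapply(res, function(r) stats::setNames(numeric(length(r)), r))
  def_n <- lapply(res, function(r) stats::setNames(numeric(length(r)), r))
  for (f in frames) {
    xyz <- traj$coords[[f]]
    laddered <- lapply(1:2, function(k) {
      given <- .frame_hbonds(xyz, don[[k]], acc_other[[k]],
                             tab$resid[acc_other[[k]]], d_cut, angle_cut)
      taken <- .frame_hbonds(xyz, don_other[[k]], acc_self[[k]],
                             tab$resid[acc_self[[k]]], d_cut, angle_cut)
      unique(c(given$res_d, taken$res_a))
    })
    for (k in 1:2) {
      dh <- .chain_dihedrals(xyz, tab, chain_pair[k])
      defined <- !is.na(dh$phi) & !is.na(dh$psi)
      isb <- .in_beta_region(dh$phi, dh$psi) & dh$resid %in% laddered[[k]]
      beta_n[[k]][as.character(dh$resid[isb & defined])] <-
        beta_n[[k]][as.character(dh$resid[isb & defined])] + 1
      def_n[[k]][as.character(dh$resid[defined])] <-
        def_n[[k]][as.character(dh$resid[defined])] + 1
    }
  }
  per <- do.call(rbind, lapply(1:2, function(k) {
    fr <- ifelse(def_n[[k]] > 0, beta_n[[k]] / def_n[[k]], NA_real_)
    data.frame(chain = chain_pair[k], resid = res[[k]], beta_fraction = fr,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  list(per_residue = per,
       interface = mean(per$beta_fraction, na.rm = TRUE))
}

# pairwise best-fit RMSD matrix over an atom selection
.rmsd_matrix <- function(traj, selection) {
  nf <- n_frames(traj)
  M <- matrix(0, nf, nf)
  coords <- lapply(traj$coords, function(x) x[selection, , drop = FALSE])
  for (i in seq_len(nf - 1)) for (j in seq(i + 1, nf)) {
    M[i, j] <- M[j, i] <- superpose(coords[[i]], coords[[j]])$rmsd
  }
  M
}

#' Quality-threshold clustering of trajectory frames
#'
#' Greedy QT on the pairwise best-fit backbone RMSD: repeatedly take the
#' unassigned frame with the largest number of unassigned neighbors within
#' `cutoff` (ties broken by lowest frame index), form a cluster of it plus
#' those neighbors with that frame as center, and repeat until every frame
#' is assigned.
#'
#' @param traj a `Trajectory`.
#' @param selection integer atom rows used for the metric; default the
#'   backbone (N, CA, C) of the inner chains (all but the first and last).
#' @param cutoff RMSD cutoff, Angstrom (default 3.5).
#' @return a `ClusterAssignment`: list with `labels` (frame -> cluster id),
#'   `centers` (cluster id -> frame index), `populations` (fractions
#'   summing to 1).
#' @export
qt_cluster <- function(traj, selection = NULL, cutoff = 3.5) {
  tab <- traj$atom_table
  if (is.null(selection)) {
    chains <- unique(tab$chain)
    inner <- if (length(chains) > 2) chains[-c(1, length(chains))] else chains
    selection <- atom_selection(tab, chains = inner, elety = c("N", "CA", "C"))
  }
  if (!length(selection)) stop("empty selection")
  nf <- n_frames(traj)
  M <- .rmsd_matrix(traj, selection)
  labels <- rep(NA_integer_, nf)
  centers <- integer(); sizes <- integer()
  cl <- 0L
  while (anyNA(labels)) {
    un <- which(is.na(labels))
    nb <- vapply(un, function(i) sum(M[i, un] <= cutoff), integer(1)) # incl self
    pick <- un[which.max(nb)]
    members <- un[M[pick, un] <= cutoff]
    cl <- cl + 1L
    labels[members] <- cl
    centers[cl] <- pick
    sizes[cl] <- length(members)
  }
  structure(list(labels = labels,
                 centers = stats::setNames(centers, seq_len(cl)),
                 populations = stats::setNames(sizes / nf, seq_len(cl))),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat("QT clustering:", length(x$centers), "clusters; populations:",
      paste(sprintf("%.2f", x$populations), collapse = " "), "\n")
  invisible(x)
}

#' Write a cluster assignment as TSV
#' @param ca a `ClusterAssignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(ca, path) {
  utils::write.table(
    data.frame(frame = seq_along(ca$labels), cluster = ca$labels,
               is_center = seq_along(ca$labels) %in% ca$centers),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-frame best-fit RMSD series
#'
#' @param traj a `Trajectory`.
#' @param reference `"initial"` (frame 1), `"mean"` (average conformation
#'   after aligning every frame on frame 1), or a `FibrilModel`.
#' @param selection integer atom rows (default backbone N, CA, C of all
#'   chains).
#' @return data.frame with `time` and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, reference = "initial", selection = NULL) {
  tab <- traj$atom_table
  if (is.null(selection))
    selection <- atom_selection(tab, elety = c("N", "CA", "C"))
  if (!length(selection)) stop("selection mismatch: no atoms selected")
  coords <- lapply(traj$coords, function(x) x[selection, , drop = FALSE])
  ref <- if (inherits(reference, "FibrilModel")) {
    mt <- model_atom_table(reference)
    key_t <- paste(tab$chain, tab$resid, tab$elety)[selection]
    idx <- match(key_t, paste(mt$chain, mt$resid, mt$elety))
    if (anyNA(idx)) stop("selection mismatch: reference model lacks selected atoms")
    as.matrix(mt[idx, c("x", "y", "z")])
  } else if (identical(reference, "initial")) {
    coords[[1]]
  } else if (identical(reference, "mean")) {
    aligned <- lapply(coords, function(x)
      apply_superposition(superpose(coords[[1]], x), x))
    Reduce(`+`, aligned) / length(aligned)
  } else stop("unknown reference")
  data.frame(time = traj$times,
             rmsd = vapply(coords, function(x) superpose(ref, x)$rmsd,
                           numeric(1)))
}

#' Backbone RMSD between two fibril polymorphs over matched regions
#'
#' Extracts every window of `n_chains` consecutive chains from each model,
#' pairs the two regions gaplessly, superposes backbone (N, CA, C) atoms,
#' and returns the minimum RMSD over all window pairs -- the
#' polymorph-to-polymorph similarity measure used to ask whether a
#' cross-interacting tetramer resembles an experimentally resolved
#' polymorph.
#'
#' @param modelA,modelB `FibrilModel`s.
#' @param regionA,regionB integer `c(start, end)`, equal lengths; every
#'   chain in a window must resolve its region.
#' @param n_chains chains per window (default 4, tetramer vs tetramer).
#' @return minimum backbone RMSD, Angstrom.
#' @export
compare_polymorphs <- function(modelA, regionA, modelB, regionB, n_chains = 4) {
  al <- gapless_align(regionA, regionB)
  winA <- .chain_windows(modelA, n_chains)
  winB <- .chain_windows(modelB, n_chains)
  best <- Inf
  for (wa in winA) for (wb in winB) {
    ca <- do.call(rbind, lapply(modelA$chains[wa], .aligned_backbone,
                                resids = al$residA))
    cb <- do.call(rbind, lapply(modelB$chains[wb], .aligned_backbone,
                                resids = al$residB))
    best <- min(best, superpose(ca, cb)$rmsd)
  }
  best
}

.chain_windows <- function(model, n_chains) {
  n <- length(model$chains)
  if (n < n_chains)
    stop("model supplies only ", n, " chains; ", n_chains, " required")
  lapply(seq_len(n - n_chains + 1), function(s) seq(s, s + n_chains - 1))
}
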
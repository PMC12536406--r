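#' Beta-sheet-like harmonic CA:CA distance restraints
#'
#' Generates one harmonic restraint per aligned residue pair across the
#' heteromeric junction, plus one per residue shared by each homomeric
#' neighboring chain pair. These bias adjacent chains into the in-register
#' cross-beta arrangement that supports inter-strand backbone hydrogen
#' bonding. In the worked case only the aligned regions (9-42 of
#' amyloid-beta vs 4-37 of IAPP) are restrained across the junction, which
#' leaves the disulfide-constrained IAPP N-terminus (residues 1-3) free.
#'
#' @param model a `FibrilModel` with `junction_interface` set (a purely
#'   homomeric stack gets homomeric restraints only).
#' @param junction_align `AlignmentMap` whose `residA` refers to the chain
#'   before the junction and `residB` to the chain after it; ignored for a
#'   homomeric model.
#' @param r0 target CA:CA distance in Angstrom; default 4.8, the canonical
#'   cross-beta inter-strand spacing.
#' @param k force constant, kcal/mol/A^2.
#' @return data.frame of restraints (columns `category`, `chain_i`,
#'   `resid_i`, `atom_i`, `chain_j`, `resid_j`, `atom_j`, `r0`, `k`).
#' @export
beta_sheet_restraints <- function(model, junction_align = NULL, r0 = 4.8, k = 5) {
  stopifnot(r0 > 0, k >= 0)
  nch <- length(model$chains)
  if (nch < 2) {
    warning("single-chain model: no beta-sheet-like restraints generated")
    return(.empty_restraints())
  }
  out <- list()
  jif <- model$junction_interface
  for (i in seq_len(nch - 1)) {
    ci <- model$chains[[i]]; cj <- model$chains[[i + 1]]
    if (!is.na(jif) && i == jif) {
      if (is.null(junction_align))
        stop("junction_align required for a model with a junction interface")
      missA <- setdiff(junction_align$residA, chain_resids(ci))
      missB <- setdiff(junction_align$residB, chain_resids(cj))
      if (length(missA) || length(missB))
        stop("coverage error: aligned resid(s) missing from junction chains: ",
             paste(c(missA, missB), collapse = ","))
      out[[length(out) + 1]] <- data.frame(
        category = "junction", chain_i = ci$id, resid_i = junction_align$residA,
        atom_i = "CA", chain_j = cj$id, resid_j = junction_align$residB,
        atom_j = "CA", r0 = r0, k = k, stringsAsFactors = FALSE)
    } else {
      shared <- intersect(chain_resids(ci), chain_resids(cj))
      out[[length(out) + 1]] <- data.frame(
        category = "beta", chain_i = ci$id, resid_i = shared,
        atom_i = "CA", chain_j = cj$id, resid_j = shared,
        atom_j = "CA", r0 = r0, k = k, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

.empty_restraints <- function() {
  data.frame(category = character(), chain_i = character(),
             resid_i = integer(), atom_i = character(),
             chain_j = character(), resid_j = integer(),
             atom_j = character(), r0 = numeric(), k = numeric(),
             stringsAsFactors = FALSE)
}

#' Graded shape-similarity force-constant schedules
#'
#' Assigns each chain a shape-restraint force constant that decreases
#' monotonically from the outermost chain toward the junction within each
#' molecule, so chains far from the junction are held near their template
#' geometry while junction chains are free to adapt. Six qualitatively
#' distinct monotone decay profiles are provided:
#'
#' 1. linear; 2. linear-steep (quadratic in the normalized distance, lower
#' near the junction); 3. exponential-shallow; 4. exponential-steep;
#' 5. step (outermost chain at `k_max`, all others at `k_min`);
#' 6. uniform-low (all chains at `k_min`).
#'
#' @param variant integer 1-6.
#' @param model `FibrilModel` with `junction_interface` set.
#' @param k_max,k_min force-constant bounds, kcal/mol/A^2,
#'   `0 <= k_min <= k_max`.
#' @return A `ShapeRestraintSchedule`: list with `variant` and
#'   `per_chain_k` (named numeric by chain id).
#' @export
shape_schedule <- function(variant, model, k_max = 5, k_min = 0.5) {
  if (!variant %in% 1:6) stop("variant error: unknown schedule variant ", variant)
  if (is.na(model$junction_interface))
    stop("shape schedules require a model with junction_interface set")
  if (k_min < 0 || k_min > k_max) stop("need 0 <= k_min <= k_max")
  jif <- model$junction_interface
  ids <- names(model$chains)
  n <- length(ids)
  # normalized distance from the junction within each molecule block:
  # 0 at the junction-adjacent chain, 1 at the outermost chain
  dist <- c(rev(seq_len(jif)) - 1L, seq_len(n - jif) - 1L)
  span <- c(rep(max(jif - 1L, 1L), jif), rep(max(n - jif - 1L, 1L), n - jif))
  t <- dist / span
  profile <- switch(variant,
    `1` = t,
    `2` = t^2,
    `3` = (exp(2 * t) - 1) / (exp(2) - 1),
    `4` = (exp(4 * t) - 1) / (exp(4) - 1),
    `5` = as.numeric(dist == span),
    `6` = rep(0, n))
  kk <- k_min + (k_max - k_min) * profile
  structure(list(variant = as.integer(variant),
                 per_chain_k = stats::setNames(kk, ids)),
            class = "ShapeRestraintSchedule")
}

#' Intra-chain shape-similarity restraints
#'
#' For each chain with a positive schedule force constant, restrains all
#' intra-chain CA-CA distances (sequence separation `>= seq_sep_min`,
#' reference distance `<= dist_cutoff`) to the corresponding distance in a
#' reference model. Encoding the chain shape as an internal distance matrix
#' makes the bias invariant to rigid rotation and translation.
#'
#' @param model `FibrilModel` to restrain.
#' @param schedule a `ShapeRestraintSchedule`.
#' @param reference `FibrilModel` with matching chain ids and resids whose
#'   geometry defines the target distances.
#' @param seq_sep_min minimum residue separation (default 2).
#' @param dist_cutoff maximum reference distance to restrain, Angstrom
#'   (default 12).
#' @return data.frame of restraints (same columns as
#'   [beta_sheet_restraints()], category `"shape"`).
#' @export
shape_restraints <- function(model, schedule, reference,
                             seq_sep_min = 2, dist_cutoff = 12) {
  out <- list()
  for (cid in names(model$chains)) {
    kk <- schedule$per_chain_k[[cid]]
    if (is.null(kk) || kk <= 0) next
    if (!cid %in% names(reference$chains))
      stop("coverage error: reference lacks chain ", cid)
    rch <- reference$chains[[cid]]
    resids <- chain_resids(model$chains[[cid]])
    if (!identical(resids, chain_resids(rch)))
      stop("coverage error: resid mismatch between model and reference chain ", cid)
    ca <- chain_coords(rch, resids, "CA")
    dm <- as.matrix(stats::dist(ca))
    idx <- which(upper.tri(dm), arr.ind = TRUE)
    sep <- abs(resids[idx[, 2]] - resids[idx[, 1]])
    keep <- sep >= seq_sep_min & dm[idx] <= dist_cutoff
    idx <- idx[keep, , drop = FALSE]
    if (!nrow(idx)) next
    out[[length(out) + 1]] <- data.frame(
      category = "shape", chain_i = cid, resid_i = resids[idx[, 1]],
      atom_i = "CA", chain_j = cid, resid_j = resids[idx[, 2]],
      atom_j = "CA", r0 = dm[idx], k = kk, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(.empty_restraints())
  do.call(rbind, out)
}

#' Bundle restraints into a RestraintSet
#'
#' @param beta data.frame from [beta_sheet_restraints()].
#' @param shape data.frame from [shape_restraints()] (optional).
#' @param schedule the `ShapeRestraintSchedule` used (optional).
#' @return A `RestraintSet`.
#' @export
restraint_set <- function(beta, shape = .empty_restraints(), schedule = NULL) {
  for (df in list(beta = beta, shape = shape)) {
    key <- paste(df$chain_i, df$resid_i, df$atom_i,
                 df$chain_j, df$resid_j, df$atom_j)
    if (anyDuplicated(key))
      stop("duplicate atom pairs within a restraint category")
  }
  structure(list(beta = beta, shape = shape, schedule = schedule),
            class = "RestraintSet")
}

#' @export
print.RestraintSet <- function(x, ...) {
  cat(sprintf("RestraintSet: %d beta-sheet-like, %d shape-similarity restraints\n",
              nrow(x$beta), nrow(x$shape)))
  if (!is.null(x$schedule))
    cat("  schedule variant", x$schedule$variant, ": k =",
        paste(sprintf("%s:%.2f", names(x$schedule$per_chain_k),
                      x$schedule$per_chain_k), collapse = " "), "\n")
  invisible(x)
}

.restraint_order <- function(df) {
  order(df$category, df$chain_i, df$resid_i, df$chain_j, df$resid_j)
}

#' Write / read a restraint set as TSV
#'
#' Columns: `category`, `chain_i`, `resid_i`, `atom_i`, `chain_j`,
#' `resid_j`, `atom_j`, `r0_A`, `k_kcal_mol_A2`; rows in deterministic
#' (category, chain, resid, partner) order. Round-trips losslessly.
#'
#' @param set a `RestraintSet`.
#' @param path file path.
#' @return `path` ([write_restraints()]) or a `RestraintSet`
#'   ([read_restraints()]).
#' @export
write_restraints <- function(set, path) {
  df <- rbind(set$beta, set$shape)
  df <- df[.restraint_order(df), ]
  names(df)[names(df) == "r0"] <- "r0_A"
  names(df)[names(df) == "k"] <- "k_kcal_mol_A2"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_restraints
#' @export
read_restraints <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t")[[1]]
  want <- c("category", "chain_i", "resid_i", "atom_i",
            "chain_j", "resid_j", "atom_j", "r0_A", "k_kcal_mol_A2")
  if (!identical(hdr, want))
    stop("parse error at line 1: bad header")
  if (length(lines) < 2)
    return(restraint_set(.empty_restraints()))
  rows <- lapply(seq(2, length(lines)), function(i) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) != 9)
      stop("parse error at line ", i, ": expected 9 fields, got ", length(f))
    r0 <- suppressWarnings(as.numeric(f[8])); kk <- suppressWarnings(as.numeric(f[9]))
    ri <- suppressWarnings(as.integer(f[3])); rj <- suppressWarnings(as.integer(f[6]))
    if (anyNA(c(r0, kk, ri, rj)) || r0 <= 0 || kk < 0)
      stop("parse error at line ", i, ": invalid numeric fields")
    data.frame(category = f[1], chain_i = f[2], resid_i = ri, atom_i = f[4],
               chain_j = f[5], resid_j = rj, atom_j = f[7],
               r0 = r0, k = kk, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  restraint_set(beta = df[df$category %in% c("beta", "junction"), , drop = FALSE],
                shape = df[df$category == "shape", , drop = FALSE])
}
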
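#' @title Core domain types: Chain and FibrilModel
#' @name crossbeta-types
#' @description
#' A `Chain` is one peptide of a fibril stack: an ordered set of residues
#' with named atoms and coordinates in Angstrom, plus chain-level chemistry
#' (disulfide bridges, C-terminal amidation). A `FibrilModel` is an ordered
#' list of chains along the fibril axis, optionally carrying the index of a
#' heteromeric junction interface.
NULL

# one- to three-letter amino acid code map
AA123 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
           L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
           S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Reference peptide sequences
#'
#' One-letter sequences of the two peptides the package's worked case
#' models: the 42-residue amyloid-beta peptide and the 37-residue islet
#' amyloid polypeptide (human amylin, disulfide 2-7, amidated C-terminus).
#'
#' @return A character scalar (one-letter codes).
#' @export
abeta42_sequence <- function() "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"

#' @rdname abeta42_sequence
#' @export
iapp_sequence <- function() "KCNTATCATQRLANFLVHSSNNFGAILSSTNVGSNTY"

#' Construct a Chain
#'
#' @param id single-letter chain label.
#' @param atoms data.frame with columns `resid` (1-based integer), `resname`
#'   (3-letter code), `elety` (atom name), `x`, `y`, `z` (Angstrom).
#' @param molecule one of `"ABETA42"`, `"IAPP"`, `"OTHER"`.
#' @param disulfides list of length-2 integer vectors of CYS resid pairs.
#' @param c_term_amidated logical; amidated C-terminus.
#' @param protonation named character vector, resid -> protonation tag
#'   (e.g. `"delta"` for an HSD histidine read from a CHARMM-dialect file).
#' @return An object of class `Chain`.
#' @export
new_chain <- function(id, atoms, molecule = "OTHER",
                      disulfides = list(), c_term_amidated = FALSE,
                      protonation = character()) {
  molecule <- match.arg(molecule, c("ABETA42", "IAPP", "OTHER"))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("resid", "resname", "elety", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  atoms$resid <- as.integer(atoms$resid)
  ch <- structure(
    list(id = as.character(id), molecule = molecule, atoms = atoms,
         disulfides = disulfides, c_term_amidated = isTRUE(c_term_amidated),
         protonation = protonation),
    class = "Chain")
  validate_chain(ch)
  ch
}

#' @rdname new_chain
#' @param chain a `Chain` to validate.
#' @export
validate_chain <- function(chain) {
  resids <- chain_resids(chain)
  if (any(diff(resids) <= 0))
    stop("chain ", chain$id, ": resids must be strictly increasing")
  has_ca <- vapply(resids, function(r)
    any(chain$atoms$resid == r & chain$atoms$elety == "CA"), logical(1))
  if (!all(has_ca))
    stop("malformed chain ", chain$id, ": residue(s) ",
         paste(resids[!has_ca], collapse = ","), " lack a CA atom")
  for (ss in chain$disulfides) {
    ok <- all(ss %in% resids) &&
      all(chain$atoms$resname[match(ss, chain$atoms$resid)] == "CYS")
    if (!ok)
      stop("chain ", chain$id, ": disulfide pair ",
           paste(ss, collapse = "-"), " does not reference existing CYS resids")
  }
  invisible(chain)
}

#' Residue ids of a chain (sorted unique)
#' @param chain a `Chain`.
#' @return integer vector.
#' @export
chain_resids <- function(chain) sort(unique(chain$atoms$resid))

#' One-letter sequence of a chain
#' @param chain a `Chain`.
#' @return character scalar.
#' @export
chain_sequence <- function(chain) {
  resids <- chain_resids(chain)
  rn <- chain$atoms$resname[match(resids, chain$atoms$resid)]
  inv <- stats::setNames(names(AA123), AA123)
  paste(ifelse(rn %in% names(inv), inv[rn], "X"), collapse = "")
}

#' Coordinates of one named atom
#'
#' @param chain a `Chain`.
#' @param resid residue id.
#' @param elety atom name (default `"CA"`).
#' @return numeric xyz of length 3, or `NULL` if absent.
#' @export
atom_xyz <- function(chain, resid, elety = "CA") {
  i <- which(chain$atoms$resid == resid & chain$atoms$elety == elety)
  if (!length(i)) return(NULL)
  unlist(chain$atoms[i[1], c("x", "y", "z")], use.names = FALSE)
}

#' Coordinate matrix for selected atoms of a chain
#'
#' @param chain a `Chain`.
#' @param resids residue ids (default all).
#' @param elety atom names to keep, in the given per-residue order
#'   (default `c("N","CA","C")`, the backbone set used for RMSD).
#' @return numeric matrix, rows ordered by residue then by `elety` order;
#'   missing atoms are dropped.
#' @export
chain_coords <- function(chain, resids = NULL, elety = c("N", "CA", "C")) {
  if (is.null(resids)) resids <- chain_resids(chain)
  a <- chain$atoms[chain$atoms$resid %in% resids & chain$atoms$elety %in% elety, ]
  a <- a[order(match(a$resid, resids), match(a$elety, elety)), ]
  as.matrix(a[, c("x", "y", "z")])
}

#' Construct a FibrilModel
#'
#' Chains are ordered along the fibril axis; the order encodes axial
#' stacking (outermost chain first). `junction_interface = k` means the
#' heteromeric interface lies between `chains[[k]]` and `chains[[k+1]]`.
#'
#' @param chains list of `Chain` objects in stacking order.
#' @param junction_interface integer index or `NA` for a homomeric stack.
#' @param provenance free-text origin note.
#' @return An object of class `FibrilModel`.
#' @export
new_fibril_model <- function(chains, junction_interface = NA, provenance = "") {
  ids <- vapply(chains, function(ch) ch$id, character(1))
  if (anyDuplicated(ids)) stop("chain ids must be unique: ", paste(ids, collapse = ","))
  names(chains) <- ids
  if (!is.na(junction_interface)) {
    k <- as.integer(junction_interface)
    if (k < 1 || k >= length(chains))
      stop("junction_interface out of range")
    if (chains[[k]]$molecule == chains[[k + 1]]$molecule)
      stop("junction_interface must separate different molecules")
    junction_interface <- k
  }
  structure(list(chains = chains,
                 junction_interface = junction_interface,
                 provenance = provenance),
            class = "FibrilModel")
}

#' @export
print.FibrilModel <- function(x, ...) {
  cat("FibrilModel:", length(x$chains), "chains [",
      paste(names(x$chains), collapse = ""), "]\n")
  for (ch in x$chains) {
    r <- range(chain_resids(ch))
    cat(sprintf("  chain %s  %-7s resids %d-%d  (%d atoms)%s%s\n",
                ch$id, ch$molecule, r[1], r[2], nrow(ch$atoms),
                if (length(ch$disulfides)) " SS" else "",
                if (ch$c_term_amidated) " NH2" else ""))
  }
  if (!is.na(x$junction_interface))
    cat("  junction between chains", names(x$chains)[x$junction_interface],
        "and", names(x$chains)[x$junction_interface + 1], "\n")
  invisible(x)
}

#' @export
print.Chain <- function(x, ...) {
  r <- range(chain_resids(x))
  cat(sprintf("Chain %s (%s): resids %d-%d, %d atoms\n",
              x$id, x$molecule, r[1], r[2], nrow(x$atoms)))
  invisible(x)
}

#' Flat atom table of a model
#'
#' One row per atom across all chains, in stacking order; the row order is
#' the coordinate-row convention used by trajectories and the CG engine.
#'
#' @param model a `FibrilModel`.
#' @return data.frame with columns `chain`, `resid`, `resname`, `elety`,
#'   `x`, `y`, `z`.
#' @export
model_atom_table <- function(model) {
  do.call(rbind, lapply(model$chains, function(ch) {
    cbind(data.frame(chain = ch$id, stringsAsFactors = FALSE),
          ch$atoms[order(match(ch$atoms$resid, chain_resids(ch))), ])
  })) -> tab
  rownames(tab) <- NULL
  tab
}

#' Replace all coordinates of a model from a flat coordinate matrix
#'
#' @param model a `FibrilModel`.
#' @param xyz numeric matrix with one row per atom in `model_atom_table`
#'   order.
#' @return the updated `FibrilModel`.
#' @export
set_model_coords <- function(model, xyz) {
  tab <- model_atom_table(model)
  if (nrow(xyz) != nrow(tab)) stop("coordinate row count mismatch")
  off <- 0L
  for (i in seq_along(model$chains)) {
    n <- nrow(model$chains[[i]]$atoms)
    ord <- order(match(model$chains[[i]]$atoms$resid,
                       chain_resids(model$chains[[i]])))
    blk <- xyz[off + seq_len(n), , drop = FALSE]
    model$chains[[i]]$atoms[ord, c("x", "y", "z")] <- blk
    off <- off + n
  }
  model
}

#' Region constants for the worked amyloid-beta / IAPP case
#'
#' Named residue regions (1-based, inclusive) used at the different stages:
#' template alignment 11-42 vs 6-37, junction restraints 9-42 vs 4-37,
#' trajectory analysis 12-42 vs 7-37, and polymorph comparison 18-42 vs
#' 13-37.
#'
#' @param stage one of `"template"`, `"restraint"`, `"analysis"`,
#'   `"polymorph"`.
#' @return list with integer vectors `ABETA42` and `IAPP`, each
#'   `c(start, end)`.
#' @export
region_spec <- function(stage = c("template", "restraint", "analysis", "polymorph")) {
  stage <- match.arg(stage)
  switch(stage,
    template  = list(ABETA42 = c(11L, 42L), IAPP = c(6L, 37L)),
    restraint = list(ABETA42 = c(9L, 42L),  IAPP = c(4L, 37L)),
    analysis  = list(ABETA42 = c(12L, 42L), IAPP = c(7L, 37L)),
    polymorph = list(ABETA42 = c(18L, 42L), IAPP = c(13L, 37L)))
}
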
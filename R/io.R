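#' Read a fibril structure from PDB or mmCIF
#'
#' Parses a structure file into a [new_fibril_model()] object. The CHARMM
#' PDB dialect is accepted: segment ids are used when the chain column is
#' blank, the HSD/HSE/HSP histidine names are normalized to HIS with a
#' recorded protonation tag, and amide cap atoms (`NT`) are kept. Disulfide
#' bridges are detected geometrically (SG-SG under 2.5 A) and a chain whose
#' last residue carries an `NT` cap is flagged C-terminally amidated.
#'
#' @param path file path.
#' @param format `"PDB"`, `"CIF"`, or `"auto"` (by extension).
#' @return A `FibrilModel` with chains in file order. When the chains
#'   change recognized molecule exactly once along the stack, that
#'   interface is recorded as the junction.
#' @export
read_structure <- function(path, format = c("auto", "PDB", "CIF")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "CIF" else "PDB"
  }
  obj <- tryCatch(
    if (format == "CIF") bio3d::read.cif(path, verbose = FALSE)
    else suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("format error reading '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  atoms <- obj$atom
  atoms <- atoms[atoms$resid != "HOH" & atoms$resid != "TIP3", , drop = FALSE]
  if (!nrow(atoms)) stop("format error: no atom records in '", path, "'")
  chain_lab <- atoms$chain
  if (all(is.na(chain_lab)) && "segid" %in% names(atoms))
    chain_lab <- substr(atoms$segid, 1, 1)
  chain_lab[is.na(chain_lab) | chain_lab == ""] <- "A"
  chains <- list()
  for (cid in unique(chain_lab)) {
    a <- atoms[chain_lab == cid, , drop = FALSE]
    prot <- character()
    his <- c(HSD = "delta", HSE = "epsilon", HSP = "both")
    is_his <- a$resid %in% names(his)
    if (any(is_his)) {
      tagged <- unique(a[is_his, c("resno", "resid")])
      prot <- stats::setNames(his[tagged$resid], as.character(tagged$resno))
      a$resid[is_his] <- "HIS"
    }
    df <- data.frame(resid = a$resno, resname = a$resid, elety = a$elety,
                     x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
    df <- df[order(df$resid), ]
    ss <- .detect_disulfides(df)
    last <- max(df$resid)
    amid <- any(df$resid == last & df$elety == "NT")
    chains[[cid]] <- new_chain(cid, df, molecule = .guess_molecule(df),
                               disulfides = ss, c_term_amidated = amid,
                               protonation = prot)
  }
  # a single adjacent change of recognized molecule marks the junction
  mols <- vapply(chains, function(ch) ch$molecule, character(1))
  jif <- NA
  if (length(chains) > 1) {
    flips <- which(mols[-length(mols)] != mols[-1] &
                     mols[-length(mols)] != "OTHER" & mols[-1] != "OTHER")
    if (length(flips) == 1) jif <- flips
  }
  new_fibril_model(chains, junction_interface = jif,
                   provenance = paste0("read from ", basename(path)))
}

.detect_disulfides <- function(df) {
  sg <- df[df$resname == "CYS" & df$elety == "SG", , drop = FALSE]
  out <- list()
  if (nrow(sg) >= 2) {
    for (i in seq_len(nrow(sg) - 1)) for (j in seq(i + 1, nrow(sg))) {
      d <- sqrt(sum((unlist(sg[i, c("x", "y", "z")]) -
                     unlist(sg[j, c("x", "y", "z")]))^2))
      if (d < 2.5) out[[length(out) + 1]] <- c(sg$resid[i], sg$resid[j])
    }
  }
  out
}

.guess_molecule <- function(df) {
  resids <- sort(unique(df$resid))
  rn <- df$resname[match(resids, df$resid)]
  inv <- stats::setNames(names(AA123), AA123)
  seq1 <- paste(ifelse(rn %in% names(inv), inv[rn], "X"), collapse = "")
  if (nchar(seq1) >= 8 && grepl(seq1, abeta42_sequence(), fixed = TRUE)) return("ABETA42")
  if (nchar(seq1) >= 8 && grepl(seq1, iapp_sequence(), fixed = TRUE)) return("IAPP")
  "OTHER"
}

#' Write a fibril model as PDB
#'
#' @param model a `FibrilModel`.
#' @param path output path.
#' @param dialect `"standard"` writes HIS for all histidines; `"charmm"`
#'   writes HSD/HSE/HSP according to the recorded protonation tag (HSD when
#'   untagged) and fills the segment-id column with the chain id.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, dialect = c("standard", "charmm")) {
  dialect <- match.arg(dialect)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.pdb_lines(model, dialect), con)
  writeLines("END", con)
  invisible(path)
}

.pdb_lines <- function(model, dialect = "standard") {
  lines <- character()
  serial <- 0L
  for (ch in model$chains) {
    a <- ch$atoms[order(match(ch$atoms$resid, chain_resids(ch))), ]
    rn <- a$resname
    if (any(rn == "HIS")) {
      if (dialect == "charmm") {
        tag <- ch$protonation[as.character(a$resid)]
        tag[is.na(tag)] <- "delta"
        rn[rn == "HIS"] <- c(delta = "HSD", epsilon = "HSE",
                             both = "HSP")[tag[rn == "HIS"]]
      }
    }
    for (i in seq_len(nrow(a))) {
      serial <- serial + 1L
      nm <- a$elety[i]
      nm <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      lines <- c(lines, sprintf(
        "ATOM  %5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s",
        serial %% 100000L, nm, rn[i], ch$id, a$resid[i],
        a$x[i], a$y[i], a$z[i], 1.0, 0.0,
        if (dialect == "charmm") ch$id else ""))
    }
    lines <- c(lines, "TER")
  }
  lines
}

#' Construct a Trajectory
#'
#' Frames of coordinates over a fixed atom ordering. The atom table follows
#' the [model_atom_table()] row convention so trajectories, models and the
#' CG engine share one indexing.
#'
#' @param atom_table data.frame with columns `chain`, `resid`, `resname`,
#'   `elety` (coordinates columns, if present, are ignored).
#' @param coords list of N x 3 numeric matrices, one per frame.
#' @param times numeric vector of frame times (ps), strictly increasing.
#' @param metadata list (seed, parameters, ...).
#' @return An object of class `Trajectory`.
#' @export
new_trajectory <- function(atom_table, coords, times = seq_along(coords) - 1,
                           metadata = list()) {
  n <- nrow(atom_table)
  if (!all(vapply(coords, nrow, integer(1)) == n))
    stop("all frames must have ", n, " atoms")
  if (length(times) != length(coords) || any(diff(times) <= 0))
    stop("times must match frame count and be strictly increasing")
  structure(list(atom_table = atom_table[, c("chain", "resid", "resname", "elety")],
                 coords = coords, times = as.numeric(times),
                 metadata = metadata),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, t = %.3g..%.3g ps\n",
              length(x$coords), nrow(x$atom_table),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `Trajectory`.
#' @return integer.
#' @export
n_frames <- function(traj) length(traj$coords)

#' Write a trajectory as multi-model PDB
#'
#' @param traj a `Trajectory`.
#' @param topology the `FibrilModel` supplying residue chemistry; its atom
#'   table must match the trajectory's.
#' @param path output path.
#' @param dialect passed to the PDB writer.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, topology, path, dialect = "standard") {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(traj$coords)) {
    m <- set_model_coords(topology, traj$coords[[f]])
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(.pdb_lines(m, dialect), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB as a trajectory
#'
#' @param path file path.
#' @param dt time spacing to assign between frames (ps).
#' @return A `Trajectory`.
#' @export
read_trajectory_pdb <- function(path, dt = 1) {
  obj <- tryCatch(suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
                  error = function(e) stop("format error reading '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  model1 <- read_structure_frame(obj)
  xyz <- obj$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  coords <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  new_trajectory(model_atom_table(model1), coords,
                 times = dt * (seq_len(nrow(xyz)) - 1),
                 metadata = list(source = basename(path)))
}

# internal: FibrilModel from an already-parsed bio3d object (first frame)
read_structure_frame <- function(obj) {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  bio3d::write.pdb(obj, file = tf, xyz = if (is.null(dim(obj$xyz))) obj$xyz else obj$xyz[1, ])
  read_structure(tf, "PDB")
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of one-letter sequences.
#' @export
read_fasta_sequences <- function(path) {
  fa <- bio3d::read.fasta(path)
  out <- apply(fa$ali, 1, function(r) paste(r[r != "-"], collapse = ""))
  stats::setNames(toupper(out), fa$id)
}
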
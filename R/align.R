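#' Gapless residue correspondence between two regions
#'
#' Pairs residue `residA` of one molecule with residue `residB = residA -
#' offset` of the other, with a constant offset over the whole region --
#' the correspondence used both for template superposition (regions 11-42
#' vs 6-37 in the worked amyloid-beta/IAPP case) and for junction
#' restraints (9-42 vs 4-37).
#'
#' @param regionA,regionB integer `c(start, end)`, 1-based inclusive; equal
#'   lengths required.
#' @return An `AlignmentMap`: data.frame with columns `residA`, `residB`
#'   and attribute `offset`.
#' @export
gapless_align <- function(regionA, regionB) {
  lenA <- regionA[2] - regionA[1] + 1L
  lenB <- regionB[2] - regionB[1] + 1L
  if (lenA != lenB)
    stop("alignment-length error: regions have lengths ", lenA, " and ", lenB)
  if (lenA < 1) stop("alignment-length error: empty region")
  map <- data.frame(residA = seq(regionA[1], regionA[2]),
                    residB = seq(regionB[1], regionB[2]))
  attr(map, "offset") <- as.integer(regionA[1] - regionB[1])
  class(map) <- c("AlignmentMap", "data.frame")
  map
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' mobile coordinates onto the reference.
#'
#' @param ref_coords,mob_coords N x 3 matrices, N >= 3, matched row order.
#' @return A `SuperpositionResult`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom) and `n_atoms`. Applying
#'   `mob %*% t(rotation) + translation` (rowwise) yields the fitted
#'   coordinates.
#' @export
superpose <- function(ref_coords, mob_coords) {
  ref <- as.matrix(ref_coords); mob <- as.matrix(mob_coords)
  if (nrow(ref) != nrow(mob) || ncol(ref) != 3 || ncol(mob) != 3 || nrow(ref) < 3)
    stop("input error: need matched N x 3 coordinate sets with N >= 3")
  cr <- colMeans(ref); cm <- colMeans(mob)
  P <- sweep(mob, 2, cm); Q <- sweep(ref, 2, cr)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)          # fitted = mob %*% t(R) + t
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cr - R %*% cm),
                 rmsd = rmsd, n_atoms = nrow(ref)),
            class = "SuperpositionResult")
}

#' Apply a superposition to coordinates
#' @param sup a `SuperpositionResult`.
#' @param coords N x 3 matrix.
#' @return transformed N x 3 matrix.
#' @export
apply_superposition <- function(sup, coords) {
  sweep(as.matrix(coords) %*% t(sup$rotation), 2, sup$translation, "+")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("Superposition over %d atoms: RMSD %.4f A\n", x$n_atoms, x$rmsd))
  invisible(x)
}

# backbone coordinate block for one chain over an aligned region
.aligned_backbone <- function(chain, resids, atoms = c("N", "CA", "C")) {
  missing <- resids[!resids %in% chain_resids(chain)]
  if (length(missing))
    stop("coverage error: chain ", chain$id, " lacks resid(s) ",
         paste(missing, collapse = ","))
  chain_coords(chain, resids, atoms)
}

#' Rank candidate template pairs by backbone RMSD
#'
#' Stage A of the pipeline: candidate conformers of molecule A are paired
#' with candidates of molecule B; pairs failing the resolved-range filters
#' (the worked case requires all of 1-42 resolved for amyloid-beta and at
#' least 6-37 for IAPP) are flagged and excluded from ranking; passing
#' pairs are superposed over the gapless alignment region on backbone
#' (N, CA, C) atoms and sorted by RMSD ascending, ties kept in input order.
#'
#' @param candA,candB lists of single-conformer `FibrilModel`s (the first
#'   chain of each is the monomer compared); list names are used as ids.
#' @param align an `AlignmentMap` whose `residA`/`residB` refer to
#'   molecules A/B.
#' @param resolved_requirementA,resolved_requirementB integer `c(start,
#'   end)` ranges that must be fully resolved for a candidate to pass.
#' @param backbone_atoms atom names used for RMSD (default N, CA, C; add
#'   `"O"` if wanted).
#' @param stack if `TRUE`, superpose all chains of each candidate as one
#'   assembly rather than the first chain only.
#' @return A `TemplateRanking` data.frame with columns `idA`, `idB`,
#'   `backbone_rmsd`, `passed_filters`; passing rows sorted by RMSD. An
#'   attribute `warning` is set when no pair passes.
#' @export
rank_template_pairs <- function(candA, candB, align,
                                resolved_requirementA, resolved_requirementB,
                                backbone_atoms = c("N", "CA", "C"),
                                stack = FALSE) {
  idsA <- names(candA) %||% paste0("A", seq_along(candA))
  idsB <- names(candB) %||% paste0("B", seq_along(candB))
  okA <- vapply(candA, .resolved, logical(1), req = resolved_requirementA)
  okB <- vapply(candB, .resolved, logical(1), req = resolved_requirementB)
  rows <- expand.grid(ia = seq_along(candA), ib = seq_along(candB))
  rows <- rows[order(rows$ia, rows$ib), ]
  res <- data.frame(idA = idsA[rows$ia], idB = idsB[rows$ib],
                    backbone_rmsd = NA_real_,
                    passed_filters = okA[rows$ia] & okB[rows$ib],
                    stringsAsFactors = FALSE)
  for (r in which(res$passed_filters)) {
    mA <- candA[[rows$ia[r]]]; mB <- candB[[rows$ib[r]]]
    chainsA <- if (stack) mA$chains else mA$chains[1]
    chainsB <- if (stack) mB$chains else mB$chains[1]
    if (length(chainsA) != length(chainsB) && stack)
      stop("stack superposition requires equal chain counts")
    ca <- do.call(rbind, lapply(chainsA, .aligned_backbone,
                                resids = align$residA, atoms = backbone_atoms))
    cb <- do.call(rbind, lapply(chainsB, .aligned_backbone,
                                resids = align$residB, atoms = backbone_atoms))
    res$backbone_rmsd[r] <- superpose(ca, cb)$rmsd
  }
  pass <- res[res$passed_filters, ]
  pass <- pass[order(pass$backbone_rmsd), ]
  out <- rbind(pass, res[!res$passed_filters, ])
  rownames(out) <- NULL
  if (!nrow(pass)) attr(out, "warning") <- "no candidate pair passed the resolved-range filters"
  class(out) <- c("TemplateRanking", "data.frame")
  out
}

.resolved <- function(model, req) {
  all(seq(req[1], req[2]) %in% chain_resids(model$chains[[1]]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a template ranking as TSV
#' @param ranking a `TemplateRanking`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
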
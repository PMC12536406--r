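#' Graft residues from a donor chain onto a target chain
#'
#' Copies the residues of `resid_range` from the donor into the target
#' after rigidly superposing the donor onto the target over the shared
#' `anchor_resids` (backbone N, CA, C atoms; CA only if the backbone is
#' incomplete). Used to complete unresolved termini, e.g. appending IAPP
#' residues 1-5 from a solution NMR structure onto a cryo-EM fibril chain
#' resolved from residue 6.
#'
#' Pre-existing target atoms are never moved.
#'
#' @param target `Chain` to complete.
#' @param donor `Chain` providing the missing residues.
#' @param resid_range integer `c(start, end)` of residues to copy; `NULL`
#'   or zero length grafts nothing.
#' @param anchor_resids residues present in both chains used for the
#'   superposition (at least 1; >= 2 recommended).
#' @return the completed `Chain`.
#' @export
graft_residues <- function(target, donor, resid_range, anchor_resids) {
  if (is.null(resid_range) || !length(resid_range)) return(target)
  rng <- seq(resid_range[1], resid_range[2])
  t_res <- chain_resids(target); d_res <- chain_resids(donor)
  clash <- intersect(rng, t_res)
  if (length(clash))
    stop("conflict error: resid(s) ", paste(clash, collapse = ","),
         " already present in target chain ", target$id)
  if (!all(rng %in% d_res))
    stop("donor chain ", donor$id, " lacks resid(s) ",
         paste(setdiff(rng, d_res), collapse = ","))
  missing_anchor <- anchor_resids[!(anchor_resids %in% t_res & anchor_resids %in% d_res)]
  if (length(missing_anchor) || !length(anchor_resids))
    stop("anchor error: anchor resid(s) ",
         paste(missing_anchor, collapse = ","), " not present in both chains")

  atoms <- c("N", "CA", "C")
  ref <- chain_coords(target, anchor_resids, atoms)
  mob <- chain_coords(donor, anchor_resids, atoms)
  if (nrow(ref) != nrow(mob) || nrow(ref) < 3) {   # fall back to CA anchors
    ref <- chain_coords(target, anchor_resids, "CA")
    mob <- chain_coords(donor, anchor_resids, "CA")
    if (nrow(ref) < 3)
      stop("anchor error: need at least 3 matched anchor atoms")
  }
  sup <- superpose(ref, mob)

  add <- donor$atoms[donor$atoms$resid %in% rng, , drop = FALSE]
  add[, c("x", "y", "z")] <- apply_superposition(sup, as.matrix(add[, c("x", "y", "z")]))
  merged <- rbind(target$atoms, add)
  merged <- merged[order(merged$resid), ]
  new_chain(target$id, merged, molecule = target$molecule,
            disulfides = target$disulfides,
            c_term_amidated = target$c_term_amidated,
            protonation = target$protonation)
}
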
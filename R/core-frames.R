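# Frame recentring and leaflet assignment. The membrane normal is fixed to
# the z axis throughout the package (planar bilayers only).

#' Recentre frames on a selection's centre of mass
#'
#' Translates every frame along z so that the mass-weighted centre of the
#' selected atoms sits at z = 0; x and y are untouched. All depth-resolved
#' observables (density, potential, pressure, permeation) assume a
#' recentred trajectory so that the bilayer midplane is the origin.
#'
#' @param trajectory a [trajectory()]
#' @param selection atom indices to centre on; defaults to all lipid atoms
#' @return a recentred [trajectory()]
#' @export
recenter_frames <- function(trajectory, selection = lipid_atoms(trajectory)) {
  if (length(selection) == 0L) stop("recentring selection is empty")
  m <- trajectory$topology$atoms$mass[selection]
  out <- trajectory
  for (k in seq_len(n_frames(trajectory))) {
    comz <- sum(m * trajectory$coords[selection, 3L, k]) / sum(m)
    out$coords[, 3L, k] <- trajectory$coords[, 3L, k] - comz
  }
  out
}

#' Assign lipids to leaflets
#'
#' In a recentred, non-porated planar bilayer the sign of a lipid's
#' reference atom z is an exact leaflet label: phospholipids use their
#' `headgroup_ref` atom, sterols their `hydroxyl_ref`. The assignment is
#' computed per frame; the trajectory-level label is the modal (majority)
#' assignment, and molecules whose per-frame label ever changes are
#' reported as flip-flop candidates. Waters and ions are never assigned.
#'
#' @param trajectory a recentred [trajectory()]
#' @return an object of class `"leaflet_assignment"`: list with `leaflet`
#'   (named character vector, molecule id -> `"outer"`/`"inner"`),
#'   `per_frame` (molecule x frame matrix), `flip_flop` (molecule ids whose
#'   assignment changed between frames) and `counts`.
#' @export
assign_leaflets <- function(trajectory) {
  at <- trajectory$topology$atoms
  lip <- !(at$species %in% .SOLVENT_SPECIES)
  mols <- unique(at$molecule_id[lip])
  ref_idx <- vapply(mols, function(m) {
    rows <- which(at$molecule_id == m)
    r <- rows[at$role[rows] %in% c("headgroup_ref", "hydroxyl_ref")]
    if (!length(r))
      stop("lipid molecule ", m, " (", at$species[rows[1L]],
           ") has no headgroup_ref/hydroxyl_ref reference atom")
    r[1L]
  }, integer(1L))
  nf <- n_frames(trajectory)
  per_frame <- matrix("", length(mols), nf,
                      dimnames = list(as.character(mols), NULL))
  for (k in seq_len(nf))
    per_frame[, k] <- ifelse(trajectory$coords[ref_idx, 3L, k] > 0,
                             "outer", "inner")
  modal <- apply(per_frame, 1L, function(v) names(which.max(table(v))))
  flip <- rownames(per_frame)[apply(per_frame, 1L, function(v) length(unique(v)) > 1L)]
  structure(list(leaflet = modal, per_frame = per_frame,
                 flip_flop = as.integer(flip), midplane_z = 0,
                 counts = c(outer = sum(modal == "outer"),
                            inner = sum(modal == "inner"))),
            class = "leaflet_assignment")
}

#' @export
print.leaflet_assignment <- function(x, ...) {
  cat("Leaflet assignment:", x$counts[["outer"]], "outer /",
      x$counts[["inner"]], "inner lipids")
  if (length(x$flip_flop))
    cat(";", length(x$flip_flop), "flip-flop candidate(s)")
  cat("\n")
  invisible(x)
}

#' Molecules of a leaflet
#' @param leaflets a [assign_leaflets()] result
#' @param side `"outer"` or `"inner"`
#' @return integer molecule ids
#' @export
leaflet_molecules <- function(leaflets, side) {
  as.integer(names(leaflets$leaflet)[leaflets$leaflet == side])
}
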
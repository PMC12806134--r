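#' Atom roles recognised by the analysis
#'
#' Each atom in a [topology()] carries a `role` that tells the observables
#' which atoms to use: `headgroup_ref` (phosphate-level reference of a
#' phospholipid), `ester_ref` (glycerol/ester region), `tail_carbon`
#' (acyl-chain carbon; `role_index` gives the carbon number, counted from 2
#' at the first chain carbon), `hydroxyl_ref` (sterol hydroxyl),
#' `water_oxygen` (single-site water) and `other`.
#'
#' @keywords internal
.ATOM_ROLES <- c("headgroup_ref", "ester_ref", "tail_carbon",
                 "hydroxyl_ref", "water_oxygen", "other")

# species names reserved for non-lipids
.SOLVENT_SPECIES <- c("WAT", "CAT", "ANI")

#' Build a molecular topology
#'
#' A topology binds per-atom metadata (mass, partial charge, role) to
#' per-species metadata (sterol flag, acyl-chain atom sequences, headgroup
#' charge). It is deliberately engine-agnostic: no force-field files are
#' parsed, the manifest is plain structured text (see [read_topology()]).
#'
#' @param atoms data.frame with columns `atom_id` (integer), `name`,
#'   `species`, `molecule_id` (integer), `mass` (amu), `charge` (e),
#'   `role` (one of the recognised roles) and optionally `role_index`
#'   (carbon number for `tail_carbon` atoms, `NA` otherwise).
#' @param species_meta named list, one entry per lipid species, each a list
#'   with elements `is_sterol` (logical), `chains` (list of character
#'   vectors of chain atom names, in chain order) and `headgroup_charge`
#'   (e). Water and ion species (`WAT`, `CAT`, `ANI`) need no entry.
#' @return An object of class `"topology"`.
#' @export
topology <- function(atoms, species_meta = list()) {
  stopifnot(is.data.frame(atoms))
  needed <- c("atom_id", "name", "species", "molecule_id", "mass", "charge", "role")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    stop("topology atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!"role_index" %in% names(atoms)) atoms$role_index <- NA_integer_
  if (any(!atoms$role %in% .ATOM_ROLES))
    stop("unknown atom role(s): ",
         paste(unique(setdiff(atoms$role, .ATOM_ROLES)), collapse = ", "))
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("all atom masses must be positive")
  # tail carbon indices must run consecutively from 2 within each chain
  tc <- atoms[atoms$role == "tail_carbon", ]
  if (nrow(tc) && any(is.na(tc$role_index)))
    stop("tail_carbon atoms need a role_index (carbon number)")
  molecules <- tapply(atoms$species, atoms$molecule_id, function(s) s[[1L]])
  structure(list(atoms = atoms,
                 molecules = molecules,
                 species_meta = species_meta),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  sp <- table(unlist(x$molecules))
  cat("Topology:", nrow(x$atoms), "atoms,", length(x$molecules), "molecules\n")
  cat("  species:", paste(sprintf("%s (%d)", names(sp), sp), collapse = ", "), "\n")
  invisible(x)
}

#' Number of atoms in a topology or trajectory
#' @param x a `topology` or `trajectory`
#' @return integer atom count
#' @export
n_atoms <- function(x) {
  if (inherits(x, "trajectory")) nrow(x$topology$atoms)
  else if (inherits(x, "topology")) nrow(x$atoms)
  else stop("n_atoms() needs a topology or trajectory")
}

#' Build a trajectory
#'
#' A trajectory is an ordered set of frames bound to one [topology()].
#' Coordinates are stored as an `n_atoms x 3 x n_frames` array in nm; the
#' per-frame box is `n_frames x 3` (Lx, Ly, Lz in nm). Frame times are
#' `time0 + (0:(n-1)) * dt` ps; the frame spacing `dt` is a required input
#' and never inferred.
#'
#' @param topology a [topology()]
#' @param coords numeric array `n_atoms x 3 x n_frames` (a plain
#'   `n_atoms x 3` matrix is accepted for a single frame), nm
#' @param box numeric matrix `n_frames x 3` or length-3 vector recycled to
#'   all frames, nm
#' @param dt frame spacing, ps
#' @param time0 time of the first frame, ps
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(topology, coords, box, dt = 1, time0 = 0) {
  stopifnot(inherits(topology, "topology"))
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3L, 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2L] == 3L)
  if (dim(coords)[1L] != nrow(topology$atoms))
    stop("coordinate count (", dim(coords)[1L],
         ") does not match topology atom count (", nrow(topology$atoms), ")")
  nf <- dim(coords)[3L]
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3L, byrow = TRUE)
  stopifnot(nrow(box) == nf, ncol(box) == 3L)
  if (any(box <= 0)) stop("box lengths must be positive")
  if (!is.finite(dt) || dt <= 0) stop("dt must be a positive frame spacing (ps)")
  structure(list(topology = topology, coords = coords, box = box,
                 dt = dt, time = time0 + (seq_len(nf) - 1) * dt),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", dim(x$coords)[3L], "frame(s),", n_atoms(x), "atoms, dt =",
      x$dt, "ps\n")
  cat("  box (frame 1):", paste(sprintf("%.3f", x$box[1L, ]), collapse = " x "),
      "nm\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory a `trajectory`
#' @return integer frame count
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3L]

#' Select atom indices by species, role or leaflet
#'
#' @param trajectory a `trajectory`
#' @param species optional character vector of species to keep
#' @param role optional character vector of roles to keep
#' @param leaflet optional `"outer"` or `"inner"`; requires `leaflets`
#' @param leaflets a [assign_leaflets()] result, needed when `leaflet` is set
#' @return integer vector of atom indices
#' @export
select_atoms <- function(trajectory, species = NULL, role = NULL,
                         leaflet = NULL, leaflets = NULL) {
  at <- trajectory$topology$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(species)) keep <- keep & at$species %in% species
  if (!is.null(role)) keep <- keep & at$role %in% role
  if (!is.null(leaflet)) {
    if (is.null(leaflets)) stop("leaflet selection needs a leaflet assignment")
    mol_leaf <- leaflets$leaflet[as.character(at$molecule_id)]
    keep <- keep & !is.na(mol_leaf) & mol_leaf == leaflet
  }
  which(keep)
}

#' Indices of lipid atoms (everything that is not water or ion)
#' @param trajectory a `trajectory`
#' @return integer vector of atom indices
#' @export
lipid_atoms <- function(trajectory) {
  at <- trajectory$topology$atoms
  which(!at$species %in% .SOLVENT_SPECIES)
}
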
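# Coordinate file I/O: fixed-column GRO (nm) and PDB (Angstrom at the
# boundary, converted to nm on read). Velocities in GRO files are ignored.

# default masses for a provisional topology built from atom names
.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   P = 30.974, S = 32.06)

.guess_mass <- function(name) {
  el <- toupper(substr(gsub("^[0-9]+", "", name), 1L, 1L))
  m <- .ELEMENT_MASS[el]
  ifelse(is.na(m), 12.011, m)
}

.provisional_topology <- function(name, resname, resid) {
  species <- resname
  role <- ifelse(species == "WAT" & grepl("^O", name), "water_oxygen", "other")
  topology(data.frame(
    atom_id = seq_along(name), name = name, species = species,
    molecule_id = as.integer(resid), mass = .guess_mass(name),
    charge = 0, role = role, stringsAsFactors = FALSE))
}

#' Read a multi-frame coordinate file
#'
#' Reads fixed-column GRO (possibly concatenated frames) or PDB
#' (ATOM/HETATM records, CRYST1 box, MODEL/ENDMDL frame delimiters; single
#' implicit model accepted). PDB coordinates (Angstrom) are converted to nm.
#' When no `topology` is supplied a provisional one is built from residue
#' and atom names with element-guessed masses, zero charges and `other`
#' roles; supply the real manifest for any charge- or mass-weighted
#' analysis.
#'
#' @param path file path
#' @param dialect `"gro"` or `"pdb"`; default guessed from the extension
#' @param topology optional [topology()] to bind (atom count must match)
#' @param dt frame spacing in ps assigned to the trajectory
#' @return a [trajectory()]
#' @export
read_coordinates <- function(path, dialect = c("auto", "gro", "pdb"),
                             topology = NULL, dt = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto")
    dialect <- if (tolower(tools::file_ext(path)) == "pdb") "pdb" else "gro"
  parsed <- if (dialect == "gro") .read_gro(path) else .read_pdb(path)
  nf <- length(parsed$frames)
  if (nf == 0L) stop("no frames found in ", path)
  na <- nrow(parsed$frames[[1L]]$xyz)
  for (k in seq_len(nf))
    if (nrow(parsed$frames[[k]]$xyz) != na)
      stop("atom count varies across frames (frame ", k, " has ",
           nrow(parsed$frames[[k]]$xyz), ", expected ", na, ")")
  coords <- array(NA_real_, c(na, 3L, nf))
  box <- matrix(NA_real_, nf, 3L)
  for (k in seq_len(nf)) {
    coords[, , k] <- parsed$frames[[k]]$xyz
    box[k, ] <- parsed$frames[[k]]$box
  }
  if (is.null(topology))
    topology <- .provisional_topology(parsed$name, parsed$resname, parsed$resid)
  trajectory(topology, coords, box, dt = dt, time0 = parsed$time0)
}

.read_gro <- function(path) {
  lines <- readLines(path)
  frames <- list(); i <- 1L; ln <- length(lines)
  name <- resname <- resid <- NULL
  time0 <- 0
  first <- TRUE
  while (i <= ln) {
    if (!nzchar(trimws(lines[i])) && i == ln) break
    title <- lines[i]
    if (first) {
      tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1L]]
      if (length(tm) == 2L) time0 <- as.numeric(tm[2L])
    }
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat)) stop("GRO parse error at line ", i + 1L,
                         ": expected atom count, got '", lines[i + 1L], "'")
    if (i + 1L + nat + 1L > ln) stop("GRO file truncated: missing box line")
    atom_lines <- lines[(i + 2L):(i + 1L + nat)]
    bad <- which(nchar(atom_lines) < 44L)
    if (length(bad)) stop("GRO parse error at line ", i + 1L + bad[1L],
                          ": fixed-width atom line too short")
    xyz <- suppressWarnings(
      cbind(as.numeric(substr(atom_lines, 21L, 28L)),
            as.numeric(substr(atom_lines, 29L, 36L)),
            as.numeric(substr(atom_lines, 37L, 44L))))
    if (anyNA(xyz)) {
      bad <- which(is.na(rowSums(xyz)))[1L]
      stop("GRO parse error at line ", i + 1L + bad,
           ": malformed coordinate field")
    }
    boxline <- suppressWarnings(
      as.numeric(strsplit(trimws(lines[i + 2L + nat]), "\\s+")[[1L]]))
    if (length(boxline) < 3L || anyNA(boxline[1:3]))
      stop("GRO parse error at line ", i + 2L + nat, ": malformed box line")
    if (first) {
      name <- trimws(substr(atom_lines, 11L, 15L))
      resname <- trimws(substr(atom_lines, 6L, 10L))
      resid <- as.integer(substr(atom_lines, 1L, 5L))
      first <- FALSE
    }
    frames[[length(frames) + 1L]] <- list(xyz = xyz, box = boxline[1:3])
    i <- i + nat + 3L
    while (i <= ln && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  list(frames = frames, name = name, resname = resname, resid = resid,
       time0 = time0)
}

# PDB reading goes through bio3d (the field's standard R reader); the box is
# taken from CRYST1 and everything converted Angstrom -> nm.
.read_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  cr <- grep("^CRYST1", readLines(path), value = TRUE)
  if (!length(cr)) stop("PDB file has no CRYST1 record (missing box)")
  box_a <- as.numeric(c(substr(cr[1L], 7L, 15L), substr(cr[1L], 16L, 24L),
                        substr(cr[1L], 25L, 33L)))
  if (anyNA(box_a)) stop("malformed CRYST1 record")
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3L
  frames <- lapply(seq_len(nf), function(k) {
    m <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE) / 10
    list(xyz = m, box = box_a / 10)
  })
  list(frames = frames, name = pdb$atom$elety, resname = pdb$atom$resid,
       resid = as.integer(pdb$atom$resno), time0 = 0)
}

#' Write a trajectory to a coordinate file
#'
#' GRO output is fixed-column with positions to 3 decimals in nm; PDB
#' output wraps every frame in a MODEL/ENDMDL pair (coordinates in
#' Angstrom, box as CRYST1). Both forms round-trip through
#' [read_coordinates()].
#'
#' @param trajectory a non-empty [trajectory()]
#' @param path output path
#' @param dialect `"gro"` or `"pdb"`
#' @return `path`, invisibly
#' @export
write_coordinates <- function(trajectory, path, dialect = c("gro", "pdb")) {
  dialect <- match.arg(dialect)
  if (!inherits(trajectory, "trajectory") || n_frames(trajectory) < 1L ||
      n_atoms(trajectory) < 1L)
    stop("cannot write an empty trajectory")
  at <- trajectory$topology$atoms
  nf <- n_frames(trajectory)
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "gro") {
    for (k in seq_len(nf)) {
      xyz <- trajectory$coords[, , k]
      writeLines(sprintf("asymem frame t= %.4f", trajectory$time[k]), con)
      writeLines(sprintf("%5d", nrow(at)), con)
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         at$molecule_id %% 100000L,
                         substr(at$species, 1L, 5L),
                         substr(at$name, 1L, 5L),
                         at$atom_id %% 100000L,
                         xyz[, 1L], xyz[, 2L], xyz[, 3L]), con)
      writeLines(sprintf("%10.5f%10.5f%10.5f", trajectory$box[k, 1L],
                         trajectory$box[k, 2L], trajectory$box[k, 3L]), con)
    }
  } else {
    b <- trajectory$box[1L, ] * 10
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       b[1L], b[2L], b[3L], 90, 90, 90), con)
    for (k in seq_len(nf)) {
      xyz <- trajectory$coords[, , k] * 10
      writeLines(sprintf("MODEL     %4d", k), con)
      writeLines(sprintf(
        "ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00",
        at$atom_id %% 100000L, substr(at$name, 1L, 4L),
        substr(at$species, 1L, 4L), at$molecule_id %% 10000L,
        xyz[, 1L], xyz[, 2L], xyz[, 3L]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}

#' Read / write a topology manifest
#'
#' The manifest is a YAML sidecar, engine-agnostic by design: per-species
#' atom templates (name, mass, charge, role, carbon index) plus species
#' metadata, and an ordered molecule list `(species, count)` from which the
#' per-atom table is expanded in file order.
#'
#' @param path manifest path
#' @return [read_topology()]: a [topology()].
#' @export
read_topology <- function(path) {
  m <- yaml::read_yaml(path)
  if (is.null(m$species) || is.null(m$molecules))
    stop("manifest needs 'species' and 'molecules' blocks")
  species_meta <- lapply(m$species, function(s) {
    list(is_sterol = isTRUE(s$is_sterol),
         chains = lapply(s$chains %||% list(), as.character),
         headgroup_charge = s$headgroup_charge %||% 0)
  })
  rows <- list(); mol_id <- 0L; atom_id <- 0L
  for (blk in m$molecules) {
    tmpl <- m$species[[blk$species]]$atoms
    if (is.null(tmpl)) stop("species '", blk$species, "' has no atom template")
    for (r in seq_len(blk$count)) {
      mol_id <- mol_id + 1L
      for (a in tmpl) {
        atom_id <- atom_id + 1L
        rows[[atom_id]] <- data.frame(
          atom_id = atom_id, name = a$name, species = blk$species,
          molecule_id = mol_id, mass = a$mass, charge = a$charge %||% 0,
          role = a$role %||% "other",
          role_index = as.integer(a$carbon %||% NA),
          stringsAsFactors = FALSE)
      }
    }
  }
  topology(do.call(rbind, rows),
           species_meta = species_meta[!names(species_meta) %in% .SOLVENT_SPECIES])
}

#' @rdname read_topology
#' @param topology a [topology()] whose molecules are grouped by species in
#'   contiguous runs (the generator's ordering)
#' @export
write_topology <- function(topology, path) {
  at <- topology$atoms
  mol_species <- unlist(topology$molecules[as.character(sort(unique(at$molecule_id)))])
  runs <- rle(as.character(mol_species))
  species_blocks <- list()
  for (sp in unique(at$species)) {
    first_mol <- at$molecule_id[at$species == sp][1L]
    tmpl <- at[at$molecule_id == first_mol, ]
    meta <- topology$species_meta[[sp]]
    species_blocks[[sp]] <- list(
      is_sterol = isTRUE(meta$is_sterol),
      headgroup_charge = meta$headgroup_charge %||% 0,
      chains = meta$chains %||% list(),
      atoms = lapply(seq_len(nrow(tmpl)), function(i) {
        a <- as.list(tmpl[i, c("name", "mass", "charge", "role")])
        if (!is.na(tmpl$role_index[i])) a$carbon <- tmpl$role_index[i]
        a
      }))
  }
  molecules <- lapply(seq_along(runs$lengths), function(i)
    list(species = runs$values[i], count = runs$lengths[i]))
  yaml::write_yaml(list(species = species_blocks, molecules = molecules), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
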
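# Seeded synthetic bilayer trajectories with analytic ground truth.
#
# The generator emulates the equilibrium *ensemble statistics* of a planar
# two-leaflet bilayer in water -- headgroup density peaks at +/- d/2, acyl
# chains with prescribed per-carbon order parameters, molecular tilt with a
# prescribed modal angle, AR(1) box-area wander, charge sheets with a
# closed-form potential, and rare single-file water crossings -- without any
# dynamics or force field. Every observable the package computes can
# therefore be checked against a known truth.

# species atom templates: sat = 16-carbon chain, unsat = 18-carbon chain
.PL_SPECIES <- list(
  POPC = list(chains = c(16L, 18L), headgroup_charge = 0),
  PSM  = list(chains = c(16L, 16L), headgroup_charge = 0),
  POPE = list(chains = c(16L, 18L), headgroup_charge = 0),
  POPS = list(chains = c(16L, 18L), headgroup_charge = -1))

.CHOL_TAIL_N <- 8L   # pseudo-atoms along the sterol axis
.HEAD_MASS <- 180.0
.TAIL_MASS <- 14.0
.CHORD_NM <- 0.25    # carbon i-1 -> i+1 chord length

.chain_atom_names <- function(nc, chain_idx) {
  suff <- c("A", "B")[chain_idx]
  paste0("C", 2:nc, suff)
}

.species_template <- function(sp) {
  if (sp == "CHOL") {
    data.frame(
      name = c("O3", paste0("C", 2:(1L + .CHOL_TAIL_N))),
      mass = c(17.0, rep(45.0, .CHOL_TAIL_N)),
      charge = 0,
      role = c("hydroxyl_ref", rep("tail_carbon", .CHOL_TAIL_N)),
      role_index = c(NA_integer_, 2:(1L + .CHOL_TAIL_N)),
      stringsAsFactors = FALSE)
  } else {
    meta <- .PL_SPECIES[[sp]]
    if (is.null(meta)) stop("unknown lipid species: ", sp)
    rows <- data.frame(name = "P", mass = .HEAD_MASS,
                       charge = meta$headgroup_charge,
                       role = "headgroup_ref", role_index = NA_integer_,
                       stringsAsFactors = FALSE)
    for (ci in seq_along(meta$chains)) {
      nc <- meta$chains[ci]
      rows <- rbind(rows, data.frame(
        name = .chain_atom_names(nc, ci), mass = .TAIL_MASS, charge = 0,
        role = "tail_carbon", role_index = 2:nc, stringsAsFactors = FALSE))
    }
    rows
  }
}

.species_meta_for <- function(species) {
  meta <- list()
  for (sp in species) {
    if (sp == "CHOL") {
      meta$CHOL <- list(is_sterol = TRUE, chains = list(paste0("C", 2:(1L + .CHOL_TAIL_N))),
                        headgroup_charge = 0)
    } else {
      m <- .PL_SPECIES[[sp]]
      meta[[sp]] <- list(
        is_sterol = FALSE,
        chains = lapply(seq_along(m$chains),
                        function(ci) .chain_atom_names(m$chains[ci], ci)),
        headgroup_charge = m$headgroup_charge)
    }
  }
  meta
}

#' Specify a synthetic bilayer
#'
#' Collects the controllable quantities of the generator. Phospholipid
#' fractions are given per leaflet *among phospholipids*; the cholesterol
#' fraction is applied on top, so the full leaflet composition is
#' `c(phospholipids * (1 - chol), CHOL = chol)`. Default compositions follow
#' the plasma-membrane convention: the outer leaflet is PC/SM, the inner
#' leaflet PE/PC/PS; tails are one saturated 16-carbon and one unsaturated
#' 18-carbon chain (SM: two saturated 16-carbon chains).
#'
#' @param n_lipids named integer vector `c(outer=, inner=)`: lipids per leaflet
#' @param composition list with `outer`/`inner` named phospholipid fraction
#'   vectors (each summing to 1)
#' @param chol_fraction named vector `c(outer=, inner=)` of CHOL mole fractions
#' @param apl area per lipid by species, nm^2
#' @param headgroup_peak_z headgroup density peak position, nm (> 0); the
#'   ground-truth headgroup-peak thickness is `2 * headgroup_peak_z`
#' @param headgroup_sigma headgroup peak width, nm
#' @param target_scd list of per-carbon order-parameter targets keyed by
#'   chain length (`"16"`, `"18"`); each a vector over carbons `2..n`, values
#'   in `[-0.5, 1]`. Carbons `3..n-1` are recoverable (the chord convention
#'   needs both neighbours).
#' @param tilt_mode_deg named vector of modal tilt angles (degrees, angle to
#'   the bilayer *plane*); key `default` covers unlisted species
#' @param tilt_sd_deg spread of the per-molecule tilt draw, degrees
#' @param water_count single-site waters filling `|z| > headgroup_peak_z`
#' @param charge_profile data.frame `z` (nm), `sigma` (e/nm^2): charge sheets
#'   realised as discrete point-charge layers
#' @param box length-3 nm vector; `NA` in x/y sizes the box from the larger
#'   leaflet's composition-weighted area
#' @param area_fluctuation_sd stationary SD of the AR(1) box-area series, nm^2
#' @param dt frame spacing, ps
#' @param seed integer seed governing all randomness
#' @return an object of class `"bilayer_spec"`
#' @export
bilayer_spec <- function(n_lipids = c(outer = 60L, inner = 60L),
                         composition = list(
                           outer = c(POPC = 0.55, PSM = 0.45),
                           inner = c(POPE = 0.50, POPC = 0.30, POPS = 0.20)),
                         chol_fraction = c(outer = 0.2, inner = 0.2),
                         apl = c(POPC = 0.6, PSM = 0.6, POPE = 0.6,
                                 POPS = 0.6, CHOL = 0.3),
                         headgroup_peak_z = 1.95,
                         headgroup_sigma = 0.15,
                         target_scd = list(`16` = rep(0.2, 15L),
                                           `18` = rep(0.2, 17L)),
                         tilt_mode_deg = c(default = 73, CHOL = 75),
                         tilt_sd_deg = 2.5,
                         water_count = 1500L,
                         charge_profile = data.frame(z = numeric(0),
                                                     sigma = numeric(0)),
                         box = c(NA, NA, 10),
                         area_fluctuation_sd = 0.25,
                         dt = 100,
                         seed = 1L) {
  for (side in c("outer", "inner")) {
    f <- composition[[side]]
    if (abs(sum(f) - 1) > 1e-9)
      stop("phospholipid fractions for ", side, " leaflet must sum to 1")
    if (any(f < 0)) stop("negative fraction in ", side, " composition")
  }
  if (any(chol_fraction < 0 | chol_fraction >= 1))
    stop("chol_fraction must lie in [0, 1)")
  if (headgroup_peak_z <= 0) stop("headgroup_peak_z must be > 0")
  for (v in target_scd)
    if (any(v < -0.5 | v > 1))
      stop("target order parameters must lie in [-0.5, 1]")
  if (!"default" %in% names(tilt_mode_deg))
    tilt_mode_deg <- c(tilt_mode_deg, default = 73)
  structure(list(n_lipids = n_lipids, composition = composition,
                 chol_fraction = chol_fraction, apl = apl,
                 headgroup_peak_z = headgroup_peak_z,
                 headgroup_sigma = headgroup_sigma,
                 target_scd = target_scd, tilt_mode_deg = tilt_mode_deg,
                 tilt_sd_deg = tilt_sd_deg, water_count = water_count,
                 charge_profile = charge_profile, box = box,
                 area_fluctuation_sd = area_fluctuation_sd,
                 dt = dt, seed = seed),
            class = "bilayer_spec")
}

# full leaflet composition (phospholipids scaled + CHOL), as fractions
.leaflet_fractions <- function(spec, side) {
  chol <- spec$chol_fraction[[side]]
  f <- spec$composition[[side]] * (1 - chol)
  if (chol > 0) f <- c(f, CHOL = chol)
  f
}

# theta (rad, to z axis) realising a target S = (3 cos^2 theta - 1) / 2
.theta_for_scd <- function(s) acos(sqrt((2 * s + 1) / 3))

# in-plane / along-normal scalar profiles of chain atoms built from
# interleaved chords: atom k+1 = atom k-1 + chord(theta_target(carbon k+1)).
# Positions are (cos(phi) X, sin(phi) X, -sign Z) for a shared azimuth phi.
.chain_profile <- function(targets) {
  m <- length(targets)            # atoms, carbons 2..(m+1)
  theta <- .theta_for_scd(targets)
  X <- Z <- numeric(m)
  X[2L] <- 0.5 * .CHORD_NM * sin(theta[2L])
  Z[2L] <- 0.5 * .CHORD_NM * cos(theta[2L])
  for (k in 2:(m - 1L)) {
    X[k + 1L] <- X[k - 1L] + .CHORD_NM * sin(theta[k])
    Z[k + 1L] <- Z[k - 1L] + .CHORD_NM * cos(theta[k])
  }
  list(X = X, Z = Z)
}

# reflect values into [lo, hi]
.reflect <- function(x, lo, hi) {
  w <- 2 * (hi - lo)
  y <- (x - lo) %% w
  y <- ifelse(y > (hi - lo), w - y, y)
  lo + y
}

#' Generate a synthetic bilayer trajectory with known ground truth
#'
#' Lipids sit on per-leaflet square lattices sized by the
#' composition-weighted area per lipid. Per frame, each lipid's headgroup
#' reference atom is drawn `Normal(+/- headgroup_peak_z, headgroup_sigma)`;
#' chain carbons are placed so that every carbon's `C(i-1) -> C(i+1)` chord
#' sits at the exact polar angle realising that carbon's target order
#' parameter (azimuth uniform per chain per frame); the molecular axis is
#' tilted so its angle to the bilayer plane is drawn around the stated mode;
#' the box area follows a stationary AR(1) series with the stated SD; waters
#' jitter outside `|z| > headgroup_peak_z` on continuous reflected AR(1)
#' paths; charge sheets are realised as discrete point-charge layers plus a
#' neutral remainder, and one +1 counterion is added per -1 of lipid charge.
#' All randomness derives from `spec$seed`.
#'
#' @param spec a [bilayer_spec()]
#' @param n_frames number of frames (>= 1)
#' @return list with elements `trajectory` (a recentred [trajectory()]) and
#'   `ground_truth` (thickness, per-carbon order targets, tilt modes, area
#'   SD, analytic sheet-potential step in mV, empty permeation ledger)
#' @export
generate_bilayer_trajectory <- function(spec, n_frames = 100L) {
  stopifnot(inherits(spec, "bilayer_spec"), n_frames >= 1L)
  set.seed(spec$seed)
  nf <- as.integer(n_frames)

  counts <- lapply(c(outer = "outer", inner = "inner"), function(side)
    composition_counts(.leaflet_fractions(spec, side), spec$n_lipids[[side]]))
  leaf_area <- vapply(counts, function(ct) sum(ct * spec$apl[names(ct)]),
                      numeric(1))
  Abar <- max(leaf_area)
  box <- spec$box
  if (is.na(box[1L])) box[1L] <- sqrt(Abar)
  if (is.na(box[2L])) box[2L] <- sqrt(Abar)
  if (box[1L] * box[2L] < 0.9 * Abar)
    stop("lattice overflow: box area ", round(box[1L] * box[2L], 2),
         " nm^2 cannot host ", round(Abar, 2), " nm^2 of lipids")
  A0 <- box[1L] * box[2L]
  Lz <- box[3L]
  if (spec$headgroup_peak_z + 0.5 > Lz / 2)
    stop("box z too small for headgroup_peak_z")

  # ---- topology assembly (outer lipids, inner lipids, waters, ions, sheets)
  species_order <- list()
  for (side in c("outer", "inner")) {
    ct <- counts[[side]]
    for (sp in names(ct)) if (ct[[sp]] > 0L)
      species_order[[length(species_order) + 1L]] <-
        list(side = side, species = sp, count = ct[[sp]])
  }
  n_neg <- 0L
  atom_rows <- list(); mol_id <- 0L; atom_id <- 0L
  mol_index <- list()   # per molecule: species, side, atom index range
  for (blk in species_order) {
    tmpl <- .species_template(blk$species)
    for (r in seq_len(blk$count)) {
      mol_id <- mol_id + 1L
      idx <- atom_id + seq_len(nrow(tmpl))
      atom_id <- atom_id + nrow(tmpl)
      atom_rows[[mol_id]] <- data.frame(
        atom_id = idx, name = tmpl$name, species = blk$species,
        molecule_id = mol_id, mass = tmpl$mass, charge = tmpl$charge,
        role = tmpl$role, role_index = tmpl$role_index,
        stringsAsFactors = FALSE)
      mol_index[[mol_id]] <- list(species = blk$species, side = blk$side,
                                  atoms = idx)
      n_neg <- n_neg - sum(tmpl$charge)
    }
  }
  n_lip_mol <- mol_id

  add_simple <- function(species, name, mass, charge, role, count) {
    out <- integer(count)
    for (r in seq_len(count)) {
      mol_id <<- mol_id + 1L
      atom_id <<- atom_id + 1L
      atom_rows[[mol_id]] <<- data.frame(
        atom_id = atom_id, name = name, species = species,
        molecule_id = mol_id, mass = mass, charge = charge, role = role,
        role_index = NA_integer_, stringsAsFactors = FALSE)
      out[r] <- atom_id
    }
    out
  }
  wat_idx <- add_simple("WAT", "OW", 18.015, 0, "water_oxygen",
                        spec$water_count)
  n_counter <- as.integer(round(n_neg))
  if (abs(n_neg - n_counter) > 1e-9)
    stop("lipid charge not neutralisable with monovalent counterions")
  cat_idx <- if (n_counter > 0L)
    add_simple("CAT", "NA", 22.99, +1, "other", n_counter) else integer(0)

  sheets <- spec$charge_profile
  n_sheet_pts <- 64L
  sheet_idx <- list()
  if (nrow(sheets)) {
    for (j in seq_len(nrow(sheets))) {
      qtot <- sheets$sigma[j] * A0
      spn <- if (sheets$sigma[j] >= 0) "CAT" else "ANI"
      sheet_idx[[j]] <- add_simple(spn, "SH", 23.0, qtot / n_sheet_pts,
                                   "other", n_sheet_pts)
    }
  }

  topo <- topology(do.call(rbind, atom_rows),
                   species_meta = .species_meta_for(
                     unique(vapply(species_order, `[[`, "", "species"))))
  na <- nrow(topo$atoms)

  # ---- static placement shared by all frames -------------------------------
  lattice_xy <- function(n, Lx, Ly) {
    ns <- ceiling(sqrt(n))
    gx <- ((seq_len(ns) - 0.5) / ns) * Lx
    gy <- ((seq_len(ns) - 0.5) / ns) * Ly
    g <- expand.grid(x = gx, y = gy)
    g[sample.int(nrow(g), n), , drop = FALSE]
  }
  sides <- vapply(mol_index[seq_len(n_lip_mol)], `[[`, "", "side")
  site <- matrix(NA_real_, n_lip_mol, 2L)
  for (side in c("outer", "inner")) {
    sel <- which(sides == side)
    xy <- lattice_xy(length(sel), box[1L], box[2L])
    site[sel, ] <- as.matrix(xy)
  }

  # chain scalar profiles per chain length (identical for all molecules)
  prof <- lapply(spec$target_scd, .chain_profile)

  # water / counterion bases and AR(1) paths (continuous, reflected)
  zpk <- spec$headgroup_peak_z
  wz_lo <- zpk + 0.1; wz_hi <- Lz / 2 - 0.1
  free_pt <- function(n) {
    side <- sample(c(-1, 1), n, replace = TRUE)
    cbind(runif(n, 0, box[1L]), runif(n, 0, box[2L]),
          side * runif(n, wz_lo, wz_hi))
  }
  wat_base <- free_pt(length(wat_idx))
  cat_base <- if (length(cat_idx)) free_pt(length(cat_idx)) else
    matrix(0, 0L, 3L)
  ar1_paths <- function(base_z, nf, sd_step = 0.03, phi = 0.8) {
    n <- length(base_z)
    z <- matrix(0, n, nf)
    state <- numeric(n)
    for (k in seq_len(nf)) {
      state <- phi * state + rnorm(n, 0, sd_step)
      zk <- base_z + state
      z[, k] <- ifelse(base_z > 0, .reflect(zk, wz_lo, wz_hi),
                       .reflect(zk, -wz_hi, -wz_lo))
    }
    z
  }
  wat_z <- ar1_paths(wat_base[, 3L], nf)
  cat_z <- if (nrow(cat_base)) ar1_paths(cat_base[, 3L], nf) else NULL

  sheet_xy <- lapply(sheet_idx, function(idx)
    cbind(runif(length(idx), 0, box[1L]), runif(length(idx), 0, box[2L])))

  # AR(1) box-area series with stationary SD area_fluctuation_sd
  phiA <- 0.9
  sdA <- spec$area_fluctuation_sd
  area_series <- numeric(nf)
  a <- rnorm(1, 0, sdA)
  for (k in seq_len(nf)) {
    area_series[k] <- A0 + a
    a <- phiA * a + rnorm(1, 0, sdA * sqrt(1 - phiA^2))
  }

  # ---- per-frame assembly --------------------------------------------------
  tilt_for <- function(sp) {
    m <- spec$tilt_mode_deg
    if (sp %in% names(m)) m[[sp]] else m[["default"]]
  }
  coords <- array(NA_real_, c(na, 3L, nf))
  boxes <- matrix(NA_real_, nf, 3L)
  sgn <- ifelse(sides == "outer", 1, -1)
  spp <- vapply(mol_index[seq_len(n_lip_mol)], `[[`, "", "species")
  tilt_mode <- vapply(spp, tilt_for, numeric(1))
  L_axis <- ifelse(spp == "CHOL", 0.9, 1.75)

  for (k in seq_len(nf)) {
    sc <- sqrt(area_series[k] / A0)
    boxes[k, ] <- c(box[1L] * sc, box[2L] * sc, Lz)
    hz <- rnorm(n_lip_mol, sgn * ifelse(spp == "CHOL", zpk - 0.4, zpk),
                spec$headgroup_sigma)
    alpha <- .reflect(rnorm(n_lip_mol, tilt_mode, spec$tilt_sd_deg), 0.5, 89.5) *
      pi / 180
    phi_m <- runif(n_lip_mol, 0, 2 * pi)
    phi_c <- matrix(runif(2L * n_lip_mol, 0, 2 * pi), n_lip_mol, 2L)
    Hx <- site[, 1L] * sc; Hy <- site[, 2L] * sc
    # axis tip (terminal-carbon midpoint target)
    Tx <- Hx + L_axis * cos(alpha) * cos(phi_m)
    Ty <- Hy + L_axis * cos(alpha) * sin(phi_m)
    Tz <- hz - sgn * L_axis * sin(alpha)
    for (mi in seq_len(n_lip_mol)) {
      info <- mol_index[[mi]]
      idx <- info$atoms
      s <- sgn[mi]
      if (info$species == "CHOL") {
        tfrac <- seq_len(.CHOL_TAIL_N) / .CHOL_TAIL_N
        coords[idx[1L], , k] <- c(Hx[mi], Hy[mi], hz[mi])
        coords[idx[-1L], 1L, k] <- Hx[mi] + tfrac * (Tx[mi] - Hx[mi])
        coords[idx[-1L], 2L, k] <- Hy[mi] + tfrac * (Ty[mi] - Hy[mi])
        coords[idx[-1L], 3L, k] <- hz[mi] + tfrac * (Tz[mi] - hz[mi])
      } else {
        nchain <- .PL_SPECIES[[info$species]]$chains
        coords[idx[1L], , k] <- c(Hx[mi], Hy[mi], hz[mi])
        offs <- list(c(0.05, 0, 0), c(-0.05, 0, 0))
        # terminal midpoint relative to the molecular anchor
        ends <- vapply(seq_along(nchain), function(ci) {
          p <- prof[[as.character(nchain[ci])]]
          m <- length(p$X)
          c(offs[[ci]][1L] + cos(phi_c[mi, ci]) * p$X[m],
            offs[[ci]][2L] + sin(phi_c[mi, ci]) * p$X[m],
            -s * p$Z[m])
        }, numeric(3))
        m_rel <- rowMeans(ends)
        anchor <- c(Tx[mi], Ty[mi], Tz[mi]) - m_rel
        at <- 1L
        for (ci in seq_along(nchain)) {
          p <- prof[[as.character(nchain[ci])]]
          m <- length(p$X)
          rows <- idx[at + seq_len(m)]
          coords[rows, 1L, k] <- anchor[1L] + offs[[ci]][1L] +
            cos(phi_c[mi, ci]) * p$X
          coords[rows, 2L, k] <- anchor[2L] + offs[[ci]][2L] +
            sin(phi_c[mi, ci]) * p$X
          coords[rows, 3L, k] <- anchor[3L] - s * p$Z
          at <- at + m
        }
      }
    }
    coords[wat_idx, 1L, k] <- wat_base[, 1L] * sc
    coords[wat_idx, 2L, k] <- wat_base[, 2L] * sc
    coords[wat_idx, 3L, k] <- wat_z[, k]
    if (length(cat_idx)) {
      coords[cat_idx, 1L, k] <- cat_base[, 1L] * sc
      coords[cat_idx, 2L, k] <- cat_base[, 2L] * sc
      coords[cat_idx, 3L, k] <- cat_z[, k]
    }
    if (length(sheet_idx)) for (j in seq_along(sheet_idx)) {
      coords[sheet_idx[[j]], 1L, k] <- sheet_xy[[j]][, 1L] * sc
      coords[sheet_idx[[j]], 2L, k] <- sheet_xy[[j]][, 2L] * sc
      coords[sheet_idx[[j]], 3L, k] <- sheets$z[j]
    }
  }

  traj <- trajectory(topo, coords, boxes, dt = spec$dt)

  # analytic plateau-to-plateau potential step of the sheet stack (mV):
  # for a neutral stack, psi(above) - psi(below) = K * sum(sigma_j z_j)
  pot_step <- if (nrow(sheets) && abs(sum(sheets$sigma)) < 1e-12)
    .POTENTIAL_MV * sum(sheets$sigma * sheets$z) else NA_real_

  gt <- list(
    thickness_nm = 2 * spec$headgroup_peak_z,
    target_scd = lapply(spec$target_scd, function(v) {
      m <- length(v)
      # recoverable carbons: 3..(m); chord convention loses the two ends
      data.frame(carbon = (2:(m + 1L))[2:(m - 1L)], scd = v[2:(m - 1L)])
    }),
    tilt_mode_deg = spec$tilt_mode_deg,
    area_sd_nm2 = spec$area_fluctuation_sd,
    analytic_potential_step_mV = pot_step,
    counts = counts,
    events = data.frame(water_id = integer(0), direction = character(0),
                        entry_frame = integer(0), dwell_frames = integer(0)))
  list(trajectory = traj, ground_truth = gt)
}

#' Inject water permeation events with known direction and dwell time
#'
#' Rewrites the z-path of chosen waters so each enters the hydrophobic slab
#' through one boundary, spends exactly `dwell_frames` frames strictly
#' inside, and exits through the opposite boundary, monotone in z; x and y
#' are lightly jittered. Consecutive events on one water must alternate
#' sides (the exit side of one crossing is the entry side of the next).
#'
#' @param trajectory a [trajectory()]
#' @param events data.frame with columns `water_id` (molecule id of a
#'   water), `direction` (`"outer_to_inner"` or `"inner_to_outer"`),
#'   `entry_frame` (first frame inside, >= 2) and `dwell_frames`
#' @param bounds hydrophobic slab bounds `c(lower, upper)` nm
#' @return list with the rewritten `trajectory` and `ground_truth` (the
#'   event table with dwell times in ns)
#' @export
inject_permeation_events <- function(trajectory, events,
                                     bounds = c(-1.2, 1.2)) {
  stopifnot(inherits(trajectory, "trajectory"))
  nf <- n_frames(trajectory)
  at <- trajectory$topology$atoms
  lo <- bounds[1L]; hi <- bounds[2L]
  stopifnot(lo < hi)
  if (nrow(events)) {
    ok <- vapply(events$water_id, function(w)
      any(at$molecule_id == w & at$role == "water_oxygen"), logical(1))
    if (any(!ok)) stop("not a water molecule: ",
                       paste(events$water_id[!ok], collapse = ", "))
    if (any(events$entry_frame < 2L))
      stop("entry_frame must be >= 2 (a crossing needs a preceding frame)")
    if (any(events$entry_frame + events$dwell_frames > nf))
      stop("dwell frames exceed the remaining frames")
  }
  coords <- trajectory$coords
  Lz <- trajectory$box[1L, 3L]
  delta <- 0.04 * (hi - lo)
  for (w in unique(events$water_id)) {
    ev <- events[events$water_id == w, , drop = FALSE]
    ev <- ev[order(ev$entry_frame), , drop = FALSE]
    if (nrow(ev) > 1L) {
      gaps <- ev$entry_frame[-1L] - (ev$entry_frame[-nrow(ev)] +
                                       ev$dwell_frames[-nrow(ev)])
      if (any(gaps < 2L)) stop("overlapping events for water ", w)
      ent <- ifelse(ev$direction == "outer_to_inner", 1, -1)
      if (any(ent[-1L] != -ent[-length(ent)] * 1))
        stop("consecutive events for water ", w, " must alternate direction")
    }
    aidx <- which(at$molecule_id == w & at$role == "water_oxygen")[1L]
    z <- numeric(nf)
    rest <- min(hi + 1.2, Lz / 2 - 0.2)
    restlo <- max(lo - 1.2, -Lz / 2 + 0.2)
    cur <- 1L
    curz <- if (ev$direction[1L] == "outer_to_inner") rest else restlo
    for (j in seq_len(nrow(ev))) {
      e <- ev$entry_frame[j]; dw <- ev$dwell_frames[j]
      o2i <- ev$direction[j] == "outer_to_inner"
      in_from <- if (o2i) hi - delta else lo + delta
      in_to <- if (o2i) lo + delta else hi - delta
      just_in_side <- if (o2i) hi + 0.08 else lo - 0.08
      just_out_side <- if (o2i) lo - 0.08 else hi + 0.08
      # approach segment: frames cur..e-1 ends just outside the entry bound
      if (e - 1L >= cur)
        z[cur:(e - 1L)] <- seq(curz, just_in_side, length.out = e - cur)
      # inside segment, strictly within the open interval
      z[e:(e + dw - 1L)] <- seq(in_from, in_to, length.out = dw)
      z[e + dw] <- just_out_side
      cur <- e + dw
      curz <- just_out_side
    }
    if (cur < nf) {
      away <- if (curz > 0) rest else restlo
      z[(cur + 1L):nf] <- seq(curz + (away - curz) / (nf - cur), away,
                              length.out = nf - cur)
    }
    coords[aidx, 3L, ] <- z
    coords[aidx, 1L, ] <- coords[aidx, 1L, ] + rnorm(nf, 0, 0.01)
    coords[aidx, 2L, ] <- coords[aidx, 2L, ] + rnorm(nf, 0, 0.01)
  }
  out <- trajectory
  out$coords <- coords
  gt <- events
  gt$dwell_ns <- gt$dwell_frames * trajectory$dt / 1000
  list(trajectory = out, ground_truth = gt)
}

#' Generate a toy pair-interaction system with an exact virial pressure
#'
#' A stand-in ensemble for validating the slab pressure decomposition:
#' point particles in a periodic box interacting through a truncated
#' (unshifted) 12-6 pair potential. Per-pair minimum-image forces and the
#' exact global virial pressure are computed by direct summation and stored
#' with the configuration.
#'
#' @param n_particles particle count (>= 1)
#' @param box length-3 box, nm
#' @param arrangement `"ideal_gas"` (interactions disabled), `"bulk_fluid"`
#'   (uniform with the pair potential active) or `"single_pair"`
#' @param epsilon,sigma,cutoff pair-potential parameters (kJ/mol, nm, nm)
#' @param temperature K (kinetic term uses equipartition, no velocities)
#' @param positions 2 x 3 matrix for `single_pair`
#' @param seed integer seed
#' @return an object of class `"pair_system"` with elements `coords`, `box`,
#'   `pairs` (i, j, minimum-image displacement d = r_i - r_j, force on i,
#'   separation r), `pressure_bar` (exact global virial pressure),
#'   `temperature` and the potential parameters
#' @export
generate_pair_system <- function(n_particles, box = c(8, 8, 8),
                                 arrangement = c("ideal_gas", "bulk_fluid",
                                                 "single_pair"),
                                 epsilon = 0.65, sigma = 0.34, cutoff = 1.0,
                                 temperature = 300, positions = NULL,
                                 seed = 1L) {
  arrangement <- match.arg(arrangement)
  stopifnot(n_particles >= 1L)
  set.seed(seed)
  if (arrangement == "single_pair") {
    if (is.null(positions))
      positions <- rbind(c(box[1] / 2, box[2] / 2, box[3] / 2 - 0.5),
                         c(box[1] / 2, box[2] / 2, box[3] / 2 + 0.5))
    coords <- positions
    n_particles <- nrow(coords)
  } else {
    coords <- cbind(runif(n_particles, 0, box[1]),
                    runif(n_particles, 0, box[2]),
                    runif(n_particles, 0, box[3]))
    if (arrangement == "bulk_fluid") {
      # resample particles overlapping closer than 0.1 sigma
      for (attempt in seq_len(1000L)) {
        d2 <- .min_image_dist2(coords, box)
        bad <- unique(which(d2 < (0.1 * sigma)^2, arr.ind = TRUE)[, 1L])
        if (!length(bad)) break
        coords[bad, ] <- cbind(runif(length(bad), 0, box[1]),
                               runif(length(bad), 0, box[2]),
                               runif(length(bad), 0, box[3]))
        if (attempt == 1000L) stop("could not place non-overlapping particles")
      }
    }
  }
  interacting <- arrangement != "ideal_gas"
  pairs <- .pair_forces(coords, box, epsilon, sigma, cutoff, interacting)
  V <- prod(box)
  W <- if (nrow(pairs)) sum(pairs$dx * pairs$fx + pairs$dy * pairs$fy +
                              pairs$dz * pairs$fz) else 0
  p_bar <- (n_particles * .kB * temperature / V + W / (3 * V)) * .PRESSURE_BAR
  structure(list(coords = coords, box = box, pairs = pairs,
                 pressure_bar = p_bar, temperature = temperature,
                 epsilon = if (interacting) epsilon else 0, sigma = sigma,
                 cutoff = cutoff, arrangement = arrangement),
            class = "pair_system")
}

.min_image_dist2 <- function(coords, box) {
  n <- nrow(coords)
  d2 <- matrix(Inf, n, n)
  for (a in 1:3) {
    d <- outer(coords[, a], coords[, a], "-")
    d <- d - box[a] * round(d / box[a])
    if (a == 1L) d2 <- d * d else d2 <- d2 + d * d
  }
  diag(d2) <- Inf
  d2
}

# truncated, unshifted LJ forces for all pairs within the cutoff.
# d = r_i - r_j (minimum image); f = force on particle i.
.pair_forces <- function(coords, box, epsilon, sigma, cutoff, interacting) {
  empty <- data.frame(i = integer(0), j = integer(0), dx = numeric(0),
                      dy = numeric(0), dz = numeric(0), fx = numeric(0),
                      fy = numeric(0), fz = numeric(0), r = numeric(0))
  n <- nrow(coords)
  if (!interacting || n < 2L) return(empty)
  dd <- lapply(1:3, function(a) {
    d <- outer(coords[, a], coords[, a], "-")
    d - box[a] * round(d / box[a])
  })
  r2 <- dd[[1L]]^2 + dd[[2L]]^2 + dd[[3L]]^2
  sel <- which(upper.tri(r2) & r2 < cutoff^2, arr.ind = TRUE)
  if (!nrow(sel)) return(empty)
  i <- sel[, 1L]; j <- sel[, 2L]
  lin <- sel[, 1L] + (sel[, 2L] - 1L) * n
  dx <- dd[[1L]][lin]; dy <- dd[[2L]][lin]; dz <- dd[[3L]][lin]
  r <- sqrt(r2[lin])
  sr6 <- (sigma / r)^6
  # |F| * r = 24 eps (2 sr^12 - sr^6); force on i along +d when repulsive
  fmag_r <- 24 * epsilon * (2 * sr6^2 - sr6)
  f_over_r2 <- fmag_r / r^2
  data.frame(i = i, j = j, dx = dx, dy = dy, dz = dz,
             fx = f_over_r2 * dx, fy = f_over_r2 * dy, fz = f_over_r2 * dz,
             r = r)
}

#' @export
print.pair_system <- function(x, ...) {
  cat("Pair system (", x$arrangement, "): ", nrow(x$coords), " particles, ",
      nrow(x$pairs), " interacting pairs, P = ",
      format(x$pressure_bar, digits = 6), " bar\n", sep = "")
  invisible(x)
}
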
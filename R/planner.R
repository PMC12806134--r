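# Membrane-construction arithmetic: integer apportionment of leaflet
# compositions, leaflet-area matching, lipid-number mismatch (STRESS-style
# variants), cholesterol asymmetry, and double-bilayer two-compartment
# systems with ion bookkeeping.

# default headgroup charges used for neutrality bookkeeping
.SPECIES_CHARGE <- c(POPC = 0, PSM = 0, POPE = 0, POPS = -1, CHOL = 0)

#' Apportion a composition into integer counts
#'
#' Largest-remainder apportionment: counts sum to exactly `n`; remainder
#' ties are broken by descending fraction, then lexical species name.
#'
#' @param fractions named non-negative fractions summing to 1
#' @param n total count (>= 0)
#' @return named integer vector summing to `n`
#' @export
composition_counts <- function(fractions, n) {
  if (any(fractions < 0)) stop("negative fraction")
  if (length(fractions) && abs(sum(fractions) - 1) > 1e-6)
    stop("fractions must sum to 1")
  n <- as.integer(n)
  if (n < 0L) stop("n must be >= 0")
  q <- fractions * n
  base <- floor(q + 1e-12)
  rem <- q - base
  left <- n - sum(base)
  ord <- order(-rem, -fractions, names(fractions))
  add <- integer(length(fractions))
  if (left > 0L) add[ord[seq_len(left)]] <- 1L
  out <- as.integer(base + add)
  names(out) <- names(fractions)
  out
}

#' A single-leaflet plan
#'
#' @param counts named integer species counts
#' @param apl area per lipid by species, nm^2
#' @return an object of class `"leaflet_plan"`: counts, `chol_fraction`,
#'   `expected_area` (nm^2, `sum(count * apl)`) and the `apl` table
#' @export
leaflet_plan <- function(counts, apl = c(POPC = 0.6, PSM = 0.6, POPE = 0.6,
                                         POPS = 0.6, CHOL = 0.3)) {
  counts <- counts[counts > 0]
  if (any(counts < 0)) stop("negative lipid count")
  missing_apl <- setdiff(names(counts), names(apl))
  if (length(missing_apl))
    stop("no area per lipid for species: ", paste(missing_apl, collapse = ", "))
  total <- sum(counts)
  chol_n <- if ("CHOL" %in% names(counts)) counts[["CHOL"]] else 0L
  structure(list(counts = counts,
                 chol_fraction = if (total) chol_n / total else 0,
                 expected_area = sum(counts * apl[names(counts)]),
                 apl = apl),
            class = "leaflet_plan")
}

#' @export
print.leaflet_plan <- function(x, ...) {
  cat("Leaflet plan:", paste(sprintf("%s=%d", names(x$counts), x$counts),
                             collapse = ", "),
      sprintf("| area %.2f nm^2\n", x$expected_area))
  invisible(x)
}

#' Lipid-count offset that matches two leaflet areas
#'
#' The offset is `round(|area_outer - area_inner| / mean_apl)` lipids,
#' where `mean_apl` is the composition-weighted mean area per lipid of the
#' adjusted leaflet, applied with the sign that moves the adjusted
#' leaflet's area toward the other leaflet's. The offset is apportioned
#' across species by [composition_counts()] so the component ratio is
#' maintained.
#'
#' @param area_outer,area_inner leaflet areas, nm^2
#' @param leaflet_to_adjust `"outer"` or `"inner"`
#' @param apl area per lipid by species, nm^2
#' @param fractions composition of the adjusted leaflet (species fractions
#'   summing to 1, cholesterol included)
#' @param plan optional [leaflet_plan()] for the adjusted leaflet; when
#'   given, the adjusted plan is returned too
#' @return list with `offset` (signed lipid count for the adjusted
#'   leaflet), `delta_counts` (signed per-species counts), `mean_apl`,
#'   `residual_area` (nm^2 mismatch after adjustment) and, when `plan` is
#'   supplied, `adjusted_plan`
#' @export
area_match_offsets <- function(area_outer, area_inner,
                               leaflet_to_adjust = c("outer", "inner"),
                               apl, fractions, plan = NULL) {
  leaflet_to_adjust <- match.arg(leaflet_to_adjust)
  if (area_outer <= 0 || area_inner <= 0) stop("areas must be positive")
  mean_apl <- sum(fractions * apl[names(fractions)])
  if (!is.finite(mean_apl) || mean_apl <= 0)
    stop("composition-weighted mean area per lipid is zero")
  darea <- area_outer - area_inner
  n_off <- as.integer(round(abs(darea) / mean_apl))
  own_larger <- if (leaflet_to_adjust == "outer") darea > 0 else darea < 0
  sgn <- if (own_larger) -1L else 1L
  offset <- sgn * n_off
  delta_counts <- sgn * composition_counts(fractions, n_off)
  adj <- offset * mean_apl
  residual <- if (leaflet_to_adjust == "outer")
    abs(area_outer + adj - area_inner) else abs(area_inner + adj - area_outer)
  out <- list(offset = offset, delta_counts = delta_counts,
              mean_apl = mean_apl, residual_area = residual)
  if (!is.null(plan)) {
    new_counts <- plan$counts
    for (sp in names(delta_counts)) {
      cur <- if (sp %in% names(new_counts)) new_counts[[sp]] else 0L
      new_counts[[sp]] <- cur + delta_counts[[sp]]
    }
    if (any(new_counts < 0)) stop("adjustment would make a species count negative")
    out$adjusted_plan <- leaflet_plan(new_counts, plan$apl)
  }
  out
}

#' A full assembly plan (one bilayer, or a mirrored double bilayer)
#'
#' @param outer,inner [leaflet_plan()]s
#' @param label model label (free text, e.g. `"H20"`, `"+5%"`, `"D2H"`)
#' @param box optional length-3 box, nm
#' @param double logical: mirrored double-bilayer (two-compartment) system
#' @param ions list of per-compartment ion counts,
#'   `list(interior = c(cation =, anion =), exterior = ...)`; for a single
#'   bilayer the sole solvent compartment is `exterior`
#' @param species_charges named lipid charges (e) for neutrality bookkeeping
#' @param auto_neutralize add monovalent counterions to the exterior
#'   compartment so the plan's net charge is zero (default TRUE; matches the
#'   generator, which always neutralises charged lipids)
#' @return an object of class `"assembly_plan"`
#' @export
assembly_plan <- function(outer, inner, label = "", box = NULL,
                          double = FALSE,
                          ions = list(interior = c(cation = 0L, anion = 0L),
                                      exterior = c(cation = 0L, anion = 0L)),
                          species_charges = .SPECIES_CHARGE,
                          auto_neutralize = TRUE) {
  stopifnot(inherits(outer, "leaflet_plan"), inherits(inner, "leaflet_plan"))
  mult <- if (double) 2L else 1L
  lipid_charge <- function(lp) sum(lp$counts *
                                     species_charges[names(lp$counts)])
  net <- mult * (lipid_charge(outer) + lipid_charge(inner)) +
    sum(vapply(ions, function(io) io[["cation"]] - io[["anion"]], numeric(1)))
  if (auto_neutralize && net != 0) {
    if (abs(net - round(net)) > 1e-9)
      stop("neutrality unreachable with monovalent ions (fractional charge)")
    net <- as.integer(round(net))
    if (net < 0) ions$exterior[["cation"]] <- ions$exterior[["cation"]] - net
    else ions$exterior[["anion"]] <- ions$exterior[["anion"]] + net
    net <- 0L
  }
  structure(list(outer = outer, inner = inner, label = label, box = box,
                 double = double, ions = ions,
                 net_charge = net, species_charges = species_charges),
            class = "assembly_plan")
}

#' @export
print.assembly_plan <- function(x, ...) {
  cat("Assembly plan", if (nzchar(x$label)) paste0("'", x$label, "'"), ":",
      if (x$double) "double bilayer (mirrored)" else "single bilayer", "\n")
  cat("  outer:"); print(x$outer)
  cat("  inner:"); print(x$inner)
  cat(sprintf("  ions: interior %d+/%d-, exterior %d+/%d- | net charge %+g e\n",
              x$ions$interior[["cation"]], x$ions$interior[["anion"]],
              x$ions$exterior[["cation"]], x$ions$exterior[["anion"]],
              x$net_charge))
  invisible(x)
}

#' Lipid-number mismatch (STRESS-style) variant of a plan
#'
#' Scales the outer leaflet's total count by `(1 + percent/100)`, rounds,
#' and re-apportions it across species by [composition_counts()]; the inner
#' leaflet is untouched.
#'
#' @param plan an [assembly_plan()]
#' @param percent signed percentage (e.g. `+5`, `-10`)
#' @return an adjusted [assembly_plan()]
#' @export
stress_variant <- function(plan, percent) {
  stopifnot(inherits(plan, "assembly_plan"))
  tot <- sum(plan$outer$counts)
  new_tot <- as.integer(round(tot * (1 + percent / 100)))
  if (new_tot < 1L) stop("resulting lipid count below 1")
  fr <- plan$outer$counts / tot
  new_counts <- composition_counts(fr, new_tot)
  assembly_plan(leaflet_plan(new_counts, plan$outer$apl), plan$inner,
                label = sprintf("%s%+g%%", plan$label, percent),
                box = plan$box, double = plan$double, ions = plan$ions,
                species_charges = plan$species_charges)
}

#' Combine two leaflet models into a cholesterol-asymmetric plan
#'
#' The inner leaflet is fixed; the outer leaflet is adjusted via
#' [area_match_offsets()] so its expected area moves to the inner
#' leaflet's.
#'
#' @param outer_plan,inner_plan [leaflet_plan()]s
#' @param label model label
#' @return an [assembly_plan()]
#' @export
combine_asymchol <- function(outer_plan, inner_plan, label = "asymCHOL") {
  fr <- outer_plan$counts / sum(outer_plan$counts)
  amo <- area_match_offsets(outer_plan$expected_area,
                            inner_plan$expected_area, "outer",
                            outer_plan$apl, fr, plan = outer_plan)
  assembly_plan(amo$adjusted_plan, inner_plan, label = label)
}

#' Plan a double-bilayer two-compartment system with ions
#'
#' The system is the bilayer plan plus its z-mirror, stacked so both inner
#' leaflets face the interior compartment; periodic boundaries close the
#' exterior compartment. Ion pairs per compartment are
#' `round(c * N_A * V)`; extra monovalent counterions are added to the
#' compartment facing charged lipids so the net system charge is zero.
#'
#' @param bilayer_plan an [assembly_plan()] for one bilayer
#' @param interior_conc,exterior_conc salt concentrations, mM
#' @param volumes water volumes per compartment,
#'   `c(interior = , exterior = )` nm^3
#' @return a double-bilayer [assembly_plan()]
#' @export
plan_physiol_system <- function(bilayer_plan, interior_conc, exterior_conc,
                                volumes) {
  stopifnot(inherits(bilayer_plan, "assembly_plan"))
  if (interior_conc < 0 || exterior_conc < 0) stop("concentrations must be >= 0")
  if (any(volumes <= 0)) stop("compartment volumes must be positive")
  # mM * nm^3 -> molecules: 1e-3 mol/L * N_A / (1e24 nm^3/L)
  pairs <- function(conc, vol) as.integer(round(conc * 1e-3 *
                                                  .N_AVOGADRO * 1e-24 * vol))
  n_int <- pairs(interior_conc, volumes[["interior"]])
  n_ext <- pairs(exterior_conc, volumes[["exterior"]])
  sc <- bilayer_plan$species_charges
  q_leaf <- function(lp) sum(lp$counts * sc[names(lp$counts)])
  # two mirror copies: inner leaflets face the interior, outer the exterior
  q_int <- 2 * q_leaf(bilayer_plan$inner)
  q_ext <- 2 * q_leaf(bilayer_plan$outer)
  counter <- function(q, base) {
    if (abs(q - round(q)) > 1e-9)
      stop("neutrality unreachable with monovalent ions (fractional lipid charge)")
    q <- as.integer(round(q))
    c(cation = base + max(0L, -q), anion = base + max(0L, q))
  }
  assembly_plan(bilayer_plan$outer, bilayer_plan$inner,
                label = paste0(bilayer_plan$label, " PHYSIOL"),
                box = bilayer_plan$box, double = TRUE,
                ions = list(interior = counter(q_int, n_int),
                            exterior = counter(q_ext, n_ext)),
                species_charges = sc)
}

#' Realize a plan as a starting structure
#'
#' Delegates to the synthetic-bilayer placement to emit a one-frame
#' starting structure plus a manifest of exact per-species counts per
#' leaflet (and per compartment for double systems). Double-bilayer plans
#' produce two mirror-image bilayers with their inner leaflets facing the
#' interior compartment, plus the planned ions.
#'
#' @param plan an [assembly_plan()]
#' @param spec_defaults named list of [bilayer_spec()] overrides (e.g.
#'   `headgroup_peak_z`, `water_count`, `seed`)
#' @param bilayer_offset for double systems, distance of each bilayer
#'   midplane from z = 0, nm
#' @return list with `trajectory` (one frame) and `manifest`
#' @export
realize_plan <- function(plan, spec_defaults = list(), bilayer_offset = 4) {
  stopifnot(inherits(plan, "assembly_plan"))
  to_frac <- function(lp) lp$counts / sum(lp$counts)
  strip_chol <- function(fr) {
    chol <- if ("CHOL" %in% names(fr)) fr[["CHOL"]] else 0
    pl <- fr[names(fr) != "CHOL"]
    list(pl = pl / sum(pl), chol = chol)
  }
  fo <- strip_chol(to_frac(plan$outer)); fi <- strip_chol(to_frac(plan$inner))
  args <- list(
    n_lipids = c(outer = sum(plan$outer$counts),
                 inner = sum(plan$inner$counts)),
    composition = list(outer = fo$pl, inner = fi$pl),
    chol_fraction = c(outer = fo$chol, inner = fi$chol),
    apl = plan$outer$apl)
  args[names(spec_defaults)] <- spec_defaults
  spec <- do.call(bilayer_spec, args)
  gen <- generate_bilayer_trajectory(spec, n_frames = 1L)
  traj <- gen$trajectory
  # count audit against the plan
  counts <- .leaflet_species_counts(traj)
  for (side in c("outer", "inner")) {
    planned <- if (side == "outer") plan$outer$counts else plan$inner$counts
    got <- counts[[side]][names(planned)]
    got[is.na(got)] <- 0L
    if (!all(got == planned))
      stop("realized structure does not match planned counts (", side, ")")
  }
  manifest <- list(label = plan$label, double = plan$double,
                   leaflets = counts, ions = plan$ions,
                   net_charge = plan$net_charge)
  if (plan$double) {
    traj <- .stack_double_bilayer(traj, plan, bilayer_offset)
    manifest$leaflets <- list(
      upper = counts, lower = counts)
  }
  list(trajectory = traj, manifest = manifest)
}

.leaflet_species_counts <- function(traj) {
  leaf <- assign_leaflets(traj)
  at <- traj$topology$atoms
  out <- list()
  for (side in c("outer", "inner")) {
    mols <- leaflet_molecules(leaf, side)
    sp <- vapply(mols, function(m)
      at$species[which(at$molecule_id == m)[1L]], "")
    tb <- table(sp)
    out[[side]] <- stats::setNames(as.integer(tb), names(tb))
  }
  out
}

# two mirror-image copies of a one-frame bilayer, inner leaflets inward,
# plus the planned compartment ions
.stack_double_bilayer <- function(traj, plan, offset) {
  at <- traj$topology$atoms
  # lipids only: waters and the generator's counterions are replaced by the
  # plan's per-compartment ion bookkeeping
  keep <- !(at$species %in% c("WAT", "CAT", "ANI"))
  at1 <- at[keep, , drop = FALSE]
  x1 <- traj$coords[keep, , 1L, drop = FALSE][, , 1L]
  # upper copy at +offset (outer leaflet up), mirrored lower copy at -offset
  up <- x1; up[, 3L] <- x1[, 3L] + offset
  lo <- x1; lo[, 3L] <- -x1[, 3L] - offset
  at2 <- at1
  at2$molecule_id <- at2$molecule_id + max(at1$molecule_id)
  at2$atom_id <- at2$atom_id + max(at1$atom_id)
  box <- traj$box[1L, ]
  Lz <- 2 * (offset + box[3L] / 2)
  mk_ions <- function(compartment, counts, at_offset, mol_offset) {
    n <- sum(counts)
    if (n == 0L) return(NULL)
    zr <- if (compartment == "interior")
      c(-offset + 1.0, offset - 1.0) else c(offset + 2.6, Lz / 2 - 0.3)
    z <- runif(n, zr[1L], zr[2L])
    if (compartment == "exterior")        # split across the periodic images
      z <- z * sample(c(-1, 1), n, replace = TRUE)
    data.frame(
      atom_id = at_offset + seq_len(n),
      name = rep(c("NA", "CL"), c(counts[["cation"]], counts[["anion"]])),
      species = rep(c("CAT", "ANI"), c(counts[["cation"]], counts[["anion"]])),
      molecule_id = mol_offset + seq_len(n),
      mass = rep(c(22.99, 35.45), c(counts[["cation"]], counts[["anion"]])),
      charge = rep(c(1, -1), c(counts[["cation"]], counts[["anion"]])),
      role = "other", role_index = NA_integer_,
      x = runif(n, 0, box[1L]), y = runif(n, 0, box[2L]), z = z,
      stringsAsFactors = FALSE)
  }
  ions_int <- mk_ions("interior", plan$ions$interior,
                      max(at2$atom_id), max(at2$molecule_id))
  ions_ext <- mk_ions("exterior", plan$ions$exterior,
                      max(at2$atom_id) + NROW(ions_int),
                      max(at2$molecule_id) + NROW(ions_int))
  atoms <- rbind(at1, at2,
                 if (!is.null(ions_int)) ions_int[, names(at1)],
                 if (!is.null(ions_ext)) ions_ext[, names(at1)])
  coords <- rbind(up, lo,
                  if (!is.null(ions_int)) as.matrix(ions_int[, c("x", "y", "z")]),
                  if (!is.null(ions_ext)) as.matrix(ions_ext[, c("x", "y", "z")]))
  atoms$atom_id <- seq_len(nrow(atoms))
  topo <- topology(atoms, species_meta = traj$topology$species_meta)
  trajectory(topo, coords, c(box[1L], box[2L], Lz), dt = traj$dt)
}
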
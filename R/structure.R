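# Structural observables: lateral area statistics, density profiles,
# thickness, tilt distributions and acyl-chain order parameters.

#' Lateral area statistics and area per lipid
#'
#' The per-frame lateral area is `Lx * Ly`. The fluctuation is reported as
#' the population standard deviation of the series (a descriptive statistic
#' over the full series, not a sample estimate). Area per lipid divides the
#' mean area by each leaflet's lipid count.
#'
#' @param trajectory a [trajectory()]
#' @param leaflets a [assign_leaflets()] result
#' @return an object of class `"area_stats"`: list with `series` (nm^2),
#'   `mean`, `sd` and `apl` (named by leaflet, nm^2)
#' @export
lateral_area_stats <- function(trajectory, leaflets) {
  series <- trajectory$box[, 1L] * trajectory$box[, 2L]
  mu <- mean(series)
  sdev <- sqrt(mean((series - mu)^2))
  apl <- vapply(c(outer = "outer", inner = "inner"), function(side) {
    nlip <- sum(leaflets$leaflet == side)
    if (nlip == 0L) stop("no lipids assigned to the ", side, " leaflet")
    mu / nlip
  }, numeric(1))
  structure(list(series = series, mean = mu, sd = sdev, apl = apl),
            class = "area_stats")
}

#' @export
print.area_stats <- function(x, ...) {
  cat(sprintf("Lateral area: %.3f +/- %.3f nm^2 (n = %d frames)\n",
              x$mean, x$sd, length(x$series)))
  cat(sprintf("  area per lipid: outer %.4f, inner %.4f nm^2\n",
              x$apl[["outer"]], x$apl[["inner"]]))
  invisible(x)
}

#' Mass or charge density profile along the membrane normal
#'
#' Histograms the selected atoms' z coordinates weighted by mass (amu) or
#' partial charge (e), per frame, divides by the bin volume (mean lateral
#' box area times bin width) and averages over frames. Bins are uniform and
#' placed so that z = 0 is a bin edge.
#'
#' @param trajectory a recentred [trajectory()]
#' @param selection atom indices (see [select_atoms()])
#' @param bin_width bin width, nm (default 0.1)
#' @param weight `"mass"` (amu/nm^3) or `"charge"` (e/nm^3)
#' @param label selection label carried in the result
#' @return an object of class `"density_profile"`: data.frame with `z`
#'   (bin centers, nm) and `density`; attributes `edges`, `bin_width`,
#'   `weight`, `area` (mean lateral area) and `label`
#' @export
density_profile <- function(trajectory, selection, bin_width = 0.1,
                            weight = c("mass", "charge"), label = "") {
  weight <- match.arg(weight)
  if (length(selection) == 0L) stop("empty selection")
  if (bin_width <= 0) stop("bin_width must be positive")
  at <- trajectory$topology$atoms
  w <- if (weight == "mass") at$mass[selection] else at$charge[selection]
  zmax <- max(trajectory$box[, 3L]) / 2
  nbin_side <- ceiling(zmax / bin_width + 1e-9)
  edges <- seq(-nbin_side, nbin_side) * bin_width
  nb <- length(edges) - 1L
  nf <- n_frames(trajectory)
  acc <- numeric(nb)
  for (k in seq_len(nf)) {
    z <- trajectory$coords[selection, 3L, k]
    bi <- findInterval(z, edges, rightmost.closed = TRUE)
    bi[bi < 1L] <- 1L; bi[bi > nb] <- nb
    rs <- rowsum(w, bi)
    at_bins <- as.integer(rownames(rs))
    acc[at_bins] <- acc[at_bins] + rs[, 1L]
  }
  area <- mean(trajectory$box[, 1L] * trajectory$box[, 2L])
  dens <- acc / (nf * area * bin_width)
  out <- data.frame(z = (edges[-1L] + edges[-length(edges)]) / 2,
                    density = dens)
  structure(out, class = c("density_profile", "data.frame"),
            edges = edges, bin_width = bin_width, weight = weight,
            area = area, label = label, total = sum(w))
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("%s density profile '%s': %d bins of %.3g nm, peak %.4g at z = %.2f nm\n",
              attr(x, "weight"), attr(x, "label"), nrow(x),
              attr(x, "bin_width"), max(x$density), x$z[which.max(x$density)]))
  invisible(x)
}

# three-point parabolic refinement of a peak position
.parabolic_peak <- function(z, v, i, bw) {
  denom <- v[i - 1L] - 2 * v[i] + v[i + 1L]
  if (abs(denom) < .Machine$double.eps) return(z[i])
  z[i] + 0.5 * bw * (v[i - 1L] - v[i + 1L]) / denom
}

#' Membrane thickness from a density profile
#'
#' The thickness is the distance between the maximal densities of the two
#' leaflets along z: the maximum-density bin is located separately on each
#' side of z = 0, refined by three-point parabolic interpolation, and the
#' peak-to-peak distance returned. Running it on a headgroup-only or
#' phospholipid-only profile gives the corresponding selective thickness.
#'
#' @param profile a [density_profile()] covering both sides of z = 0
#' @return thickness, nm
#' @export
membrane_thickness <- function(profile) {
  bw <- attr(profile, "bin_width")
  peak_side <- function(side) {
    sel <- if (side > 0) profile$z > 0 else profile$z < 0
    z <- profile$z[sel]; v <- profile$density[sel]
    if (length(v) < 3L) stop("no leaflet peak: profile does not cover z ",
                             if (side > 0) "> 0" else "< 0")
    i <- which.max(v)
    if (i == 1L || i == length(v))
      stop("no leaflet peak: density is monotone for z ",
           if (side > 0) "> 0" else "< 0")
    .parabolic_peak(z, v, i, bw)
  }
  peak_side(+1) - peak_side(-1)
}

# molecular axis per molecule: from a reference atom to the (midpoint of)
# terminal chain carbon(s). Sterols: hydroxyl -> last tail carbon;
# phospholipids: headgroup -> midpoint of the terminal carbons of each chain.
.molecule_axes <- function(trajectory, mols) {
  at <- trajectory$topology$atoms
  meta <- trajectory$topology$species_meta
  lapply(mols, function(m) {
    rows <- which(at$molecule_id == m)
    sp <- at$species[rows[1L]]
    sm <- meta[[sp]]
    ref <- rows[at$role[rows] %in% c("headgroup_ref", "hydroxyl_ref")][1L]
    if (is.na(ref)) stop("molecule ", m, " has no axis reference atom")
    if (!is.null(sm) && length(sm$chains)) {
      term_names <- vapply(sm$chains, function(ch) ch[length(ch)], "")
      tips <- rows[match(term_names, at$name[rows])]
    } else {
      tips <- rows[which.max(at$role_index[rows])]
    }
    list(ref = ref, tips = tips[!is.na(tips)])
  })
}

#' Tilt-angle distribution of a lipid species
#'
#' The tilt angle is measured between the molecular axis and the bilayer
#' *plane*: `asin(|axis_z| / |axis|)` in degrees, in `[0, 90]` -- 90 deg
#' means perpendicular to the plane. The most probable angle is the center
#' of the maximal histogram bin refined parabolically.
#'
#' @param trajectory a [trajectory()]
#' @param species species name (e.g. `"CHOL"`, `"POPC"`)
#' @param leaflets a [assign_leaflets()] result
#' @param leaflet `"outer"` or `"inner"`
#' @param bin_width histogram bin width, degrees
#' @return an object of class `"tilt_distribution"`: list with `breaks`,
#'   `prob` (normalised histogram), `mode_deg`, `species`, `leaflet`
#' @export
tilt_distribution <- function(trajectory, species, leaflets, leaflet = "outer",
                              bin_width = 1) {
  mols <- leaflet_molecules(leaflets, leaflet)
  at <- trajectory$topology$atoms
  mols <- mols[vapply(mols, function(m)
    at$species[which(at$molecule_id == m)[1L]] == species, logical(1))]
  if (!length(mols)) stop("species ", species, " not present in the ",
                          leaflet, " leaflet")
  axes <- .molecule_axes(trajectory, mols)
  nf <- n_frames(trajectory)
  angles <- numeric(0)
  n_skip <- 0L
  for (k in seq_len(nf)) {
    a <- vapply(axes, function(ax) {
      tip <- colMeans(trajectory$coords[ax$tips, , k, drop = FALSE])
      v <- tip - trajectory$coords[ax$ref, , k]
      nv <- sqrt(sum(v^2))
      if (nv < 1e-9) return(NA_real_)
      asin(min(1, abs(v[3L]) / nv)) * 180 / pi
    }, numeric(1))
    n_skip <- n_skip + sum(is.na(a))
    angles <- c(angles, a[!is.na(a)])
  }
  if (n_skip > 0L) warning(n_skip, " degenerate (zero-length) axes skipped")
  if (!length(angles)) stop("all molecular axes degenerate")
  breaks <- seq(0, 90, by = bin_width)
  h <- hist(pmin(angles, 90 - 1e-12), breaks = breaks, plot = FALSE)
  prob <- h$counts / sum(h$counts)
  i <- which.max(prob)
  mode_deg <- if (i == 1L || i == length(prob)) h$mids[i] else
    .parabolic_peak(h$mids, prob, i, bin_width)
  structure(list(breaks = breaks, prob = prob, mode_deg = mode_deg,
                 species = species, leaflet = leaflet,
                 bin_width = bin_width, n = length(angles)),
            class = "tilt_distribution")
}

#' @export
print.tilt_distribution <- function(x, ...) {
  cat(sprintf("Tilt distribution %s (%s leaflet): mode %.1f deg (n = %d)\n",
              x$species, x$leaflet, x$mode_deg, x$n))
  invisible(x)
}

#' Acyl-chain order parameter profile
#'
#' For carbon i the orientation vector is the `C(i-1) -> C(i+1)` chord (the
#' explicit-hydrogen-free convention, an approximation to the C-H
#' deuterium convention) and `S_CD(i) = <(3 cos^2 theta - 1) / 2>` over
#' molecules and frames, theta being the chord's angle to the membrane
#' normal (z). The standard error is computed across frame means.
#'
#' @param trajectory a [trajectory()]
#' @param species phospholipid species name
#' @param chain chain index within the species (1 = sn-1, ...)
#' @param leaflets a [assign_leaflets()] result
#' @param leaflet `"outer"` or `"inner"`
#' @return an object of class `"order_profile"`: data.frame with `carbon`,
#'   `scd`, `se`
#' @export
chain_order_parameters <- function(trajectory, species, chain = 1L,
                                   leaflets, leaflet = "inner") {
  at <- trajectory$topology$atoms
  meta <- trajectory$topology$species_meta[[species]]
  if (is.null(meta) || length(meta$chains) < chain)
    stop("chain ", chain, " not defined for species ", species)
  chain_names <- meta$chains[[chain]]
  if (length(chain_names) < 3L) stop("chain has fewer than 3 carbons")
  mols <- leaflet_molecules(leaflets, leaflet)
  mols <- mols[vapply(mols, function(m)
    at$species[which(at$molecule_id == m)[1L]] == species, logical(1))]
  if (!length(mols)) stop("species ", species, " not present in the ",
                          leaflet, " leaflet")
  # chain atom index matrix: molecules x chain position
  idx <- t(vapply(mols, function(m) {
    rows <- which(at$molecule_id == m)
    rows[match(chain_names, at$name[rows])]
  }, integer(length(chain_names))))
  carbons <- at$role_index[idx[1L, ]]
  nf <- n_frames(trajectory)
  m <- length(chain_names)
  inner <- 2:(m - 1L)                # carbons with both neighbours
  frame_means <- matrix(NA_real_, nf, length(inner))
  for (k in seq_len(nf)) {
    xyz <- trajectory$coords[, , k]
    v <- xyz[idx[, inner + 1L, drop = FALSE], , drop = FALSE] -
      xyz[idx[, inner - 1L, drop = FALSE], , drop = FALSE]
    dim(v) <- c(length(mols), length(inner), 3L)
    cos2 <- v[, , 3L]^2 / (v[, , 1L]^2 + v[, , 2L]^2 + v[, , 3L]^2)
    frame_means[k, ] <- colMeans((3 * cos2 - 1) / 2)
  }
  scd <- colMeans(frame_means)
  se <- apply(frame_means, 2L, stats::sd) / sqrt(nf)
  out <- data.frame(carbon = carbons[inner], scd = scd, se = se)
  structure(out, class = c("order_profile", "data.frame"),
            species = species, chain = chain, leaflet = leaflet)
}

#' Elementwise difference of two order-parameter profiles
#'
#' @param a,b [chain_order_parameters()] results on identical carbon grids
#' @return data.frame with `carbon` and `dscd` (`a - b`)
#' @export
scd_difference <- function(a, b) {
  if (!identical(a$carbon, b$carbon))
    stop("order profiles cover different carbons")
  data.frame(carbon = a$carbon, dscd = a$scd - b$scd)
}
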
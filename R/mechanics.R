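# Slab-resolved pressure tensor profiles (Irving-Kirkwood straight-line
# contour) and surface tension, validated on toy pair-interaction ensembles.
# The module never runs on force-field trajectories: it exists to make the
# decomposition's defining identities testable.

#' Slab pressure profile of a pair-system ensemble
#'
#' The kinetic term per slab is `rho(z) kB T` (equipartition with the
#' supplied temperature; the configurations carry no velocities). The
#' virial of each pair is distributed along the straight minimum-image line
#' between the two particles: every slab the segment crosses receives the
#' pair's virial tensor scaled by the fraction of the segment inside the
#' slab, divided by the slab volume. `P_N` is the zz component, `P_L` is
#' `(xx + yy) / 2`, and the lateral pressure is `pi(z) = P_L - P_N`.
#'
#' @param systems a [generate_pair_system()] object or list of them (one
#'   ensemble; identical boxes and temperatures)
#' @param n_slabs number of z slabs (>= 2)
#' @return an object of class `"pressure_profile"`: data.frame with `z`
#'   (slab centers, nm), `P_N`, `P_L`, `lateral` (all bar), `kinetic`,
#'   `virial_N`, `virial_L`; attributes `edges`, `box`,
#'   `global_pressure_bar` (ensemble mean of the exact virial pressures)
#' @export
pressure_profile <- function(systems, n_slabs) {
  if (inherits(systems, "pair_system")) systems <- list(systems)
  stopifnot(length(systems) >= 1L, n_slabs >= 2L)
  box <- systems[[1L]]$box
  Tk <- systems[[1L]]$temperature
  for (s in systems)
    if (!isTRUE(all.equal(s$box, box)) || s$temperature != Tk)
      stop("all configurations of the ensemble must share box and temperature")
  Lz <- box[3L]
  dz <- Lz / n_slabs
  if (dz < 0.01) stop("slab width below 0.01 nm")
  edges <- seq(0, Lz, length.out = n_slabs + 1L)
  v_slab <- box[1L] * box[2L] * dz
  kin <- vir_n <- vir_l <- numeric(n_slabs)
  n_wrapped <- 0L
  for (s in systems) {
    z <- s$coords[, 3L]
    out <- z < 0 | z >= Lz
    if (any(out)) { n_wrapped <- n_wrapped + sum(out); z <- z %% Lz }
    bi <- pmin(pmax(findInterval(z, edges, rightmost.closed = TRUE), 1L),
               n_slabs)
    kin <- kin + tabulate(bi, n_slabs) * .kB * Tk / v_slab
    p <- s$pairs
    if (nrow(p)) {
      frac <- .ik_fractions(z[p$i], z[p$i] - p$dz, edges, Lz)
      vir_n <- vir_n + drop(crossprod(frac, p$dz * p$fz)) / v_slab
      vir_l <- vir_l + drop(crossprod(frac, (p$dx * p$fx + p$dy * p$fy) / 2)) /
        v_slab
    }
  }
  if (n_wrapped > 0L)
    warning(n_wrapped, " particle(s) outside the box were wrapped")
  nens <- length(systems)
  kin <- kin / nens; vir_n <- vir_n / nens; vir_l <- vir_l / nens
  out <- data.frame(z = (edges[-1L] + edges[-length(edges)]) / 2,
                    P_N = (kin + vir_n) * .PRESSURE_BAR,
                    P_L = (kin + vir_l) * .PRESSURE_BAR,
                    kinetic = kin * .PRESSURE_BAR,
                    virial_N = vir_n * .PRESSURE_BAR,
                    virial_L = vir_l * .PRESSURE_BAR)
  out$lateral <- out$P_L - out$P_N
  structure(out, class = c("pressure_profile", "data.frame"),
            edges = edges, box = box,
            global_pressure_bar = mean(vapply(systems, `[[`, numeric(1),
                                              "pressure_bar")))
}

# fraction of each pair's straight minimum-image segment inside each slab,
# with periodic wrapping of the segment along z. Rows sum to exactly 1.
.ik_fractions <- function(z1, z2, edges, Lz) {
  lo <- pmin(z1, z2)
  hi <- pmax(z1, z2)
  len <- hi - lo
  n_slabs <- length(edges) - 1L
  el <- edges[-length(edges)]
  eh <- edges[-1L]
  ov <- matrix(0, length(lo), n_slabs)
  for (shift in c(-Lz, 0, Lz)) {
    a <- lo + shift; b <- hi + shift
    ov <- ov + pmax(0, outer(b, eh, pmin) - outer(a, el, pmax))
  }
  pointlike <- len < 1e-12
  if (any(pointlike)) {
    zi <- pmin(pmax(findInterval(z1[pointlike] %% Lz, edges,
                                 rightmost.closed = TRUE), 1L), n_slabs)
    ov[pointlike, ] <- 0
    ov[cbind(which(pointlike), zi)] <- 1
  }
  ov / rowSums(ov)
}

#' Surface tension from a pressure profile
#'
#' `gamma = integral (P_N(z) - P_L(z)) dz`, evaluated as the slab sum
#' `sum (P_N - P_L) * dz` (the exact quadrature for slab-averaged data),
#' converted to mN/m (1 bar nm = 0.1 mN/m).
#'
#' @param profile a [pressure_profile()] spanning the full box
#' @return surface tension, mN/m
#' @export
surface_tension <- function(profile) {
  edges <- attr(profile, "edges")
  dz <- diff(edges)
  sum((profile$P_N - profile$P_L) * dz) * .TENSION_MN_M
}

#' Elementwise difference of two pressure profiles
#'
#' @param a,b [pressure_profile()] results on identical slab grids
#' @return a `"pressure_profile"` holding `a - b` in every component
#' @export
profile_difference <- function(a, b) {
  ea <- attr(a, "edges"); eb <- attr(b, "edges")
  if (length(ea) != length(eb) || max(abs(ea - eb)) > 1e-9)
    stop("slab grids differ (", length(ea) - 1L, " vs ", length(eb) - 1L,
         " slabs)")
  out <- a
  for (col in c("P_N", "P_L", "lateral", "kinetic", "virial_N", "virial_L"))
    out[[col]] <- a[[col]] - b[[col]]
  attr(out, "global_pressure_bar") <-
    attr(a, "global_pressure_bar") - attr(b, "global_pressure_bar")
  out
}
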
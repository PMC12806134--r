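# Programmatic fixtures: tiny topologies and trajectories built in code.

# one-chain test lipid: head (headgroup_ref) + carbons 2..n_carbons
make_chain_topology <- function(n_mol = 1L, n_carbons = 8L,
                                species = "TST") {
  rows <- list()
  aid <- 0L
  for (m in seq_len(n_mol)) {
    rows[[m]] <- data.frame(
      atom_id = aid + seq_len(n_carbons),
      name = c("P", paste0("C", 2:n_carbons)),
      species = species, molecule_id = m,
      mass = c(100, rep(14, n_carbons - 1L)),
      charge = 0,
      role = c("headgroup_ref", rep("tail_carbon", n_carbons - 1L)),
      role_index = c(NA_integer_, 2:n_carbons),
      stringsAsFactors = FALSE)
    aid <- aid + n_carbons
  }
  topology(do.call(rbind, rows),
           species_meta = list(TST = list(
             is_sterol = FALSE,
             chains = list(paste0("C", 2:n_carbons)),
             headgroup_charge = 0)))
}

# chain trajectory with every carbon placed along a fixed direction `u`
# (so every C(i-1)->C(i+1) chord points along u); heads at +/- z0
make_straight_chain_traj <- function(u, n_mol = 2L, n_carbons = 8L,
                                     z0 = 1.9, box = c(5, 5, 10)) {
  topo <- make_chain_topology(n_mol, n_carbons)
  u <- u / sqrt(sum(u^2))
  coords <- array(NA_real_, c(n_mol * n_carbons, 3L, 1L))
  for (m in seq_len(n_mol)) {
    s <- if (m %% 2L) 1 else -1
    head <- c(1 + 0.5 * m, 1, s * z0)
    idx <- (m - 1L) * n_carbons + seq_len(n_carbons)
    for (k in seq_len(n_carbons))
      coords[idx[k], , 1L] <- head + (k - 1L) * 0.13 * u * c(1, 1, -s)
  }
  trajectory(topo, coords, box, dt = 100)
}

# water-only topology (single-site waters)
make_water_topology <- function(n_waters) {
  topology(data.frame(
    atom_id = seq_len(n_waters), name = "OW", species = "WAT",
    molecule_id = seq_len(n_waters), mass = 18.015, charge = 0,
    role = "water_oxygen", role_index = NA_integer_,
    stringsAsFactors = FALSE))
}

# waters following prescribed z paths (matrix: waters x frames)
make_water_traj <- function(z_paths, box = c(5, 5, 10), dt = 100) {
  n <- nrow(z_paths); nf <- ncol(z_paths)
  topo <- make_water_topology(n)
  coords <- array(NA_real_, c(n, 3L, nf))
  coords[, 1L, ] <- 1; coords[, 2L, ] <- 1
  coords[, 3L, ] <- z_paths
  trajectory(topo, coords, box, dt = dt)
}

# quiescent waters jittering outside the hydrophobic bounds
make_quiescent_waters <- function(n_waters, nf, bounds = c(-1.5, 1.5),
                                  Lz = 10, dt = 100) {
  hi <- bounds[2L]; lo <- bounds[1L]
  side <- rep(c(1, -1), length.out = n_waters)
  base <- ifelse(side > 0, runif(n_waters, hi + 0.4, Lz / 2 - 0.4),
                 runif(n_waters, -Lz / 2 + 0.4, lo - 0.4))
  z <- matrix(NA_real_, n_waters, nf)
  state <- numeric(n_waters)
  for (k in seq_len(nf)) {
    state <- 0.8 * state + rnorm(n_waters, 0, 0.05)
    zk <- base + state
    z[, k] <- ifelse(side > 0, pmin(pmax(zk, hi + 0.1), Lz / 2 - 0.1),
                     pmin(pmax(zk, -Lz / 2 + 0.1), lo - 0.1))
  }
  make_water_traj(z, box = c(5, 5, Lz), dt = dt)
}

# handcrafted charge-weighted density profile on a uniform grid with a bin
# center at every multiple of bin_width (edges offset by bin_width / 2)
make_charge_profile <- function(rho_fun, zmax = 5, bin_width = 0.05) {
  edges <- seq(-zmax - bin_width / 2, zmax + bin_width / 2, by = bin_width)
  z <- (edges[-1L] + edges[-length(edges)]) / 2
  out <- data.frame(z = z, density = rho_fun(z))
  structure(out, class = c("density_profile", "data.frame"),
            edges = edges, bin_width = bin_width, weight = "charge",
            area = 25, label = "fixture", total = NA_real_)
}

# sheet charges realised on the fixture grid (sigma e/nm^2 at centers z0)
sheet_density <- function(z0, sigma, bin_width = 0.05) {
  function(z) {
    rho <- numeric(length(z))
    for (j in seq_along(z0)) {
      i <- which.min(abs(z - z0[j]))
      rho[i] <- rho[i] + sigma[j] / bin_width
    }
    rho
  }
}

# z-reflect a trajectory
reflect_z <- function(traj) {
  traj$coords[, 3L, ] <- -traj$coords[, 3L, ]
  traj
}
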
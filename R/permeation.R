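# Water permeation event detection, directionality and dwell times.

#' Hydrophobic region bounds
#'
#' @param lower,upper z bounds, nm (`lower < upper`)
#' @param label region label (`"membrane"`, or `"lower"`/`"upper"` for
#'   double-bilayer systems)
#' @return an object of class `"hydrophobic_region"`
#' @export
hydrophobic_region <- function(lower, upper, label = "membrane") {
  if (!(lower < upper)) stop("hydrophobic region needs lower < upper")
  structure(list(lower = lower, upper = upper, label = label),
            class = "hydrophobic_region")
}

#' Locate the hydrophobic region(s) of a membrane
#'
#' `tail_density`: computes the tail-carbon mass density along z and places
#' the bounds at the outermost z where it exceeds 50% of its plateau
#' (maximum) value; double-bilayer systems yield two regions found as
#' separated density plateaus. `explicit`: passes the supplied bounds
#' through unchanged.
#'
#' @param trajectory a recentred [trajectory()]
#' @param method `"tail_density"` or `"explicit"`
#' @param bounds for `explicit`: `c(lower, upper)` or a list of them
#' @param bin_width density bin width, nm
#' @return list of [hydrophobic_region()]s
#' @export
hydrophobic_bounds <- function(trajectory, method = c("tail_density", "explicit"),
                               bounds = NULL, bin_width = 0.1) {
  method <- match.arg(method)
  if (method == "explicit") {
    if (is.null(bounds)) stop("explicit method needs bounds")
    if (!is.list(bounds)) bounds <- list(bounds)
    labs <- if (length(bounds) == 1L) "membrane" else c("lower", "upper")
    return(lapply(seq_along(bounds), function(i) {
      b <- bounds[[i]]
      if (inherits(b, "hydrophobic_region")) b else
        hydrophobic_region(b[1L], b[2L], labs[i])
    }))
  }
  sel <- select_atoms(trajectory, role = "tail_carbon")
  if (!length(sel)) stop("no tail density detected (no tail_carbon atoms)")
  prof <- density_profile(trajectory, sel, bin_width = bin_width,
                          weight = "mass", label = "tail carbons")
  thr <- 0.5 * max(prof$density)
  above <- prof$density > thr
  runs <- rle(above)
  run_id <- rep(seq_along(runs$lengths), runs$lengths)
  reg_ids <- unique(run_id[above])
  # merge above-threshold runs separated by gaps < 1.5 nm: the tail density
  # of a single bilayer dips at the midplane where opposing termini meet,
  # while genuinely separate membranes sit several nm of water apart
  merged <- list()
  for (rid in reg_ids) {
    i <- range(which(run_id == rid))
    lower <- attr(prof, "edges")[i[1L]]
    upper <- attr(prof, "edges")[i[2L] + 1L]
    if (length(merged) && lower - merged[[length(merged)]][2L] < 1.5)
      merged[[length(merged)]][2L] <- upper
    else merged[[length(merged) + 1L]] <- c(lower, upper)
  }
  if (!length(merged)) stop("no tail density detected")
  if (length(merged) > 2L)
    stop("hydrophobic plateaus not separable (found ", length(merged),
         " candidate regions)")
  labs <- if (length(merged) == 1L) "membrane" else c("lower", "upper")
  lapply(seq_along(merged), function(i)
    hydrophobic_region(merged[[i]][1L], merged[[i]][2L], labs[i]))
}

#' Detect water permeation events
#'
#' A finite-state machine per molecule per region: a molecule OUTSIDE on
#' side s becomes INSIDE when it crosses that side's bound between
#' consecutive frames; an event is emitted when it exits through the
#' *opposite* bound (direction given by the entry side: entering from above
#' (+z) and leaving below is `outer_to_inner`), and the state resets when
#' it exits through the same bound. Paths that wrap through the periodic
#' box boundary outside the membrane never traverse the region and emit
#' nothing. The dwell time counts frames strictly inside the open interval
#' times the frame spacing. Ion selections can be screened with the same
#' machinery via `selection`.
#'
#' @param trajectory a recentred [trajectory()] with constant frame spacing
#' @param regions a [hydrophobic_region()] or list of them
#' @param selection atom indices to track; defaults to all `water_oxygen`
#'   atoms
#' @return data.frame with columns `water_id`, `membrane`, `direction`,
#'   `entry_frame`, `exit_frame`, `dwell_ns`
#' @export
detect_permeation_events <- function(trajectory, regions,
                                     selection = NULL) {
  if (inherits(regions, "hydrophobic_region")) regions <- list(regions)
  if (is.null(selection))
    selection <- select_atoms(trajectory, role = "water_oxygen")
  nf <- n_frames(trajectory)
  if (nf >= 2L) {
    dts <- diff(trajectory$time)
    if (max(abs(dts - dts[1L])) > 1e-9 * max(dts))
      stop("frame gap detected: times are not evenly spaced")
  }
  at <- trajectory$topology$atoms
  dt_ns <- trajectory$dt / 1000
  res <- list()
  for (reg in regions) {
    lo <- reg$lower; hi <- reg$upper
    for (ai in selection) {
      z <- trajectory$coords[ai, 3L, ]
      Lz <- trajectory$box[, 3L]
      zone <- ifelse(z >= hi, 1L, ifelse(z <= lo, -1L, 0L))
      state <- zone[1L]           # -1 below, +1 above, 0 inside (side unknown)
      entry_side <- 0L; entry_frame <- NA_integer_; n_inside <- 0L
      discard <- state == 0L      # started inside: side unknown, no event
      for (k in 2:nf) {
        dz <- z[k] - z[k - 1L]
        dz_mi <- dz - Lz[k] * round(dz / Lz[k])
        if (zone[k] == 0L) {
          if (state != 0L) {      # entering
            entry_side <- state; entry_frame <- k; n_inside <- 1L
            discard <- FALSE
          } else {
            n_inside <- n_inside + 1L
            if (abs(dz) > Lz[k] / 2 && !discard) {
              warning("molecule ", at$molecule_id[ai],
                      " wrapped inside the region; event discarded")
              discard <- TRUE
            }
          }
          state <- 0L
        } else {
          if (state == 0L) {      # exiting
            if (!discard && entry_side != 0L && zone[k] == -entry_side) {
              res[[length(res) + 1L]] <- data.frame(
                water_id = at$molecule_id[ai], membrane = reg$label,
                direction = if (entry_side > 0L) "outer_to_inner"
                            else "inner_to_outer",
                entry_frame = entry_frame, exit_frame = k,
                dwell_ns = n_inside * dt_ns, stringsAsFactors = FALSE)
            }
            state <- zone[k]; entry_side <- 0L; n_inside <- 0L
            discard <- FALSE
          } else if (zone[k] != state) {
            # outside -> outside on the other side: through the region or
            # around the periodic boundary?
            traversed <- abs(dz) <= Lz[k] / 2
            if (traversed) {
              res[[length(res) + 1L]] <- data.frame(
                water_id = at$molecule_id[ai], membrane = reg$label,
                direction = if (state > 0L) "outer_to_inner"
                            else "inner_to_outer",
                entry_frame = k - 1L, exit_frame = k,
                dwell_ns = 0, stringsAsFactors = FALSE)
            }
            state <- zone[k]
          }
        }
      }
    }
  }
  if (!length(res))
    return(data.frame(water_id = integer(0), membrane = character(0),
                      direction = character(0), entry_frame = integer(0),
                      exit_frame = integer(0), dwell_ns = numeric(0)))
  do.call(rbind, res)
}

#' Dwell-time histogram and per-direction counts
#'
#' @param events a [detect_permeation_events()] table
#' @param bin_width dwell-time bin width, ns
#' @return list with `histogram` (data.frame `bin_lo`, `bin_hi`, `count`),
#'   `counts` (by direction), `by_membrane` (direction x membrane table),
#'   `dwell_range` and `dwell_mode` (center of the maximal bin), ns
#' @export
dwell_time_stats <- function(events, bin_width = 0.25) {
  dirs <- c("outer_to_inner", "inner_to_outer")
  counts <- vapply(dirs, function(d) sum(events$direction == d), integer(1))
  if (!nrow(events))
    return(list(histogram = data.frame(bin_lo = numeric(0),
                                       bin_hi = numeric(0),
                                       count = integer(0)),
                counts = counts, by_membrane = table(character(0)),
                dwell_range = c(NA_real_, NA_real_),
                dwell_mode = NA_real_))
  breaks <- seq(0, max(events$dwell_ns) + bin_width, by = bin_width)
  bi <- findInterval(events$dwell_ns, breaks, rightmost.closed = TRUE)
  hist_counts <- tabulate(bi, length(breaks) - 1L)
  list(histogram = data.frame(bin_lo = breaks[-length(breaks)],
                              bin_hi = breaks[-1L],
                              count = hist_counts),
       counts = counts,
       by_membrane = table(events$direction, events$membrane),
       dwell_range = range(events$dwell_ns),
       dwell_mode = breaks[which.max(hist_counts)] + bin_width / 2)
}
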
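# Config-driven orchestration: generation -> analysis -> exported tables.
# CSV for profiles and tables, JSON for scalar summaries; one seed governs
# every stage through deterministic per-stage derivation.

.PIPELINE_STAGES <- c("generate", "plan", "structure", "mechanics",
                      "potential", "permeation")

.stage_seed <- function(seed, stage) {
  (as.integer(seed) * 131L + match(stage, .PIPELINE_STAGES) * 7919L) %%
    2147483647L
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
}

#' Run the analysis pipeline from a config
#'
#' Executes the requested stages in order and writes per-stage CSV/JSON
#' outputs plus a run log and a combined `summary.json` into the output
#' directory. The config is a named list (or a path to a YAML file) with at
#' least `outdir` and `stages`; a `seed` is mandatory whenever the
#' `generate` stage is present. Identical configs and seeds produce
#' byte-identical summaries.
#'
#' Recognised blocks: `generate` ([bilayer_spec()] overrides plus
#' `n_frames`), `structure` (`species`, `chain`, `bin_width`),
#' `mechanics` (`n_particles`, `box`, `n_configs`, `n_slabs`,
#' `arrangement`), `potential` (`interior`, `exterior` region bounds, nm),
#' `permeation` (`bounds` or `tail_density`), `plan` (areas, fractions,
#' `apl`, `stress_percent`), and `input` (`trajectory`, `topology`, `dt`
#' for analysis-only runs).
#'
#' @param config named list or YAML file path
#' @return invisibly, the list of stage results (also serialised to disk)
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stages <- config$stages
  unknown <- setdiff(stages, .PIPELINE_STAGES)
  if (length(unknown))
    stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  if ("generate" %in% stages && is.null(config$seed))
    stop("a seed is mandatory when the generate stage is present")
  if (is.null(config$outdir)) stop("config needs an outdir")
  if (!is.null(config$input$trajectory) &&
      !file.exists(config$input$trajectory))
    stop("input trajectory not found: ", config$input$trajectory)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  results <- list()
  summary <- list(package = "asymem",
                  version = as.character(utils::packageVersion("asymem")),
                  seed = config$seed, stages = stages,
                  observables = list())
  traj <- NULL; gt <- NULL; leaf <- NULL
  ensure_traj <- function() {
    if (!is.null(traj)) return(invisible())
    if (is.null(config$input$trajectory))
      stop("stage needs a trajectory: add a generate stage or input$trajectory")
    topo <- if (!is.null(config$input$topology))
      read_topology(config$input$topology) else NULL
    traj <<- read_coordinates(config$input$trajectory, topology = topo,
                              dt = config$input$dt %||% 100)
    traj <<- recenter_frames(traj)
    leaf <<- assign_leaflets(traj)
    invisible()
  }

  run_stage <- function(stage) {
    switch(stage,
      generate = {
        g <- config$generate %||% list()
        n_frames <- g$n_frames %||% 100L
        g$n_frames <- NULL
        g$seed <- .stage_seed(config$seed, "generate")
        if (!is.null(g$charge_profile))
          g$charge_profile <- as.data.frame(g$charge_profile)
        spec <- do.call(bilayer_spec, g)
        gen <- generate_bilayer_trajectory(spec, n_frames = n_frames)
        traj <<- gen$trajectory; gt <<- gen$ground_truth
        leaf <<- assign_leaflets(traj)
        .write_json(gt[c("thickness_nm", "tilt_mode_deg", "area_sd_nm2",
                         "analytic_potential_step_mV")],
                    file.path(outdir, "ground_truth.json"))
        first <- trajectory(traj$topology, traj$coords[, , 1L, drop = FALSE],
                            traj$box[1L, ], dt = traj$dt)
        write_coordinates(first, file.path(outdir, "structure.gro"), "gro")
        summary$observables$n_frames <<- n_frames
        summary$observables$n_atoms <<- n_atoms(traj)
        list(spec = spec)
      },
      plan = {
        p <- config$plan
        if (is.null(p)) stop("plan stage needs a plan config block")
        apl <- unlist(p$apl %||% c(POPC = 0.6, PSM = 0.6, POPE = 0.6,
                                   POPS = 0.6, CHOL = 0.3))
        amo <- area_match_offsets(p$area_outer, p$area_inner,
                                  p$leaflet_to_adjust %||% "outer",
                                  apl, unlist(p$fractions))
        out <- list(offset = amo$offset,
                    delta_counts = as.list(amo$delta_counts),
                    mean_apl = amo$mean_apl,
                    residual_area = amo$residual_area)
        .write_json(out, file.path(outdir, "plan.json"))
        summary$observables$area_match_offset <<- amo$offset
        out
      },
      structure = {
        ensure_traj()
        s <- config$structure %||% list()
        area <- lateral_area_stats(traj, leaf)
        heads <- select_atoms(traj, role = "headgroup_ref")
        dens <- density_profile(traj, heads, bin_width = s$bin_width %||% 0.1,
                                label = "headgroups")
        thick <- membrane_thickness(dens)
        utils::write.csv(as.data.frame(dens),
                         file.path(outdir, "density_headgroups.csv"),
                         row.names = FALSE)
        species <- s$species %||% "CHOL"
        tilt <- tilt_distribution(traj, species, leaf,
                                  leaflet = s$leaflet %||% "outer")
        scd_sp <- s$scd_species %||% "POPC"
        ord <- chain_order_parameters(traj, scd_sp, chain = s$chain %||% 1L,
                                      leaflets = leaf,
                                      leaflet = s$leaflet %||% "inner")
        utils::write.csv(as.data.frame(ord),
                         file.path(outdir, "order_parameters.csv"),
                         row.names = FALSE)
        summary$observables$area_mean_nm2 <<- area$mean
        summary$observables$area_sd_nm2 <<- area$sd
        summary$observables$thickness_nm <<- thick
        summary$observables$tilt_mode_deg <<- tilt$mode_deg
        summary$observables$scd_mean <<- mean(ord$scd)
        list(area = area, thickness = thick, tilt = tilt, order = ord)
      },
      mechanics = {
        m <- config$mechanics %||% list()
        n_cfg <- m$n_configs %||% 20L
        seed0 <- .stage_seed(config$seed %||% 0L, "mechanics")
        systems <- lapply(seq_len(n_cfg), function(i)
          generate_pair_system(m$n_particles %||% 200L,
                               box = unlist(m$box %||% c(6, 6, 6)),
                               arrangement = m$arrangement %||% "bulk_fluid",
                               seed = seed0 + i))
        prof <- pressure_profile(systems, n_slabs = m$n_slabs %||% 30L)
        utils::write.csv(as.data.frame(prof),
                         file.path(outdir, "pressure_profile.csv"),
                         row.names = FALSE)
        gamma <- surface_tension(prof)
        summary$observables$surface_tension_mN_m <<- gamma
        summary$observables$global_pressure_bar <<-
          attr(prof, "global_pressure_bar")
        list(profile = prof, gamma = gamma)
      },
      potential = {
        ensure_traj()
        pot_cfg <- config$potential %||% list()
        qdens <- density_profile(traj, seq_len(n_atoms(traj)),
                                 bin_width = pot_cfg$bin_width %||% 0.1,
                                 weight = "charge", label = "all atoms")
        pot <- potential_profile(qdens)
        Lz <- max(traj$box[, 3L])
        regions <- region_spec(pot_cfg$interior %||% 1.0,
                               pot_cfg$exterior %||% (Lz / 2 - 1.0))
        dpsi <- region_potential_difference(pot, regions)
        utils::write.csv(as.data.frame(pot),
                         file.path(outdir, "potential_profile.csv"),
                         row.names = FALSE)
        summary$observables$delta_psi_mV <<- dpsi
        list(profile = pot, delta_psi = dpsi)
      },
      permeation = {
        ensure_traj()
        pm <- config$permeation %||% list()
        regions <- if (!is.null(pm$bounds))
          hydrophobic_bounds(traj, "explicit", bounds = pm$bounds)
        else hydrophobic_bounds(traj, "tail_density")
        events <- detect_permeation_events(traj, regions)
        stats <- dwell_time_stats(events, bin_width = pm$bin_width %||% 0.25)
        utils::write.csv(events, file.path(outdir, "permeation_events.csv"),
                         row.names = FALSE)
        utils::write.csv(stats$histogram,
                         file.path(outdir, "dwell_histogram.csv"),
                         row.names = FALSE)
        summary$observables$permeation_events <<- nrow(events)
        summary$observables$permeation_outer_to_inner <<-
          unname(stats$counts[["outer_to_inner"]])
        summary$observables$permeation_inner_to_outer <<-
          unname(stats$counts[["inner_to_outer"]])
        list(events = events, stats = stats)
      })
  }

  for (stage in stages) {
    results[[stage]] <- tryCatch(run_stage(stage), error = function(e) {
      writeLines(c(stage, conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  writeLines(c(paste("asymem", summary$version),
               paste("seed:", config$seed %||% "none"),
               "config:", yaml::as.yaml(config)),
             file.path(outdir, "run_log.txt"))
  .write_json(summary, file.path(outdir, "summary.json"))
  invisible(results)
}

#' Cross-model comparison table
#'
#' Collects one observable from several pipeline run directories into a
#' long-form table ready for plotting.
#'
#' @param run_dirs character vector of >= 2 pipeline output directories
#' @param observable name of a summary observable (e.g. `"thickness_nm"`)
#' @return data.frame with `model`, `observable`, `value`
#' @export
compare_models <- function(run_dirs, observable) {
  if (length(run_dirs) < 2L)
    stop("compare_models needs at least 2 run directories")
  rows <- lapply(run_dirs, function(d) {
    sp <- file.path(d, "summary.json")
    if (!file.exists(sp)) stop("no summary.json in ", d)
    s <- jsonlite::read_json(sp, simplifyVector = TRUE)
    if (!observable %in% names(s$observables))
      stop("observable '", observable, "' absent in ", d)
    data.frame(model = basename(normalizePath(d, mustWork = FALSE)),
               observable = observable,
               value = as.numeric(s$observables[[observable]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
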
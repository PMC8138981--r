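#' Demonstration-run configuration
#'
#' Parameters for [run_demo()]. Unknown keys are rejected so config files
#' fail loudly rather than silently ignoring typos. The configuration
#' round-trips unchanged through YAML ([write_run_config()] /
#' [read_run_config()]).
#'
#' @param seed Global seed; per-stage seeds are derived deterministically
#'   as `seed * 100 + stage index` (stages: 1 FRET, 2 conformation,
#'   3 force profile, 4 ddG) so stages stay independent yet reproducible.
#' @param out_dir Output directory (created if needed).
#' @param transfer_preset Transfer-function preset evaluated in the
#'   summary.
#' @param efficiency_grid True efficiencies for the FRET round trip.
#' @param traj_steps Langevin steps per conformational trajectory.
#' @param state_boundary Angle boundary for N/T classification, degrees.
#' @param fpa_replicates Replicates per force-profile construct.
#' @param ddg_runs,ddg_moves Ensemble ddG problem size.
#' @param make_plots Write PNG figures (skipped automatically when no PNG
#'   device is available).
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(seed = 1,
                       out_dir = file.path(tempdir(), "foldsense_demo"),
                       transfer_preset = "hek_cfp_yfp",
                       efficiency_grid = seq(0, 0.9, by = 0.1),
                       traj_steps = 20000,
                       state_boundary = 70,
                       fpa_replicates = 3,
                       ddg_runs = 8,
                       ddg_moves = 4000,
                       make_plots = TRUE) {
  cfg <- list(seed = seed, out_dir = out_dir,
              transfer_preset = transfer_preset,
              efficiency_grid = efficiency_grid,
              traj_steps = traj_steps, state_boundary = state_boundary,
              fpa_replicates = fpa_replicates,
              ddg_runs = ddg_runs, ddg_moves = ddg_moves,
              make_plots = make_plots)
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  if (!transfer_preset %in% c("hek_cfp_yfp", "bact_tfp_venus"))
    stop("unknown transfer preset: ", transfer_preset)
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param cfg A `"run_config"`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' End-to-end demonstration run
#'
#' Chains the full pipeline on synthetic data with known ground truth:
#' (1) forward-simulated CFP/YFP spectral stacks are unmixed, indexed, and
#' mapped to efficiency through a freshly derived transfer function
#' (round-trip error reported) and through the named preset; (2) reference
#' and mutant-like angle trajectories are sampled, classified into N/T
#' states and converted to free-energy profiles (Boltzmann inversion for
#' both, WHAM over umbrella windows for the mutant-like landscape); (3)
#' force-profile libraries are simulated for the three scenarios and peak
#' calls made; (4) the ensemble Metropolis ddG is run on the toy models.
#' Tables are written as CSV, figures as PNG, and a deterministic JSON
#' summary collects the headline statistics.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the summary list; side effect: files in
#'   `cfg$out_dir`.
#' @export
run_demo <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_seed <- function(k) as.integer(cfg$seed * 100 + k)
  summary <- list(config = unclass(cfg))

  ## Stage 1: spectral FRET round trip -----------------------------------
  donor <- fluorophore_preset("mCFP")
  acceptor <- fluorophore_preset("mCitrine")
  pair <- forster_pair(donor, acceptor)
  tf_fit <- derive_transfer_function(pair)
  scene <- ground_truth_scene(cfg$efficiency_grid, noise = "none")
  stack <- simulate_spectral_stack(donor, acceptor, scene)
  um <- unmix(stack, band_reference(donor, stack$band_edges),
              band_reference(acceptor, stack$band_edges))
  idx <- fret_index_integral(um)
  e_est <- apply_transfer(tf_fit, idx)
  preset <- transfer_preset(cfg$transfer_preset)
  fret_tab <- data.frame(true_efficiency = cfg$efficiency_grid,
                         fret_index = idx,
                         efficiency_fitted_tf = e_est,
                         efficiency_preset_tf = apply_transfer(preset, idx))
  utils::write.csv(fret_tab, file.path(cfg$out_dir, "fret_round_trip.csv"),
                   row.names = FALSE)
  summary$fret <- list(
    forster_radius_A = round(pair$R0, 2),
    transfer_fit = list(a = round(tf_fit$a, 6), b = round(tf_fit$b, 6),
                        c = round(tf_fit$c, 6),
                        r_squared = round(tf_fit$r_squared, 6)),
    round_trip_max_abs_error = round(max(abs(e_est - cfg$efficiency_grid)), 6),
    preset = cfg$transfer_preset,
    preset_efficiency_at_zero_index = apply_transfer(preset, 0))

  ## Stage 2: conformational landscapes ----------------------------------
  pots <- list(wt = dw_preset("wt"), w344r = dw_preset("w344r"))
  conf <- list()
  for (nm in names(pots)) {
    traj <- simulate_double_well_trajectory(pots[[nm]],
                                            n_steps = cfg$traj_steps,
                                            seed = stage_seed(2) +
                                              match(nm, names(pots)))
    st <- classify_states(traj, boundaries = cfg$state_boundary)
    p <- pmf_boltzmann(traj)
    write_pmf_csv(p, file.path(cfg$out_dir, sprintf("pmf_%s.csv", nm)))
    write_trajectory_csv(traj, file.path(cfg$out_dir,
                                         sprintf("trajectory_%s.csv", nm)))
    conf[[nm]] <- list(populations = round(st$populations, 4),
                       n_transitions = st$n_transitions)
  }
  wins <- simulate_umbrella_windows(pots$w344r,
                                    centers = seq(20, 160, by = 10),
                                    spring_k = 0.05,
                                    n_steps = max(2000, cfg$traj_steps %/% 4),
                                    seed = stage_seed(2) + 10L)
  wham <- pmf_wham(wins, tol = 1e-6)
  write_pmf_csv(wham, file.path(cfg$out_dir, "pmf_w344r_wham.csv"))
  def <- wham[wham$defined, ]
  conf$wham_minima_deg <- local({
    lowT <- def$bin_center < cfg$state_boundary
    c(T = def$bin_center[lowT][which.min(def$free_energy[lowT])],
      N = def$bin_center[!lowT][which.min(def$free_energy[!lowT])])
  })
  summary$conformation <- conf

  ## Stage 3: force profiles ---------------------------------------------
  fpa <- list()
  profiles <- list()
  for (nm in c("wt_cam", "w344r_cam", "no_cam")) {
    constructs <- simulate_fpa_profile(fpa_preset(nm),
                                       n_replicates = cfg$fpa_replicates,
                                       condition = nm,
                                       seed = stage_seed(3) +
                                         match(nm, c("wt_cam", "w344r_cam",
                                                     "no_cam")))
    prof <- build_profile(constructs)
    profiles[[nm]] <- prof
    pk <- profile_peak(prof)
    fpa[[nm]] <- list(peak_tether_length = if (is.na(pk)) "none" else pk)
  }
  all_prof <- do.call(rbind, lapply(names(profiles), function(nm)
    cbind(condition = nm, as.data.frame(profiles[[nm]]))))
  utils::write.csv(all_prof, file.path(cfg$out_dir, "fpa_profiles.csv"),
                   row.names = FALSE)
  summary$force_profile <- fpa

  ## Stage 4: ensemble ddG -----------------------------------------------
  ddg <- metropolis_ensemble_ddg(toy_model_preset("wt"),
                                 toy_model_preset("w344r"),
                                 n_runs = cfg$ddg_runs,
                                 n_moves = cfg$ddg_moves,
                                 seed = stage_seed(4))
  utils::write.csv(data.frame(run = seq_len(ddg$n_runs),
                              dg_wt = ddg$dg_wt_runs,
                              dg_mut = ddg$dg_mut_runs),
                   file.path(cfg$out_dir, "ddg_runs.csv"), row.names = FALSE)
  summary$ddg <- list(ddg = round(ddg$ddg, 4),
                      dg_wt = round(ddg$dg_wt, 4),
                      dg_mut = round(ddg$dg_mut, 4),
                      sign = if (ddg$ddg > 0) "reference binds more strongly"
                             else "mutation binds more strongly")

  ## Figures ---------------------------------------------------------------
  if (isTRUE(cfg$make_plots) && capabilities("png")) {
    demo_plots(cfg$out_dir, fret_tab, profiles)
  }

  jsonlite::write_json(summary,
                       file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(summary)
}

demo_plots <- function(out_dir, fret_tab, profiles) {
  grDevices::png(file.path(out_dir, "fret_round_trip.png"), 600, 500)
  graphics::plot(fret_tab$true_efficiency, fret_tab$efficiency_fitted_tf,
                 xlab = "true efficiency", ylab = "recovered efficiency",
                 main = "FRET index calibration round trip", pch = 19)
  graphics::abline(0, 1, lty = 2)
  grDevices::dev.off()
  grDevices::png(file.path(out_dir, "fpa_profiles.png"), 600, 500)
  cols <- c(wt_cam = "black", w344r_cam = "grey50", no_cam = "grey80")
  ylim <- range(unlist(lapply(profiles, function(p) p$ratio)))
  graphics::plot(NA, xlim = range(profiles[[1]]$tether_length), ylim = ylim,
                 xlab = "tether length (residues)",
                 ylab = "full-length ratio",
                 main = "Force profiles")
  for (nm in names(profiles))
    graphics::lines(profiles[[nm]]$tether_length, profiles[[nm]]$ratio,
                    type = "b", col = cols[[nm]], pch = 19)
  graphics::legend("topright", legend = names(profiles),
                   col = cols[names(profiles)], lty = 1, pch = 19)
  grDevices::dev.off()
  invisible(NULL)
}
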
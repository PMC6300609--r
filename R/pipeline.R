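#' Build a run configuration
#'
#' Exactly one of `sim` (a [sim_config()]) or `input` (a list with `path` and
#' optionally `dialect` = "default"/"thunderstorm" and `axis`, an
#' [axis_spec()]) must be given.
#'
#' @param sim A [sim_config()] for synthetic runs, or NULL.
#' @param input Real-data input description, or NULL.
#' @param frame_interval Frame interval, s (taken from `sim` when present).
#' @param protein `"endov"`, `"hogg1"`, or NULL when `d_ideal` is given.
#' @param d_ideal Sliding speed limit, um^2/s; overrides the protein preset.
#' @param t_low,t_high Activation-energy mode thresholds, k_B T.
#' @param hmm List: `K` (fixed state count) or `K_max` (BIC selection),
#'   `n_restarts`.
#' @param gate,bridge_gate,min_frames,min_range,band Linking and filter
#'   settings (see [link_tracks()], [filter_tracks()]).
#' @param salt_label Optional buffer condition label carried into outputs.
#' @param seed Master seed for the run.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = NULL, input = NULL, frame_interval = NULL,
                       protein = "endov", d_ideal = NULL,
                       t_low = 0.5, t_high = 2.0,
                       hmm = list(K = 3, n_restarts = 5),
                       gate = 600, bridge_gate = 600,
                       min_frames = 5, min_range = 300, band = 200,
                       salt_label = NA_character_, seed = 1) {
  if (is.null(sim) == is.null(input)) {
    stop("exactly one of 'sim' or 'input' must be set")
  }
  if (!is.null(sim)) frame_interval <- sim$frame_interval
  if (is.null(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be positive")
  }
  if (is.null(d_ideal)) {
    if (is.null(protein)) stop("give either a protein preset or d_ideal")
    d_ideal <- hydrodynamic_limit(protein_hydro(protein))
  }
  structure(list(sim = sim, input = input, frame_interval = frame_interval,
                 protein = protein, d_ideal = d_ideal, t_low = t_low,
                 t_high = t_high, hmm = hmm, gate = gate,
                 bridge_gate = bridge_gate, min_frames = min_frames,
                 min_range = min_range, band = band, salt_label = salt_label,
                 seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; a `sim:` block is
#' passed to [sim_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    if (!is.null(y$sim$A_true)) y$sim$A_true <- do.call(rbind, y$sim$A_true)
    y$sim <- do.call(sim_config, y$sim)
  }
  do.call(run_config, y)
}

#' Run the full scanning-mode analysis
#'
#' End-to-end pipeline: obtain localizations (from the synthetic generator,
#' rendered through the localization table format, or from a CSV file), align
#' to the DNA axis, link into trajectories with blink bridging, apply the
#' quality filters, compute instantaneous diffusion, classify modes by
#' activation energy, fit (or select) the diffusion-state HMM, decode state
#' paths, and derive the comparison statistics. Deterministic given the
#' configuration seed.
#'
#' @param cfg A [run_config()].
#' @param out_dir Optional directory for stage artifacts (tracks.csv,
#'   dinst.csv, emodes.csv, states.csv, hmm_model.txt, summary.yaml).
#' @return Object of class `scanmodes_run`: the intermediate artifacts plus a
#'   `summary` list (per-mode occupancy and mean diffusion for both
#'   classifiers, frame-level agreement, transition matrix, reducibility
#'   verdict, switch frequency, rejection counts).
#' @export
run_analysis <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  log_msg <- function(...) message("[scanmodes] ", sprintf(...))

  if (!is.null(cfg$sim)) {
    sim <- cfg$sim
    sim$seed <- cfg$seed
    gen <- simulate_multistate(sim)
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp), add = TRUE)
    render_localizations(gen$tracks, sim, path = tmp)
    locs <- read_localizations(tmp)
    axis <- axis_spec(origin = sim$axis_origin,
                      direction = c(cos(sim$axis_angle_deg * pi / 180),
                                    sin(sim$axis_angle_deg * pi / 180)),
                      length = sim$dna_length_nm)
    truth <- gen$truth
  } else {
    dia <- switch(cfg$input$dialect %||% "default",
                  default = default_dialect(),
                  thunderstorm = thunderstorm_dialect())
    locs <- read_localizations(cfg$input$path, dia)
    axis <- cfg$input$axis %||% fit_axis(locs)
    truth <- NULL
  }
  log_msg("%d localizations", nrow(locs))

  aligned <- align_to_axis(locs, axis)
  linked <- link_tracks(aligned, cfg$frame_interval,
                        gate = cfg$gate, bridge_gate = cfg$bridge_gate)
  filt <- filter_tracks(linked, cfg$min_frames, cfg$min_range, cfg$band)
  tracks <- filt$tracks
  log_msg("%d tracks linked, %d retained (rejected: %s)",
          length(unique(linked$track_id)), length(unique(tracks$track_id)),
          paste(names(filt$rejected), filt$rejected, collapse = ", "))
  if (!nrow(tracks)) stop("pipeline stage 'filter': no tracks survived")

  series <- instantaneous_diffusion(tracks)
  ens <- ensemble_diffusion(series)
  profile <- energy_profile(series, cfg$d_ideal, cfg$t_low, cfg$t_high)
  estats <- mode_statistics(profile, series)

  hmm_cfg <- cfg$hmm
  model <- if (!is.null(hmm_cfg$K_max)) {
    sel <- select_model(tracks, K_max = hmm_cfg$K_max,
                        n_restarts = hmm_cfg$n_restarts %||% 5,
                        seed = cfg$seed + 1L)
    sel$best
  } else {
    sel <- NULL
    fit_hmm(tracks, K = hmm_cfg$K %||% 3,
            n_restarts = hmm_cfg$n_restarts %||% 5, seed = cfg$seed + 1L)
  }
  if (model$degenerate) log_msg("warning: degenerate HMM fit (K = %d)", model$K)
  paths <- decode_states(model, tracks)
  hstats <- trim_and_recompute(paths, series)

  agree <- NA_real_
  hmm_modes <- NULL
  if (model$K == 3) {
    key_p <- paste(paths$track_id, paths$frame)
    key_s <- paste(series$track_id, series$frame)
    hmm_modes <- states_to_modes(paths$state[match(key_s, key_p)])
    agree <- agreement(profile$mode, hmm_modes)
  }
  tmat <- transition_matrix(paths, K = model$K)
  red <- if (all(is.finite(tmat))) reducibility(tmat) else NA_character_
  swf <- switch_frequency(paths, tracks, target = 1)

  summary <- list(
    n_localizations = nrow(locs),
    n_tracks_linked = length(unique(linked$track_id)),
    n_tracks_retained = length(unique(tracks$track_id)),
    rejected = as.list(filt$rejected),
    d_ideal_um2_s = cfg$d_ideal,
    d_ave_um2_s = ens$mean, d_sd_um2_s = ens$sd, d_sem_um2_s = ens$sem,
    energy_modes = estats,
    hmm_K = model$K,
    hmm_bic = model$bic,
    hmm_D_um2_s = model$D,
    hmm_states_trimmed = hstats,
    agreement = agree,
    transition_matrix = tmat,
    reducibility = red,
    switch_per_1000bp = swf,
    salt_label = cfg$salt_label,
    seed = cfg$seed,
    elapsed_s = proc.time()[["elapsed"]] - t0
  )
  run <- structure(list(config = cfg, locs = locs, tracks = tracks,
                        series = series, profile = profile,
                        energy_stats = estats, model = model,
                        selection = sel, paths = paths, hmm_stats = hstats,
                        hmm_modes = hmm_modes, truth = truth,
                        summary = summary),
                   class = "scanmodes_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tracks(run$tracks, file.path(out_dir, "tracks.csv"))
  utils::write.csv(as.data.frame(run$series), file.path(out_dir, "dinst.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(run$profile), file.path(out_dir, "emodes.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(run$paths), file.path(out_dir, "states.csv"),
                   row.names = FALSE)
  m <- run$model
  writeLines(c(
    sprintf("K %d", m$K),
    sprintf("D_um2_s %s", paste(format(m$D, digits = 12), collapse = " ")),
    sprintf("pi %s", paste(format(m$pi, digits = 12), collapse = " ")),
    paste("A", apply(m$A, 1, function(r) paste(format(r, digits = 12), collapse = " "))),
    sprintf("logLik %.6f", m$logLik),
    sprintf("bic %.6f", m$bic),
    sprintf("seed %d", m$seed)
  ), file.path(out_dir, "hmm_model.txt"))
  s <- run$summary
  s$energy_modes <- as.list(as.data.frame(s$energy_modes))
  s$energy_modes$mode <- as.character(s$energy_modes$mode)
  s$hmm_states_trimmed <- as.list(as.data.frame(s$hmm_states_trimmed))
  s$transition_matrix <- apply(s$transition_matrix, 1, as.numeric,
                               simplify = FALSE)
  yaml::write_yaml(s, file.path(out_dir, "summary.yaml"), precision = 12)
  invisible(out_dir)
}

#' @export
print.scanmodes_run <- function(x, ...) {
  s <- x$summary
  cat("scanmodes run:", s$n_tracks_retained, "tracks,",
      nrow(x$series), "assigned frames\n")
  cat(sprintf("  D_ave = %.4g +/- %.4g um^2/s; D_ideal = %.4g\n",
              s$d_ave_um2_s, s$d_sd_um2_s, s$d_ideal_um2_s))
  cat("  energy-mode occupancies:",
      paste(sprintf("%s %.3f", x$energy_stats$mode, x$energy_stats$occupancy),
            collapse = ", "), "\n")
  cat(sprintf("  HMM: K = %d, agreement = %s, reducibility = %s\n",
              s$hmm_K,
              ifelse(is.na(s$agreement), "NA", sprintf("%.3f", s$agreement)),
              s$reducibility))
  invisible(x)
}

#' Side-by-side comparison of the two classifiers
#'
#' Pairs each scanning mode's occupancy and mean diffusion rate as estimated
#' by the activation-energy classification and by the (trimmed) HMM states,
#' together with the frame-level agreement fraction.
#'
#' @param run A `scanmodes_run` whose model has 3 states.
#' @return List of class `classifier_comparison`: `table` (one row per mode)
#'   and `agreement`.
#' @export
compare_classifiers <- function(run) {
  stopifnot(inherits(run, "scanmodes_run"))
  if (run$model$K != 3) stop("classifier comparison needs a 3-state model")
  e <- run$energy_stats
  h <- run$hmm_stats
  tab <- data.frame(
    mode = mode_levels(),
    occupancy_energy = e$occupancy,
    occupancy_hmm = h$occupancy,
    mean_D_energy = e$mean_D,
    mean_D_hmm = h$mean_D,
    sem_D_energy = e$sem_D,
    sem_D_hmm = h$sem_D
  )
  structure(list(table = tab, agreement = run$summary$agreement),
            class = "classifier_comparison")
}

#' @export
print.classifier_comparison <- function(x, ...) {
  cat("Energy-barrier vs HMM classification\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("frame-level agreement: %.3f\n", x$agreement))
  invisible(x)
}
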
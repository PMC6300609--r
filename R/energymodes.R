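#' Hydrodynamic parameters for the sliding speed limit
#'
#' Parameters of the rotation-coupled hydrodynamic friction model for a
#' protein tracking the DNA helix: translating along the axis, rotating about
#' its own centre, and revolving about the helical axis at offset `offset_nm`,
#' once per helical pitch.
#'
#' @param radius_nm Protein hydrodynamic radius, nm.
#' @param offset_nm Distance of the protein centre from the DNA helical axis,
#'   nm. Default: radius + 1 nm (the DNA radius).
#' @param pitch_nm DNA length per helical turn, nm (10.5 bp x 0.34 nm/bp).
#' @param viscosity Solvent viscosity, Pa s.
#' @param temperature Temperature, K.
#' @return Object of class `hydro_params`.
#' @export
hydro_params <- function(radius_nm, offset_nm = radius_nm + 1,
                         pitch_nm = 3.57, viscosity = 0.89e-3,
                         temperature = 298) {
  p <- list(radius_nm = radius_nm, offset_nm = offset_nm,
            pitch_nm = pitch_nm, viscosity = viscosity,
            temperature = temperature)
  if (any(unlist(p) <= 0)) stop("all hydrodynamic parameters must be positive")
  structure(p, class = "hydro_params")
}

#' Built-in protein presets
#'
#' Hydrodynamic parameter sets for the two study proteins. The radii are
#' calibrated by root-finding so that [hydrodynamic_limit()] reproduces the
#' published sliding speed limits (0.89 um^2/s for hOGG1, 1.3 um^2/s for
#' EndoV) under the default geometry (offset = radius + 1 nm, pitch 3.57 nm,
#' water at 298 K); they are effective values, not measured radii.
#'
#' @param protein `"endov"` or `"hogg1"` (case-insensitive; EndoV covers both
#'   wild-type and wedge-mutant).
#' @return A [hydro_params()] object.
#' @export
protein_hydro <- function(protein = c("endov", "hogg1")) {
  protein <- match.arg(tolower(protein), c("endov", "hogg1"))
  r <- switch(protein, endov = 2.648861, hogg1 = 3.051495)
  hydro_params(radius_nm = r)
}

#' Upper limit of 1D diffusion for helical sliding
#'
#' Evaluates the frictionless-sliding (zero activation energy) diffusion limit
#' \eqn{D_{ideal} = k_B T / \xi} with rotation-coupled friction
#' \deqn{\xi = 6\pi\eta R + (2\pi/\ell)^2 (8\pi\eta R^3 + 6\pi\eta R\,R_{OC}^2),}
#' where R is the protein radius, R_OC its offset from the helical axis and
#' \eqn{\ell} the helical pitch. As \eqn{\ell \to \infty} rotation decouples
#' and the limit reduces to the Stokes-Einstein translational value.
#'
#' @param params A [hydro_params()] object.
#' @return D_ideal in um^2/s.
#' @export
hydrodynamic_limit <- function(params) {
  stopifnot(inherits(params, "hydro_params"))
  eta <- params$viscosity
  R <- params$radius_nm * 1e-9
  Roc <- params$offset_nm * 1e-9
  ell <- params$pitch_nm * 1e-9
  xi <- 6 * pi * eta * R +
    (2 * pi / ell)^2 * (8 * pi * eta * R^3 + 6 * pi * eta * R * Roc^2)
  .kB * params$temperature / xi * 1e12  # m^2/s -> um^2/s
}

#' Per-base-pair stepping rate constant
#'
#' Converts a 1D diffusion coefficient to the rate constant of the
#' protein-base interaction, \eqn{k = 2D/\langle x^2\rangle} with the mean
#' squared displacement per step taken as 1 bp^2 and D expressed in bp^2/s.
#'
#' @param D Diffusion coefficient, um^2/s.
#' @param msd_bp2 Mean squared displacement per interaction step, bp^2.
#' @param bp_nm Helical rise per base pair, nm (relaxed B-DNA: 0.34).
#' @param stretch Optional stretch factor for elongated DNA (effective rise =
#'   `bp_nm * stretch`); default 1.
#' @return Rate constant k, 1/s.
#' @export
rate_constant <- function(D, msd_bp2 = 1, bp_nm = 0.34, stretch = 1) {
  stopifnot(all(D >= 0), msd_bp2 > 0, bp_nm > 0, stretch > 0)
  rise <- bp_nm * stretch
  D_bp2_s <- D * .NM2_PER_UM2 / rise^2
  2 * D_bp2_s / msd_bp2
}

#' Activation energy barrier of a scanning step
#'
#' The Arrhenius relation \eqn{k = A e^{-E_a/k_B T}} with the pre-exponential
#' factor pinned to the ideal-sliding rate (at the hydrodynamic speed limit
#' \eqn{E_a = 0}, so \eqn{A = k_{ideal}}) gives
#' \eqn{E_a = \ln(k_{ideal}/k)\,k_B T = \ln(D_{ideal}/D_{inst})\,k_B T}
#' (the base-pair conversion cancels in the ratio). Values above the limit
#' give negative barriers; `D_inst = 0` returns `Inf` (classified as
#' interrogation, excluded from barrier histograms).
#'
#' @param D_inst Instantaneous diffusion coefficient(s), um^2/s.
#' @param D_ideal Hydrodynamic sliding limit, um^2/s.
#' @return Activation energy in units of k_B T.
#' @export
activation_energy <- function(D_inst, D_ideal) {
  if (!is.numeric(D_ideal) || length(D_ideal) != 1 || D_ideal <= 0) {
    stop("D_ideal must be a single positive value")
  }
  if (any(D_inst < 0, na.rm = TRUE)) stop("D_inst must be non-negative")
  ifelse(D_inst == 0, Inf, log(D_ideal / D_inst))
}

#' Mode labels used throughout the package
#' @return Character vector of the three scanning modes, slowest first.
#' @export
mode_levels <- function() c("interrogation", "sliding", "hopping")

#' Classify a step by its activation energy
#'
#' Three ranges: `E_a >= t_high` is interrogation (locally confined probing),
#' `t_low <= E_a < t_high` is helical sliding, `E_a < t_low` is hopping
#' (at or above the sliding speed limit). Boundaries are closed from below.
#'
#' @param E_a Activation energies, k_B T.
#' @param t_low,t_high Mode thresholds, k_B T (defaults 0.5 and 2).
#' @return Factor with levels `interrogation`, `sliding`, `hopping`.
#' @export
classify_mode <- function(E_a, t_low = 0.5, t_high = 2.0) {
  stopifnot(t_low < t_high)
  lab <- ifelse(E_a >= t_high, "interrogation",
                ifelse(E_a >= t_low, "sliding", "hopping"))
  factor(lab, levels = mode_levels())
}

#' Per-frame activation energies and mode labels
#'
#' Combines a diffusion series with a sliding speed limit into a frame-level
#' energy profile.
#'
#' @param series A `diffusion_series` from [instantaneous_diffusion()].
#' @param D_ideal Sliding limit, um^2/s, or a [hydro_params()] object.
#' @param t_low,t_high Mode thresholds, k_B T.
#' @return An `energy_profile` data frame: `track_id`, `frame`, `E_a`, `mode`;
#'   attribute `D_ideal`.
#' @export
energy_profile <- function(series, D_ideal, t_low = 0.5, t_high = 2.0) {
  if (inherits(D_ideal, "hydro_params")) D_ideal <- hydrodynamic_limit(D_ideal)
  ea <- activation_energy(series$D_inst_um2_s, D_ideal)
  out <- data.frame(track_id = series$track_id, frame = series$frame,
                    E_a = ea, mode = classify_mode(ea, t_low, t_high))
  structure(out, class = c("energy_profile", "data.frame"),
            D_ideal = D_ideal, t_low = t_low, t_high = t_high)
}

#' Per-mode occupancy and diffusion statistics
#'
#' Occupancy is the fraction of assigned frames carrying each mode label; the
#' per-mode diffusion rate averages the instantaneous coefficients over all
#' frames in that mode.
#'
#' @param profile An [energy_profile()] (or any data frame with `track_id`,
#'   `frame`, `mode`).
#' @param series The matching `diffusion_series`, aligned frame-by-frame.
#' @return A `mode_stats` data frame: one row per mode with `occupancy`,
#'   `mean_D`, `sd_D`, `sem_D`, `n`.
#' @export
mode_statistics <- function(profile, series) {
  if (nrow(profile) != nrow(series) ||
      !all(profile$track_id == series$track_id) ||
      !all(profile$frame == series$frame)) {
    stop("profile and series are not aligned frame-by-frame")
  }
  modes <- factor(profile$mode, levels = mode_levels())
  d <- series$D_inst_um2_s
  n <- as.integer(table(modes))
  occ <- n / length(modes)
  mean_d <- tapply(d, modes, mean, default = NA_real_)
  sd_d <- tapply(d, modes, function(v) if (length(v) > 1) stats::sd(v) else 0,
                 default = NA_real_)
  out <- data.frame(mode = mode_levels(), occupancy = occ,
                    mean_D = as.numeric(mean_d), sd_D = as.numeric(sd_d),
                    sem_D = as.numeric(sd_d) / sqrt(pmax(n, 1)), n = n)
  rownames(out) <- NULL
  structure(out, class = c("mode_stats", "data.frame"))
}

#' Salt-series aggregation of per-mode diffusion
#'
#' Collates per-mode diffusion statistics across buffer conditions and
#' reports each mode's fold-change in mean diffusion relative to the baseline
#' (lowest-salt) condition.
#'
#' @param runs Named list of `mode_stats` tables, one per salt condition;
#'   names are the condition labels in increasing salt order.
#' @param baseline Condition label used as the fold-change reference
#'   (default: the first element of `runs`).
#' @return Data frame with one row per (condition, mode): `condition`, `mode`,
#'   `mean_D`, `sem_D`, `n`, `fold_change`.
#' @export
salt_series <- function(runs, baseline = NULL) {
  stopifnot(length(runs) >= 1, !is.null(names(runs)), all(nzchar(names(runs))))
  if (is.null(baseline)) baseline <- names(runs)[1]
  if (!baseline %in% names(runs)) {
    stop("unknown condition label: ", baseline)
  }
  base <- runs[[baseline]]
  rows <- lapply(names(runs), function(cond) {
    st <- runs[[cond]]
    ref <- base$mean_D[match(st$mode, base$mode)]
    data.frame(condition = cond, mode = st$mode, mean_D = st$mean_D,
               sem_D = st$sem_D, n = st$n, fold_change = st$mean_D / ref)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
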
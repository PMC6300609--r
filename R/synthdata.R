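#' Configuration for the synthetic trajectory generator
#'
#' Defaults emulate the EndoV-style imaging experiment: a ~4.1 um elongated
#' 12-kbp DNA axis, 7.5 ms frames, three diffusion states with sticky Markov
#' switching (the fastest state above the EndoV sliding limit so hopping
#' phenomenology with negative activation energies appears), localization
#' noise drawn per track from the 20-42 nm precision range, and single-frame
#' blinking dropouts.
#'
#' @param frame_interval Frame interval, s (7.5 ms EndoV-like; 23.5 ms
#'   hOGG1-like).
#' @param n_tracks Number of trajectories.
#' @param mean_track_frames Mean of the geometric track-length law (frames).
#' @param D_states Per-state diffusion coefficients, um^2/s (ascending).
#' @param A_true State transition matrix per frame (row-stochastic).
#' @param pi_true Initial state distribution (default: stationary law of
#'   `A_true`).
#' @param loc_noise_nm Localization noise: length-2 range (sigma drawn
#'   uniformly per track) or a single fixed sigma; 0 disables noise.
#' @param blink_prob Per-frame probability that an interior frame is dropped
#'   (never two in a row; first/last frames never drop).
#' @param dna_length_nm DNA span on the image; positions reflect at its ends.
#'   `Inf` disables the boundaries.
#' @param axis_angle_deg,axis_origin Placement of the DNA axis on the image,
#'   used by [render_localizations()].
#' @param return_bias Non-Markovian memory knob: when exiting `bias_state`,
#'   the destination equal to the state it was entered from is upweighted by
#'   this factor (1 = memoryless).
#' @param bias_state State whose exits carry the return bias (default 2).
#' @param seed Integer seed; all generator randomness flows from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(frame_interval = 0.0075, n_tracks = 200,
                       mean_track_frames = 40,
                       D_states = c(0.02, 0.4, 1.6),
                       A_true = NULL, pi_true = NULL,
                       loc_noise_nm = c(20, 42), blink_prob = 0.05,
                       dna_length_nm = 4100, axis_angle_deg = 0,
                       axis_origin = c(0, 0), return_bias = 1,
                       bias_state = 2, seed = 1) {
  K <- length(D_states)
  if (is.null(A_true)) {
    A_true <- matrix(0.1 / max(K - 1, 1), K, K)
    diag(A_true) <- if (K > 1) 0.9 else 1
  }
  A_true <- as.matrix(A_true)
  if (any(A_true < 0) || any(abs(rowSums(A_true) - 1) > 1e-9)) {
    stop("A_true must be row-stochastic")
  }
  if (is.null(pi_true)) pi_true <- stationary_distribution(A_true)
  stopifnot(all(D_states >= 0), dna_length_nm > 0, blink_prob >= 0,
            blink_prob <= 1, length(pi_true) == K,
            abs(sum(pi_true) - 1) < 1e-9)
  structure(list(frame_interval = frame_interval, n_tracks = n_tracks,
                 mean_track_frames = mean_track_frames, D_states = D_states,
                 A_true = A_true, pi_true = pi_true,
                 loc_noise_nm = loc_noise_nm, blink_prob = blink_prob,
                 dna_length_nm = dna_length_nm,
                 axis_angle_deg = axis_angle_deg, axis_origin = axis_origin,
                 return_bias = return_bias, bias_state = bias_state,
                 seed = seed),
            class = "sim_config")
}

#' Stationary distribution of a Markov transition matrix
#'
#' Left Perron eigenvector of a row-stochastic matrix, normalized to sum 1.
#'
#' @param A Row-stochastic matrix.
#' @return Numeric stationary probability vector.
#' @export
stationary_distribution <- function(A) {
  e <- eigen(t(A))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

# reflect positions into [0, L]
reflect_position <- function(s, L) {
  if (!is.finite(L)) return(s)
  s <- s %% (2 * L)
  ifelse(s > L, 2 * L - s, s)
}

#' Simulate a single-mode 1D random walk
#'
#' Free Brownian walk along the DNA axis: increments are zero-mean Gaussian
#' with variance \eqn{2 D \Delta t}; observed positions add independent
#' Gaussian localization noise.
#'
#' @param D Diffusion coefficient, um^2/s.
#' @param n_frames Number of frames (>= 2).
#' @param dt Frame interval, s.
#' @param sigma_loc Localization noise sigma, nm.
#' @param seed Integer seed.
#' @return List with `tracks` (a one-track [scan_tracks()] of the observed
#'   positions) and `truth` (data frame of true positions).
#' @export
simulate_random_walk <- function(D, n_frames, dt = 0.0075, sigma_loc = 0,
                                 seed = 1) {
  if (D < 0) stop("D must be non-negative")
  if (n_frames < 2) stop("need at least 2 frames")
  with_seed(seed, {
    step_sd <- sqrt(2 * D * .NM2_PER_UM2 * dt)
    s_true <- cumsum(c(0, stats::rnorm(n_frames - 1, 0, step_sd)))
    s_obs <- s_true + if (sigma_loc > 0) stats::rnorm(n_frames, 0, sigma_loc) else 0
    tracks <- scan_tracks(data.frame(
      track_id = 1L, frame = seq_len(n_frames) - 1L, s_nm = s_obs,
      y_nm = 0, bridged = FALSE), dt)
    list(tracks = tracks,
         truth = data.frame(track_id = 1L, frame = seq_len(n_frames) - 1L,
                            s_true_nm = s_true, state = 1L))
  })
}

# sample one state sequence with optional return bias on bias_state exits
sample_states <- function(len, A, pi0, return_bias, bias_state) {
  K <- nrow(A)
  st <- integer(len)
  st[1] <- sample.int(K, 1, prob = pi0)
  entry <- NA_integer_  # state from which the current bias_state sojourn was entered
  for (t in seq_len(len - 1)) {
    c0 <- st[t]
    if (c0 == bias_state && return_bias != 1 && K > 1 && !is.na(entry)) {
      # stay with the nominal self-transition, bias the exit destination
      if (stats::runif(1) < A[c0, c0]) {
        st[t + 1] <- c0
      } else {
        others <- setdiff(seq_len(K), c0)
        w <- A[c0, others]
        w[others == entry] <- w[others == entry] * return_bias
        st[t + 1] <- others[sample.int(length(others), 1, prob = w)]
      }
    } else {
      st[t + 1] <- sample.int(K, 1, prob = A[c0, ])
    }
    if (st[t + 1] == bias_state && c0 != bias_state) entry <- c0
    if (st[t + 1] != bias_state) entry <- NA_integer_
  }
  st
}

#' Simulate multi-state switching trajectories
#'
#' Generates `n_tracks` trajectories: per frame the diffusion state evolves by
#' the configured Markov chain (optionally with a return bias injecting
#' non-Markovian memory), positions take Gaussian increments of variance
#' \eqn{2 D_{state} \Delta t} and reflect at the DNA ends, localization noise
#' is added, and interior frames blink out with the configured probability.
#'
#' @param cfg A [sim_config()].
#' @return List with `tracks` (observed [scan_tracks()], blinked frames
#'   missing and flagged via `bridged`) and `truth` (data frame `track_id`,
#'   `frame`, `s_true_nm`, `state`, `observed`, `sigma_nm`).
#' @export
simulate_multistate <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    K <- length(cfg$D_states)
    dt <- cfg$frame_interval
    step_sd <- sqrt(2 * cfg$D_states * .NM2_PER_UM2 * dt)
    L <- cfg$dna_length_nm
    mean_len <- max(cfg$mean_track_frames, 3)
    obs_rows <- list()
    truth_rows <- list()
    for (id in seq_len(cfg$n_tracks)) {
      len <- 2L + stats::rgeom(1, 1 / (mean_len - 2))
      st <- sample_states(len, cfg$A_true, cfg$pi_true,
                          cfg$return_bias, cfg$bias_state)
      s <- numeric(len)
      s[1] <- stats::runif(1, 0, min(L, 1e7))
      for (t in seq_len(len - 1)) {
        s[t + 1] <- reflect_position(s[t] + stats::rnorm(1, 0, step_sd[st[t]]), L)
      }
      sigma <- if (length(cfg$loc_noise_nm) == 2) {
        stats::runif(1, cfg$loc_noise_nm[1], cfg$loc_noise_nm[2])
      } else cfg$loc_noise_nm
      noise <- if (sigma > 0) stats::rnorm(len, 0, sigma) else numeric(len)
      yjit <- if (sigma > 0) stats::rnorm(len, 0, sigma) else numeric(len)
      observed <- rep(TRUE, len)
      if (cfg$blink_prob > 0 && len > 2) {
        for (t in 2:(len - 1)) {
          if (observed[t - 1] && stats::runif(1) < cfg$blink_prob) {
            observed[t] <- FALSE
          }
        }
      }
      frames <- seq_len(len) - 1L
      truth_rows[[id]] <- data.frame(
        track_id = id, frame = frames, s_true_nm = s, state = st,
        observed = observed, sigma_nm = sigma)
      kept <- which(observed)
      lagk <- diff(frames[kept])
      bridged <- logical(length(kept))
      if (length(kept) > 1) {
        gap2 <- which(lagk == 2)
        bridged[gap2] <- TRUE
        bridged[gap2 + 1] <- TRUE
      }
      obs_rows[[id]] <- data.frame(
        track_id = id, frame = frames[kept], s_nm = s[kept] + noise[kept],
        y_nm = yjit[kept], bridged = bridged)
    }
    list(tracks = scan_tracks(do.call(rbind, obs_rows), dt),
         truth = do.call(rbind, truth_rows))
  })
}

#' Ground-truth states as a decodable state path
#'
#' Wraps the generator's true per-frame states in the same `state_path`
#' container returned by [decode_states()], so kinetic statistics
#' ([transition_matrix()], [triplet_memory()], [switch_frequency()]) can be
#' evaluated against the ground truth.
#'
#' @param truth The `truth` data frame from [simulate_multistate()].
#' @return A `state_path` data frame.
#' @export
truth_state_path <- function(truth) {
  structure(data.frame(track_id = truth$track_id, frame = truth$frame,
                       state = truth$state),
            class = c("state_path", "data.frame"), K = max(truth$state))
}

#' Render tracks as a localization table
#'
#' Embeds axis-frame tracks into image coordinates (rotating by the
#' configured axis angle and translating to the axis origin) and lays the
#' tracks out sequentially in time (with an inter-track frame gap larger than
#' the blink bridge) so that re-linking the rendered table recovers them.
#'
#' @param tracks A [scan_tracks()] table.
#' @param cfg A [sim_config()] (for axis angle/origin) or NULL for an axis
#'   along +x at the origin.
#' @param path Optional CSV output path (written in the [default_dialect()]).
#' @param sigma_nm Value written to the precision column.
#' @param track_gap_frames Blank frames inserted between consecutive tracks.
#' @return The localization data frame (invisibly if `path` is given).
#' @export
render_localizations <- function(tracks, cfg = NULL, path = NULL,
                                 sigma_nm = 30, track_gap_frames = 5L) {
  angle <- if (is.null(cfg)) 0 else cfg$axis_angle_deg * pi / 180
  origin <- if (is.null(cfg)) c(0, 0) else cfg$axis_origin
  rows <- list()
  offset <- 0L
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, ]
    f <- tr$frame - tr$frame[1] + offset
    x <- cos(angle) * tr$s_nm - sin(angle) * tr$y_nm + origin[1]
    y <- sin(angle) * tr$s_nm + cos(angle) * tr$y_nm + origin[2]
    rows[[length(rows) + 1]] <- data.frame(
      frame = f, x_nm = x, y_nm = y, sigma_nm = sigma_nm, photons = NA_real_)
    offset <- max(f) + 1L + track_gap_frames
  }
  locs <- do.call(rbind, rows)
  rownames(locs) <- NULL
  if (!is.null(path)) {
    write_localizations(locs, path)
    return(invisible(locs))
  }
  locs
}
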
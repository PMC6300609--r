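#' Instantaneous diffusion coefficients by sliding window
#'
#' For each track, slides a `window`-frame window (default 5 frames = 4
#' single-frame displacements) along the axis positions and estimates the
#' per-frame diffusion coefficient from the one-dimensional relation
#' \eqn{\langle x^2\rangle = 2Dt}: the window's mean squared single-frame
#' displacement divided by twice the frame interval. The value is assigned to
#' the window's first frame, so the last four frames of every track carry no
#' value.
#'
#' A displacement across a bridged one-frame blink gap spans two frame
#' intervals; its squared displacement is halved before pooling (Brownian
#' scaling) and every window containing it is flagged `bridged_window` so it
#' can be excluded downstream.
#'
#' @param tracks A [scan_tracks()] table.
#' @param window Window width in frames (>= 2).
#' @return A `diffusion_series` data frame with columns `track_id`, `frame`,
#'   `D_inst_um2_s`, `bridged_window`, and attributes `window` and
#'   `frame_interval`. Tracks shorter than `window` detections contribute no
#'   rows (with a warning).
#' @export
instantaneous_diffusion <- function(tracks, window = 5) {
  stopifnot(inherits(tracks, "scan_tracks"), window >= 2)
  dt <- frame_interval(tracks)
  m <- window - 1  # displacements per window
  ids <- unique(tracks$track_id)
  out <- vector("list", length(ids))
  short <- 0L
  for (i in seq_along(ids)) {
    tr <- tracks[tracks$track_id == ids[i], ]
    n <- nrow(tr)
    if (n < window) {
      short <- short + 1L
      next
    }
    ds <- diff(tr$s_nm)
    lag <- diff(tr$frame)
    q <- ds^2 / lag  # nm^2 per frame interval
    n_assigned <- n - m
    idx <- seq_len(n_assigned)
    # mean of q over each run of m consecutive displacements
    cq <- c(0, cumsum(q))
    msd <- (cq[idx + m] - cq[idx]) / m
    cb <- c(0, cumsum(lag == 2))
    brw <- (cb[idx + m] - cb[idx]) > 0
    out[[i]] <- data.frame(
      track_id = ids[i],
      frame = tr$frame[idx],
      D_inst_um2_s = msd / (2 * dt) / .NM2_PER_UM2,
      bridged_window = brw
    )
  }
  if (short > 0) {
    warning(short, " track(s) shorter than the ", window,
            "-frame window yielded no values")
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(track_id = integer(0), frame = integer(0),
                      D_inst_um2_s = numeric(0), bridged_window = logical(0))
  }
  rownames(res) <- NULL
  structure(res, class = c("diffusion_series", "data.frame"),
            window = window, frame_interval = dt)
}

#' Duration of the sliding window
#'
#' @param frame_interval Frame interval, s.
#' @param window Window width in frames.
#' @return Window duration in seconds (5 frames at 7.5 ms = 37.5 ms).
#' @export
window_duration <- function(frame_interval, window = 5) {
  stopifnot(frame_interval > 0, window >= 1)
  window * frame_interval
}

#' Pooled ensemble diffusion statistics
#'
#' Mean, standard deviation and standard error of all assigned instantaneous
#' diffusion coefficients, pooled across tracks.
#'
#' @param series One `diffusion_series`, or a list of them (pooled).
#' @return List of class `ensemble_diffusion` with `mean`, `sd`, `sem`, `n`
#'   (all in um^2/s except `n`).
#' @export
ensemble_diffusion <- function(series) {
  if (is.data.frame(series)) series <- list(series)
  d <- unlist(lapply(series, function(s) s$D_inst_um2_s), use.names = FALSE)
  if (!length(d)) stop("no assigned diffusion values to pool")
  n <- length(d)
  s <- if (n > 1) stats::sd(d) else 0
  structure(list(mean = mean(d), sd = s, sem = s / sqrt(n), n = n),
            class = "ensemble_diffusion")
}

#' @export
print.ensemble_diffusion <- function(x, ...) {
  cat(sprintf("D_ave = %.4g +/- %.4g um^2/s (sd; sem %.4g, n = %d windows)\n",
              x$mean, x$sd, x$sem, x$n))
  invisible(x)
}

#' Histogram of instantaneous diffusion coefficients
#'
#' Bins the assigned values on user-supplied (typically log-spaced) edges and
#' returns counts plus a kernel-density support for overlaying a simulated
#' single-mode baseline.
#'
#' @param series A `diffusion_series` (or list of them).
#' @param breaks Strictly increasing bin edges, um^2/s. Values outside the
#'   range fall into the flanking bins' counts being dropped is avoided by
#'   clamping edges to the data range when `clamp = TRUE`.
#' @param clamp Extend the first/last edge to cover all data (default TRUE so
#'   counts always sum to the number of values).
#' @return List of class `diffusion_histogram`: `breaks`, `counts`, `mids`,
#'   `density`, `n`, and `kde` (a `stats::density` object on log10 D for
#'   positive values, or NULL).
#' @export
diffusion_histogram <- function(series, breaks, clamp = TRUE) {
  if (is.data.frame(series)) series <- list(series)
  d <- unlist(lapply(series, function(s) s$D_inst_um2_s), use.names = FALSE)
  if (any(diff(breaks) <= 0)) stop("bin edges must be strictly increasing")
  if (clamp && length(d)) {
    breaks[1] <- min(breaks[1], min(d))
    breaks[length(breaks)] <- max(breaks[length(breaks)], max(d) + 1e-12)
  }
  # right-open bins [e_i, e_{i+1}), last bin closed
  idx <- findInterval(d, breaks, rightmost.closed = TRUE)
  idx <- idx[idx >= 1 & idx < length(breaks)]
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  width <- diff(breaks)
  pos <- d[d > 0]
  kde <- if (length(pos) >= 2) stats::density(log10(pos)) else NULL
  structure(list(breaks = breaks, counts = counts,
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 density = counts / (length(d) * width), n = length(d),
                 kde = kde),
            class = "diffusion_histogram")
}

#' @export
plot.diffusion_histogram <- function(x, log = "x", ...) {
  graphics::plot(x$mids, x$counts, type = "h", log = log,
                 xlab = expression(D[inst] ~ (mu * m^2 ~ s^-1)),
                 ylab = "count", ...)
  invisible(x)
}
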
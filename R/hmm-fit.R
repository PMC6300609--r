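# Displacement sequences for HMM fitting: contiguous (lag-1) runs only;
# a bridged blink gap splits the track into segments because the displacement
# across it spans two frame intervals.
displacement_segments <- function(tracks) {
  ids <- unique(tracks$track_id)
  segs <- list()
  seg_id <- list()
  for (id in ids) {
    tr <- tracks[tracks$track_id == id, ]
    if (nrow(tr) < 2) next
    lag <- diff(tr$frame)
    ds <- diff(tr$s_nm)
    runs <- rle(lag == 1)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (k in seq_along(runs$values)) {
      if (runs$values[k]) {
        segs[[length(segs) + 1]] <- ds[starts[k]:ends[k]]
        seg_id[[length(seg_id) + 1]] <- id
      }
    }
  }
  list(disp = segs, track_id = unlist(seg_id))
}

#' Fit a diffusion-state hidden Markov model
#'
#' Models each single-frame axis displacement as a zero-mean Gaussian whose
#' variance is set by a hidden diffusion state: state k emits
#' \eqn{\Delta s \sim N(0,\, 2 D_k \Delta t + 2\sigma_{loc}^2)} and states
#' switch by a first-order Markov chain. Parameters are estimated by
#' Baum-Welch expectation-maximization over all contiguous displacement
#' sequences (displacements across bridged blink gaps are excluded), with the
#' best of `n_restarts` seeded initializations returned. States are reported
#' in ascending order of diffusion coefficient, so for a three-state model
#' state 1 is interrogation-like and state 3 hopping-like.
#'
#' @param tracks A [scan_tracks()] table.
#' @param K Number of diffusion states (>= 1).
#' @param n_restarts Random restarts of EM.
#' @param seed Integer seed controlling the restarts.
#' @param max_iter,tol EM stopping rule: stop when the per-observation
#'   log-likelihood gain falls below `tol`.
#' @param sigma_loc Localization noise (nm) added to every state's emission
#'   variance as \eqn{2\sigma^2}; 0 disables the correction (default).
#' @return An object of class `diffusion_hmm`: `K`, `D` (um^2/s, ascending),
#'   `pi`, `A`, `occupancy` (posterior fraction of displacements per state),
#'   `logLik`, `bic`, `n_obs`, `frame_interval`, `loglik_trace`, `degenerate`
#'   flag.
#' @seealso [select_model()], [decode_states()], [simulate.diffusion_hmm()]
#' @export
fit_hmm <- function(tracks, K, n_restarts = 5, seed = 1, max_iter = 500,
                    tol = 1e-8, sigma_loc = 0) {
  if (K < 1) stop("K must be at least 1")
  seg <- displacement_segments(tracks)
  obs <- unlist(seg$disp, use.names = FALSE)
  seqlen <- vapply(seg$disp, length, integer(1))
  n <- length(obs)
  if (n < 10 * K) stop("need at least 10 displacements per state (have ", n, ")")
  dt <- frame_interval(tracks)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(seed + r - 1L, {
      em_gaussian_hmm(obs, seqlen, K, max_iter, tol)
    })
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  # order states by emission variance (ascending D)
  ord <- order(best$var)
  v <- best$var[ord]
  A <- best$A[ord, ord, drop = FALSE]
  pim <- best$pi[ord]
  occ <- best$occ[ord]
  D <- pmax((v - 2 * sigma_loc^2), 0) / (2 * dt) / .NM2_PER_UM2
  p <- K * K + K - 1  # K(K-1) transitions + (K-1) initial + K variances
  bic <- -2 * best$loglik + p * log(n)
  degenerate <- any(occ < 1e-3) ||
    (K > 1 && any(diff(D) / pmax(D[-1], .Machine$double.eps) < 0.01))
  structure(list(K = K, D = D, pi = pim, A = A, occupancy = occ,
                 logLik = best$loglik, bic = bic, n_obs = n,
                 n_params = p, frame_interval = dt, sigma_loc = sigma_loc,
                 loglik_trace = best$trace, n_iter = best$iter,
                 degenerate = degenerate, seed = seed),
            class = "diffusion_hmm")
}

# One EM run from a random initialization (RNG already seeded by caller).
em_gaussian_hmm <- function(obs, seqlen, K, max_iter, tol) {
  n <- length(obs)
  v_hat <- mean(obs^2)
  # spread initial variances over the squared-displacement quantiles, jittered
  if (K == 1) {
    v <- v_hat * exp(stats::rnorm(1, 0, 0.1))
  } else {
    qs <- stats::quantile(obs^2, probs = seq(0.15, 0.95, length.out = K))
    v <- pmax(as.numeric(qs), v_hat * 1e-4) * exp(stats::rnorm(K, 0, 0.3))
    v <- sort(v)
  }
  A <- matrix(0.1 / max(K - 1, 1), K, K)
  diag(A) <- if (K > 1) 0.9 else 1
  pi0 <- rep(1 / K, K)
  trace <- numeric(0)
  prev <- -Inf
  it <- 0
  repeat {
    it <- it + 1
    e <- hmm_estep_cpp(obs, seqlen, v, pi0, A, FALSE)
    trace <- c(trace, e$loglik)
    if (e$loglik < prev - 1e-8 * max(1, abs(prev))) {
      stop("EM likelihood decreased: numerical failure")
    }
    done <- (e$loglik - prev) < tol * n || it >= max_iter
    prev <- e$loglik
    # M-step
    v_new <- e$Sxx / pmax(e$Ngamma, 1e-12)
    v <- pmax(v_new, v_hat * 1e-10)
    if (K > 1) {
      A <- e$xi / pmax(rowSums(e$xi), 1e-300)
      zero <- rowSums(e$xi) < 1e-300
      if (any(zero)) A[zero, ] <- 1 / K
    }
    pi0 <- e$first / sum(e$first)
    if (done) break
  }
  occ <- as.numeric(e$Ngamma) / n
  list(var = v, A = A, pi = pi0, occ = occ, loglik = e$loglik,
       trace = trace, iter = it)
}

#' Select the number of diffusion states
#'
#' Fits models with 1..`K_max` states and picks the one minimizing BIC on the
#' pooled displacement likelihood, emulating the over-specify-then-converge
#' strategy of variational state-count selection.
#'
#' @inheritParams fit_hmm
#' @param K_max Largest state count to try.
#' @return List of class `hmm_selection`: `best_k`, `best` (the winning
#'   `diffusion_hmm`), `models` (all fits), and a `bic` table.
#' @export
select_model <- function(tracks, K_max = 5, n_restarts = 5, seed = 1, ...) {
  stopifnot(K_max >= 1)
  models <- lapply(seq_len(K_max), function(k) {
    fit_hmm(tracks, K = k, n_restarts = n_restarts, seed = seed + 1000L * k, ...)
  })
  bic <- vapply(models, `[[`, numeric(1), "bic")
  best_k <- which.min(bic)
  structure(list(best_k = best_k, best = models[[best_k]], models = models,
                 bic = data.frame(K = seq_len(K_max), bic = bic,
                                  logLik = vapply(models, `[[`, numeric(1), "logLik"))),
            class = "hmm_selection")
}

#' @export
print.hmm_selection <- function(x, ...) {
  cat("Diffusion-state HMM selection (BIC):\n")
  print(x$bic, row.names = FALSE)
  cat("Best K =", x$best_k, "\n")
  invisible(x)
}

#' @export
print.diffusion_hmm <- function(x, digits = 4, ...) {
  cat("Diffusion-state HMM with", x$K, "state(s)\n")
  cat("  D (um^2/s):", paste(signif(x$D, digits), collapse = ", "), "\n")
  cat("  occupancy :", paste(signif(x$occupancy, digits), collapse = ", "), "\n")
  cat(sprintf("  logLik %.2f on %d displacements; BIC %.2f\n",
              x$logLik, x$n_obs, x$bic))
  invisible(x)
}

#' @export
summary.diffusion_hmm <- function(object, ...) {
  print(object)
  cat("  transition matrix (per frame):\n")
  m <- round(object$A, 4)
  dimnames(m) <- list(paste0("from_", seq_len(object$K)),
                      paste0("to_", seq_len(object$K)))
  print(m)
  if (object$degenerate) {
    cat("  note: near-degenerate fit (empty or duplicated state)\n")
  }
  invisible(object)
}

#' @export
coef.diffusion_hmm <- function(object, ...) {
  list(D = object$D, pi = object$pi, A = object$A)
}

#' @export
logLik.diffusion_hmm <- function(object, ...) {
  structure(object$logLik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' Simulate displacement tracks from a fitted model
#'
#' Draws `nsim` tracks of `n_frames` frames each from the fitted state chain
#' and per-state Gaussian displacement distributions.
#'
#' @param object A `diffusion_hmm`.
#' @param nsim Number of tracks.
#' @param seed Integer seed.
#' @param n_frames Frames per track.
#' @param ... Unused.
#' @return A [scan_tracks()] table with attribute `true_states` (data frame of
#'   the generating states).
#' @export
simulate.diffusion_hmm <- function(object, nsim = 1, seed = 1,
                                   n_frames = 100, ...) {
  K <- object$K
  dt <- object$frame_interval
  sdk <- sqrt(2 * object$D * .NM2_PER_UM2 * dt)
  with_seed(seed, {
    rows <- lapply(seq_len(nsim), function(id) {
      st <- integer(n_frames)
      st[1] <- sample.int(K, 1, prob = object$pi)
      for (t in seq_len(n_frames - 1)) {
        st[t + 1] <- sample.int(K, 1, prob = object$A[st[t], ])
      }
      ds <- stats::rnorm(n_frames - 1, 0, sdk[st[-n_frames]])
      data.frame(track_id = id, frame = seq_len(n_frames) - 1L,
                 s_nm = cumsum(c(0, ds)), y_nm = 0, bridged = FALSE,
                 state = st)
    })
    df <- do.call(rbind, rows)
    out <- scan_tracks(df[, c("track_id", "frame", "s_nm", "y_nm", "bridged")], dt)
    attr(out, "true_states") <- df[, c("track_id", "frame", "state")]
    out
  })
}

#' @export
plot.diffusion_hmm <- function(x, tracks = NULL, ...) {
  sdk <- sqrt(2 * x$D * .NM2_PER_UM2 * x$frame_interval)
  xs <- seq(-4 * max(sdk), 4 * max(sdk), length.out = 400)
  dens <- sapply(seq_len(x$K), function(k) {
    x$occupancy[k] * stats::dnorm(xs, 0, sdk[k])
  })
  mix <- rowSums(dens)
  if (!is.null(tracks)) {
    seg <- displacement_segments(tracks)
    obs <- unlist(seg$disp, use.names = FALSE)
    graphics::hist(obs, breaks = 60, freq = FALSE,
                   main = "Displacement mixture", xlab = "displacement (nm)")
    graphics::lines(xs, mix, lwd = 2)
  } else {
    graphics::plot(xs, mix, type = "l", lwd = 2,
                   main = "Displacement mixture", xlab = "displacement (nm)",
                   ylab = "density")
  }
  for (k in seq_len(x$K)) graphics::lines(xs, dens[, k], lty = 2)
  invisible(x)
}
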
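# Small builders and independent oracles shared across the suite.

# One track from a position vector.
make_tracks <- function(s, frames = seq_along(s) - 1L, dt = 0.0075,
                        id = 1L, y = 0) {
  scan_tracks(data.frame(track_id = id, frame = as.integer(frames), s_nm = s,
                         y_nm = y, bridged = FALSE), dt)
}

# Localization table from x/y/frame vectors.
make_locs <- function(frame, x, y, sigma = NA_real_) {
  data.frame(frame = as.integer(frame), x_nm = x, y_nm = y,
             sigma_nm = sigma, photons = NA_real_)
}

# Brute-force HMM posteriors by enumerating all K^n state paths.
# Independent of the forward-backward implementation under test.
bf_forward_backward <- function(obs, v, pi0, A) {
  K <- length(v)
  n <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  probs <- apply(paths, 1, function(st) {
    p <- pi0[st[1]] * prod(stats::dnorm(obs, 0, sqrt(v[st])))
    if (n > 1) p <- p * prod(A[cbind(st[-n], st[-1])])
    p
  })
  lik <- sum(probs)
  gamma <- sapply(seq_len(K), function(k) {
    sapply(seq_len(n), function(t) sum(probs[paths[, t] == k]))
  }) / lik
  list(loglik = log(lik), gamma = matrix(gamma, nrow = n))
}

# Hand-rolled state_path construction for label-sequence tests.
make_path <- function(states, id = 1L, K = max(states)) {
  structure(data.frame(track_id = id, frame = seq_along(states) - 1L,
                       state = as.integer(states)),
            class = c("state_path", "data.frame"), K = K)
}
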
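test_that("forward-backward matches brute-force path enumeration", {
  set.seed(9)
  for (K in 2:3) {
    for (n in c(3, 6, 8)) {
      v <- sort(rlnorm(K, 6, 1))
      A <- matrix(rgamma(K * K, 2), K)
      A <- A / rowSums(A)
      pi0 <- rgamma(K, 2); pi0 <- pi0 / sum(pi0)
      obs <- rnorm(n, 0, sqrt(sample(v, n, replace = TRUE)))
      bf <- bf_forward_backward(obs, v, pi0, A)
      e <- scanmodes:::hmm_estep_cpp(obs, length(obs), v, pi0, A, TRUE)
      expect_equal(e$loglik, bf$loglik, tolerance = 1e-10)
      g <- matrix(e$gamma, nrow = n)
      expect_lt(max(abs(g - bf$gamma)), 1e-10)
      # posterior marginals sum to 1 at every frame
      expect_equal(rowSums(g), rep(1, n), tolerance = 1e-12)
    }
  }
})

test_that("EM likelihood never decreases and K = 1 recovers the variance MLE", {
  rw <- simulate_random_walk(0.5, n_frames = 1e5 + 1, dt = 0.0075, seed = 41)
  m <- fit_hmm(rw$tracks, K = 1, n_restarts = 2, seed = 1)
  expect_true(all(diff(m$loglik_trace) > -1e-8 * abs(m$logLik)))
  # single-state MLE: displacement variance / (2 dt)
  expect_lt(abs(m$D - 0.5) / 0.5, 0.03)
  ds <- diff(rw$tracks$s_nm)
  expect_equal(m$D, mean(ds^2) / (2 * 0.0075) / 1e6, tolerance = 1e-6)
})

test_that("a 2-state fit on single-state data degenerates gracefully", {
  rw <- simulate_random_walk(0.5, n_frames = 5000, dt = 0.0075, seed = 42)
  m <- fit_hmm(rw$tracks, K = 2, n_restarts = 2, seed = 3)
  rel_gap <- abs(diff(m$D)) / max(m$D)
  expect_true(m$degenerate || rel_gap < 0.25 || min(m$occupancy) < 0.05)
})

test_that("three well-separated states are recovered from 1e5 displacements", {
  cfg <- sim_config(seed = 51, n_tracks = 1700, mean_track_frames = 60,
                    loc_noise_nm = 0, blink_prob = 0, dna_length_nm = Inf)
  gen <- simulate_multistate(cfg)
  expect_gte(nrow(gen$tracks) - cfg$n_tracks, 1e5 * 0.9)
  m <- fit_hmm(gen$tracks, K = 3, n_restarts = 3, seed = 6)
  expect_true(all(abs(m$D - cfg$D_states) / cfg$D_states < 0.10))
  expect_lt(max(abs(m$A - cfg$A_true)), 0.05)
  pi_stat <- stationary_distribution(cfg$A_true)
  expect_lt(max(abs(m$occupancy - pi_stat)), 0.05)
})

test_that("BIC selects one state for a random walk and three for 3-state data", {
  rw <- simulate_random_walk(0.645, n_frames = 2e4, dt = 0.0075, seed = 61)
  sel1 <- select_model(rw$tracks, K_max = 4, n_restarts = 2, seed = 1)
  expect_equal(sel1$best_k, 1)

  cfg <- sim_config(seed = 62, n_tracks = 350, mean_track_frames = 60,
                    loc_noise_nm = 0, blink_prob = 0, dna_length_nm = Inf)
  gen <- simulate_multistate(cfg)
  sel3 <- select_model(gen$tracks, K_max = 4, n_restarts = 2, seed = 2)
  expect_equal(sel3$best_k, 3)

  # at tiny n the penalty dominates and fewer states win
  small <- scan_tracks(gen$tracks[gen$tracks$track_id %in% 1:2, ],
                       cfg$frame_interval)
  expect_lt(select_model(small, K_max = 3, n_restarts = 2, seed = 3)$best_k, 3)
})

test_that("decoding assigns frames to the dominant posterior state", {
  rw <- simulate_random_walk(0.3, n_frames = 50, dt = 0.0075, seed = 71)
  m1 <- fit_hmm(rw$tracks, K = 1, n_restarts = 1, seed = 1)
  p1 <- decode_states(m1, rw$tracks)
  expect_true(all(p1$state == 1))
  expect_equal(nrow(p1), 50)

  # hand-built 2-state model: a large-displacement burst mid-track decodes
  # to the fast state (verified against brute-force posteriors)
  dt <- 0.0075
  m2 <- structure(list(K = 2L, D = c(0.02, 2), pi = c(0.5, 0.5),
                       A = matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
                       occupancy = c(0.5, 0.5), frame_interval = dt,
                       sigma_loc = 0), class = "diffusion_hmm")
  s <- cumsum(c(0, 5, -5, 400, -380, 6, -6))
  tr <- make_tracks(s, dt = dt)
  p2 <- decode_states(m2, tr)
  expect_equal(p2$state, c(1, 1, 2, 2, 1, 1, 1))
  v <- 2 * m2$D * 1e6 * dt
  bf <- bf_forward_backward(diff(s), v, m2$pi, m2$A)
  expect_equal(p2$state[1:6], unname(apply(bf$gamma, 1, which.max)))

  # viterbi agrees on this clear-cut case
  pv <- decode_states(m2, tr, method = "viterbi")
  expect_equal(pv$state, p2$state)
})

test_that("trimmed statistics use exactly the diffusion-assigned frames", {
  cfg <- sim_config(seed = 81, n_tracks = 30, mean_track_frames = 25,
                    loc_noise_nm = 0, blink_prob = 0)
  gen <- simulate_multistate(cfg)
  ser <- suppressWarnings(instantaneous_diffusion(gen$tracks))
  m <- fit_hmm(gen$tracks, K = 3, n_restarts = 2, seed = 4)
  paths <- decode_states(m, gen$tracks)
  st <- trim_and_recompute(paths, ser)
  expect_equal(sum(st$n), nrow(ser))
  expect_equal(sum(st$occupancy), 1)

  # a 6-frame track contributes exactly 2 frames
  tr6 <- make_tracks(seq(0, 500, by = 100))
  ser6 <- instantaneous_diffusion(tr6)
  expect_equal(nrow(ser6), 2)
  p6 <- decode_states(m, scan_tracks(as.data.frame(tr6), cfg$frame_interval))
  st6 <- trim_and_recompute(p6, ser6)
  expect_equal(sum(st6$n), 2)

  # uniform single-state paths keep occupancy 1 under trimming
  rw <- simulate_random_walk(0.3, n_frames = 40, dt = cfg$frame_interval,
                             seed = 5)
  m1 <- fit_hmm(rw$tracks, K = 1, n_restarts = 1, seed = 1)
  st1 <- trim_and_recompute(decode_states(m1, rw$tracks),
                            instantaneous_diffusion(rw$tracks))
  expect_equal(st1$occupancy, 1)
})

test_that("trimming changes occupancy negligibly on long tracks", {
  cfg <- sim_config(seed = 82, n_tracks = 150, mean_track_frames = 120,
                    loc_noise_nm = 0, blink_prob = 0)
  gen <- simulate_multistate(cfg)
  ser <- suppressWarnings(instantaneous_diffusion(gen$tracks))
  m <- fit_hmm(gen$tracks, K = 3, n_restarts = 2, seed = 7)
  paths <- decode_states(m, gen$tracks)
  trimmed <- trim_and_recompute(paths, ser)
  full_occ <- tabulate(paths$state, 3) / nrow(paths)
  expect_lt(max(abs(trimmed$occupancy - full_occ)), 0.01)
})

test_that("agreement is an exact fraction of identical labels", {
  x <- factor(c("a", "b", "a", "c"))
  expect_equal(agreement(x, x), 1)
  expect_equal(agreement(c(1, 1, 2, 2), c(2, 2, 1, 1)), 0)
  expect_equal(agreement(c(1, 2, 3, 1), c(1, 2, 1, 2)), 0.5)
  expect_error(agreement(1:3, 1:4), "length")
})

test_that("empirical transition matrices converge to the generating chain", {
  p <- make_path(c(2, 2, 2, 2))
  expect_equal(transition_matrix(p, K = 3)[2, ], c(0, 1, 0))

  cfg <- sim_config(seed = 91, n_tracks = 1700, mean_track_frames = 60,
                    loc_noise_nm = 0, blink_prob = 0)
  gen <- simulate_multistate(cfg)
  tmat <- transition_matrix(truth_state_path(gen$truth))
  expect_equal(rowSums(tmat), rep(1, 3))
  expect_lt(max(abs(tmat - cfg$A_true)), 0.02)
})

test_that("the return-memory ratio detects non-Markovian switching", {
  # deterministic alternation: every sojourn in 2 returns to 1
  p <- make_path(rep(c(1, 2), 10), K = 3)
  ms <- triplet_memory(p)
  expect_equal(ms$p_return, 1)

  # no qualifying sojourns -> NA sentinel
  expect_true(is.na(triplet_memory(make_path(c(1, 1, 1), K = 3))$ratio))

  cfg <- sim_config(seed = 92, n_tracks = 2500, mean_track_frames = 60,
                    loc_noise_nm = 0, blink_prob = 0)
  gen <- simulate_multistate(cfg)
  ms_markov <- triplet_memory(truth_state_path(gen$truth))
  expect_gte(ms_markov$n_sojourns, 3000)
  expect_gt(ms_markov$ratio, 0.9)
  expect_lt(ms_markov$ratio, 1.1)

  cfgb <- sim_config(seed = 93, n_tracks = 2500, mean_track_frames = 60,
                     loc_noise_nm = 0, blink_prob = 0, return_bias = 2)
  genb <- simulate_multistate(cfgb)
  ms_bias <- triplet_memory(truth_state_path(genb$truth))
  expect_gt(ms_bias$ratio, 1.7)
  expect_lt(ms_bias$ratio, 2.3)
})

test_that("reducibility classifies transition graphs", {
  expect_equal(reducibility(diag(3)), "reducible")
  A <- matrix(1 / 3, 3, 3)
  expect_equal(reducibility(A), "irreducible")
  B <- rbind(c(0.5, 0.5, 0, 0), c(0.5, 0.5, 0, 0),
             c(0, 0, 0.5, 0.5), c(0, 0, 0.5, 0.5))
  expect_equal(reducibility(B), "reducible")
  # connectivity through a rare transition: reducible at eps, not at eps/10
  C <- rbind(c(1 - 5e-4, 5e-4), c(0.2, 0.8))
  expect_equal(reducibility(C, eps = 1e-3), "nearly_reducible")
  expect_error(reducibility(matrix(c(0.5, 0.2, 0.5, 0.2), 2)), "sum to 1")
})

test_that("switch frequency counts entries per 1000 bp traversed", {
  # no visits to the target state
  p <- make_path(c(2, 2, 3, 3), K = 3)
  tr <- make_tracks(c(0, 100, 200, 300))
  expect_equal(switch_frequency(p, tr, target = 1), 0)

  # one entry over 340 nm = 1000 bp -> 1.0 per 1000 bp
  p1 <- make_path(c(2, 2, 1, 1), K = 3)
  tr1 <- make_tracks(c(0, 140, 240, 340))
  expect_equal(switch_frequency(p1, tr1, target = 1), 1.0)

  # doubling every displacement halves the frequency
  tr2 <- make_tracks(2 * c(0, 140, 240, 340))
  expect_equal(switch_frequency(p1, tr2, target = 1), 0.5)

  # zero traversal -> NA sentinel
  expect_true(is.na(switch_frequency(p1, make_tracks(c(0, 0, 0, 0)))))
})

test_that("model simulation round-trips through fitting", {
  cfg <- sim_config(seed = 55, n_tracks = 400, mean_track_frames = 60,
                    loc_noise_nm = 0, blink_prob = 0, dna_length_nm = Inf)
  gen <- simulate_multistate(cfg)
  m <- fit_hmm(gen$tracks, K = 3, n_restarts = 2, seed = 8)
  sim <- simulate(m, nsim = 300, seed = 9, n_frames = 80)
  m2 <- fit_hmm(sim, K = 3, n_restarts = 2, seed = 10)
  expect_true(all(abs(m2$D - m$D) / m$D < 0.15))
})
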
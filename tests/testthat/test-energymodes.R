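test_that("the rotation-coupled friction formula evaluates correctly", {
  # direct evaluation frozen from an independent hand computation of
  # kB*T / [6 pi eta R + (2 pi / l)^2 (8 pi eta R^3 + 6 pi eta R Roc^2)]
  p <- hydro_params(radius_nm = 2.2, offset_nm = 3.2, pitch_nm = 3.57,
                    viscosity = 0.89e-3, temperature = 298)
  expect_equal(hydrodynamic_limit(p), 2.114953, tolerance = 1e-6)

  # infinite pitch decouples rotation: Stokes-Einstein translational limit
  kB <- 1.380649e-23
  se <- kB * 298 / (6 * pi * 0.89e-3 * 2.2e-9) * 1e12
  p_inf <- hydro_params(radius_nm = 2.2, offset_nm = 3.2, pitch_nm = 1e9)
  expect_equal(hydrodynamic_limit(p_inf), se, tolerance = 1e-6 * se)

  # strictly decreasing in radius, offset, and 1/pitch
  d0 <- hydrodynamic_limit(hydro_params(2.5))
  expect_lt(hydrodynamic_limit(hydro_params(3.0)), d0)
  expect_lt(hydrodynamic_limit(hydro_params(2.5, offset_nm = 5)), d0)
  expect_gt(hydrodynamic_limit(hydro_params(2.5, pitch_nm = 10)), d0)

  expect_error(hydro_params(-1), "positive")
})

test_that("protein presets reproduce the published sliding speed limits", {
  expect_equal(round(hydrodynamic_limit(protein_hydro("hogg1")), 2), 0.89)
  expect_equal(round(hydrodynamic_limit(protein_hydro("endov")), 2), 1.3)
})

test_that("the stepping rate constant converts units correctly", {
  expect_equal(rate_constant(0), 0)
  # D = 1.3 um^2/s at 0.34 nm/bp: k = 2 * 1.3e6 / 0.34^2 per second
  expect_equal(rate_constant(1.3), 2 * 1.3e6 / 0.34^2, tolerance = 1e-12)
  expect_equal(rate_constant(1.3), 22491349, tolerance = 1)
  # linear in D
  expect_equal(rate_constant(2 * 0.7), 2 * rate_constant(0.7))
  # stretched DNA increases the effective rise
  expect_equal(rate_constant(1, stretch = 0.95), 2e6 / (0.34 * 0.95)^2)
})

test_that("activation energies satisfy the Arrhenius identities", {
  expect_equal(activation_energy(1.3, 1.3), 0)
  expect_equal(activation_energy(1.3 / exp(1), 1.3), 1)
  expect_equal(activation_energy(0.645, 1.3), log(1.3 / 0.645))
  expect_equal(activation_energy(0.645, 1.3), 0.701, tolerance = 1e-3)
  # above the limit the barrier is negative
  expect_lt(activation_energy(2.0, 1.3), 0)
  # D_inst = 0 -> +Inf sentinel
  expect_identical(activation_energy(0, 1.3), Inf)
  expect_error(activation_energy(0.5, -1), "positive")

  # strictly decreasing in D_inst; additive under multiplicative change
  e1 <- activation_energy(0.2, 1.3)
  e2 <- activation_energy(0.4, 1.3)
  expect_gt(e1, e2)
  expect_equal(activation_energy(0.2 / 3, 1.3), e1 + log(3))
})

test_that("mode classification implements the three barrier ranges", {
  expect_equal(as.character(classify_mode(2.5)), "interrogation")
  expect_equal(as.character(classify_mode(1.0)), "sliding")
  expect_equal(as.character(classify_mode(-0.3)), "hopping")
  # E_a = 0 means sliding at the speed limit -> hopping range
  expect_equal(as.character(classify_mode(0)), "hopping")
  # boundary convention: closed from below
  expect_equal(as.character(classify_mode(0.5)), "sliding")
  expect_equal(as.character(classify_mode(2.0)), "interrogation")
  expect_equal(as.character(classify_mode(Inf)), "interrogation")
})

test_that("mode statistics aggregate occupancy and per-mode diffusion", {
  tr <- make_tracks(seq(0, 1100, by = 100))
  ser <- instantaneous_diffusion(tr)
  prof <- energy_profile(ser, D_ideal = 10)  # all well below the limit
  expect_true(all(prof$mode == "interrogation"))
  st <- mode_statistics(prof, ser)
  expect_equal(st$occupancy, c(1, 0, 0))
  expect_equal(sum(st$occupancy), 1)
  expect_equal(st$mean_D[1], 0.01 / 0.015)

  # misaligned inputs error
  bad <- ser[seq_len(nrow(ser) - 1), ]
  expect_error(mode_statistics(prof, bad), "aligned")
})

test_that("mode mean diffusion is ordered on well-separated 3-state data", {
  cfg <- sim_config(seed = 5, n_tracks = 300, mean_track_frames = 50,
                    loc_noise_nm = 0, blink_prob = 0)
  gen <- simulate_multistate(cfg)
  ser <- suppressWarnings(instantaneous_diffusion(gen$tracks))
  prof <- energy_profile(ser, hydrodynamic_limit(protein_hydro("endov")))
  st <- mode_statistics(prof, ser)
  expect_lt(st$mean_D[st$mode == "interrogation"],
            st$mean_D[st$mode == "sliding"])
  expect_lt(st$mean_D[st$mode == "sliding"],
            st$mean_D[st$mode == "hopping"])
  expect_equal(sum(st$occupancy), 1, tolerance = 1e-12)
})

test_that("single-mode barrier occupancies match the chi-square tail law", {
  D <- 0.645
  D_ideal <- 1.3
  rw <- simulate_random_walk(D, n_frames = 1e5 + 4, dt = 0.0075, seed = 31)
  ser <- instantaneous_diffusion(rw$tracks)
  prof <- energy_profile(ser, D_ideal)
  occ <- mode_statistics(prof, ser)$occupancy
  # E_a >= t  <=>  D_inst <= D_ideal e^-t; D_inst/D ~ chi^2_4 / 4
  p_at <- function(t) stats::pchisq(4 * D_ideal * exp(-t) / D, df = 4)
  expected <- c(p_at(2), p_at(0.5) - p_at(2), 1 - p_at(0.5))
  expect_true(all(abs(occ - expected) < 0.02))
})

test_that("salt-series aggregation reports per-mode fold changes", {
  mk_stats <- function(d) {
    structure(data.frame(mode = mode_levels(), occupancy = c(0.3, 0.4, 0.3),
                         mean_D = d, sd_D = 0.1, sem_D = 0.01,
                         n = c(300, 400, 300)),
              class = c("mode_stats", "data.frame"))
  }
  base <- mk_stats(c(0.05, 0.4, 1.2))

  # identical conditions -> all fold changes 1
  out <- salt_series(list(low = base, high = base))
  expect_true(all(out$fold_change == 1))

  # only the hopping mode scaled 1.5x in the high-salt condition
  high <- mk_stats(c(0.05, 0.4, 1.8))
  out <- salt_series(list(`25mM` = base, `100mM` = high))
  hi <- out[out$condition == "100mM", ]
  expect_equal(hi$fold_change[hi$mode == "hopping"], 1.5)
  expect_equal(hi$fold_change[hi$mode == "sliding"], 1)

  expect_error(salt_series(list(a = base), baseline = "b"), "unknown condition")
})

test_that("per-mode SEM shrinks as 1/sqrt(n) when data are replicated", {
  set.seed(8)
  d <- rlnorm(200, -1, 1)
  mk <- function(v) {
    ser <- structure(data.frame(track_id = 1L, frame = seq_along(v) - 1L,
                                D_inst_um2_s = v, bridged_window = FALSE),
                     class = c("diffusion_series", "data.frame"))
    prof <- energy_profile(ser, 1.3)
    mode_statistics(prof, ser)
  }
  s1 <- mk(d)
  s4 <- mk(rep(d, 4))
  ok <- s1$n > 1
  expect_equal(s4$sem_D[ok], s1$sem_D[ok] / 2, tolerance = 0.01)
})
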
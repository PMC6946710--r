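test_that("cluster anisotropy reduces to the monomer value without transfer", {
  m <- dimer_model(coupling = 1)
  expect_equal(cluster_anisotropy(1L, m), m$r_mono)
  m0 <- oligomer_model(4L, r_mono = 0.3, coupling = 0)
  expect_equal(cluster_anisotropy(1:4, m0), rep(0.3, 4))
  # two coupled fluorophores share the excitation equally at omega*tau = 1
  expect_equal(cluster_anisotropy(2L, dimer_model(1)), 0.35 * 2 / 3,
               tolerance = 1e-12)
  expect_error(cluster_anisotropy(3L, m), "n_subunits")
})

test_that("oligomer model validates its domain and d/R0 coupling", {
  expect_error(oligomer_model(2, r_mono = 0.5), "r_mono")
  expect_error(oligomer_model(2, r_et = -0.3), "r_et")
  m <- oligomer_model(4, d_over_r0 = 0.8)
  expect_equal(m$coupling, 0.8^-6, tolerance = 1e-12)
})

test_that("ensemble anisotropy is a binomial mixture with unit weights", {
  for (n in c(2L, 5L, 12L)) {
    m <- oligomer_model(n, r_mono = 0.35, r_et = 0.02, coupling = 0.7)
    for (p in c(0, 0.25, 0.5, 0.75, 1)) {
      w <- stats::dbinom(0:(n - 1L), n - 1L, p)
      expect_lt(abs(sum(w) - 1), 1e-12)
      expect_equal(ensemble_anisotropy(p, m), ensemble_oracle(p, m),
                   tolerance = 1e-12)
      # bounded between the sensitized and monomer anisotropies
      r <- ensemble_anisotropy(p, m)
      expect_gte(r, min(m$r_et, m$r_mono) - 1e-12)
      expect_lte(r, m$r_mono + 1e-12)
    }
  }
  expect_equal(ensemble_anisotropy(0, dimer_model()), 0.35)
  expect_equal(ensemble_anisotropy(0.3, monomer_model()), 0.35)
})

test_that("dimer ensemble anisotropy is exactly affine in the on-fraction", {
  m <- dimer_model(coupling = 1.3)
  p <- seq(0, 1, by = 0.05)
  r <- ensemble_anisotropy(p, m)
  chord <- r[1L] + (r[length(r)] - r[1L]) * p
  expect_lt(max(abs(r - chord)), 1e-12)
  expect_equal(ensemble_anisotropy(0.5, m), (r[1L] + r[length(r)]) / 2,
               tolerance = 1e-12)
})

test_that("higher oligomers bow upward, less so at larger separations", {
  # the convex anisotropy-vs-switched-fraction profile of a tight oligomer
  # sags below the chord in the on-fraction orientation; the sag magnitude
  # is the upward-curvature measure
  m <- oligomer_model(4, r_mono = 0.35, r_et = 0, d_over_r0 = 0.8)
  chord_dev <- function(model) {
    ends <- ensemble_anisotropy(c(0, 1), model)
    mean(ends) - ensemble_anisotropy(0.5, model)
  }
  expect_gt(chord_dev(m), 0)
  for (n in c(3L, 4L, 5L)) {
    devs <- vapply(seq(0.5, 1.5, by = 0.1), function(d)
      chord_dev(oligomer_model(n, r_mono = 0.35, r_et = 0, d_over_r0 = d)),
      numeric(1))
    expect_true(all(devs >= -1e-15))
    expect_true(all(diff(devs) <= 1e-12))
  }
})

test_that("channel projection matches the mixing equations and inverts", {
  # no mixing: clean inversion of the r / F_tot definitions
  ch <- project_to_channels(1 / 3, 9, optics_config(apply_axelrod = FALSE))
  expect_equal(ch$i_par, 5)
  expect_equal(ch$gi_perp, 2)
  # isotropic emission gives balanced channels at any angle
  opt60 <- optics_config(na = 1.515 * sin(pi / 3), refractive_index = 1.515,
                         apply_axelrod = TRUE)
  ch0 <- project_to_channels(0, 7, opt60)
  expect_equal(ch0$i_par, ch0$gi_perp, tolerance = 1e-12)
  # hand-evaluated mixing at theta = 60 degrees from (Iz, Iy) = (5, 2)
  ch60 <- project_to_channels(1 / 3, 9, opt60)
  expect_equal(ch60$i_par, 4.34375, tolerance = 1e-10)
  expect_equal(ch60$gi_perp, 2.03125, tolerance = 1e-10)
})

test_that("simulated traces are flat without coupling or switching", {
  cond <- default_conditions(n_frames = 30L)
  noiseless <- camera_model(photons_per_fluor = 1e4, read_noise_sd = 0,
                            offset = 0)
  # no switching: total fluorescence constant in expectation
  sim <- simulate_trace(dimer_model(), switching_params(0, 30L), noiseless,
                        cond$optics, n_oligomers = 2000L, seed = 11L)
  a <- anisotropy_trace(sim$trace, cond$optics)
  expect_lt(diff(range(a$f_tot)) / mean(a$f_tot), 0.01)
  # no coupling: anisotropy flat over the photoswitching cycle
  sim0 <- simulate_trace(oligomer_model(2, coupling = 0), cond$switching,
                         noiseless, cond$optics, n_oligomers = 2000L,
                         seed = 12L)
  a0 <- anisotropy_trace(sim0$trace, cond$optics)
  keep <- a0$fraction_switched <= 0.8
  expect_lt(diff(range(a0$r[keep])), 0.02)
  expect_equal(sim0$truth$drfret_true, 0)
})

test_that("noise-free dimer pipeline recovers the closed-form ground truth", {
  m <- dimer_model(coupling = 1)
  sim <- simulate_trace(m, switching_params(0.08, 50L),
                        camera_model(photons_per_fluor = 1e4,
                                     read_noise_sd = 0, offset = 0),
                        optics_config(apply_axelrod = FALSE),
                        n_oligomers = 10000L, seed = 3L)
  res <- analyze_trace(sim$trace)
  expect_lt(abs(res$drfret - sim$truth$drfret_true), 0.01)
  expect_equal(sim$truth$r_et1_true, 0.35 * 2 / 3, tolerance = 1e-12)
  expect_equal(sim$truth$r_et0_true, 0.35)
})

test_that("ground truth drFRET is consistent with the conversion formula", {
  for (cpl in c(0.3, 1, 4)) {
    sim <- simulate_trace(dimer_model(cpl), switching_params(0.1, 10L),
                          n_oligomers = 10L, seed = 5L)
    expect_equal(sim$truth$drfret_true,
                 drfret(sim$truth$r_et0_true, sim$truth$r_et1_true),
                 tolerance = 1e-12)
  }
})

test_that("rendered stacks are deterministic and carry the right baseline", {
  dir <- withr::local_tempdir()
  args <- list(model = dimer_model(), switching = switching_params(0.1, 8L),
               scene = scene_config(32L, 32L), n_oligomers = 500L,
               seed = 42L, dir = dir)
  r1 <- do.call(render_stack, c(args, basename = "a"))
  r2 <- do.call(render_stack, c(args, basename = "b"))
  expect_identical(readBin(r1$paths$stack, "raw", file.size(r1$paths$stack)),
                   readBin(r2$paths$stack, "raw", file.size(r2$paths$stack)))
  expect_equal(r1$truth$drfret_true, r2$truth$drfret_true)

  # zero-signal scene: background ROI mean sits at the camera offset
  dark <- render_stack(monomer_model(), switching_params(0.1, 6L),
                       camera_model(photons_per_fluor = 0),
                       scene = scene_config(32L, 32L), n_oligomers = 10L,
                       seed = 7L, dir = dir, basename = "dark")
  stacks <- read_stack(dark$paths$stack)
  rois <- read_roi_json(dark$paths$roi)
  tr <- extract_trace(stacks$par, stacks$perp, rois$cell, rois$background)
  expect_lt(abs(mean(tr$bg_par) - camera_model()$offset), 0.5)
  expect_lt(abs(mean(tr$mean_par) - camera_model()$offset), 0.5)
})

test_that("rendered stack analyzed end-to-end reproduces the trace truth", {
  dir <- withr::local_tempdir()
  r <- render_stack(dimer_model(), switching_params(0.08, 50L),
                    scene = scene_config(48L, 48L), n_oligomers = 10000L,
                    seed = 9L, dir = dir)
  stacks <- read_stack(r$paths$stack)
  rois <- read_roi_json(r$paths$roi)
  tr <- extract_trace(stacks$par, stacks$perp, rois$cell, rois$background)
  res <- analyze_trace(tr)
  expect_lt(abs(res$drfret - r$truth$drfret_true), 0.01)
})
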
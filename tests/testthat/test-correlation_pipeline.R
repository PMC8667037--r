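test_that("detrending removes means and linear ramps", {
  const <- array(7, dim = c(20, 8, 8))
  expect_true(all(detrend_pixels(const, 0) == 0))
  ramp <- array(rep(1:20, 64), dim = c(20, 8, 8)) * 0.3 + 2
  expect_lt(max(abs(detrend_pixels(ramp, 1))), 1e-10)
  set.seed(1)
  noise <- array(rnorm(20 * 64), dim = c(20, 8, 8))
  dF <- detrend_pixels(noise, 0)
  expect_lt(max(abs(apply(dF, c(2, 3), mean))), 1e-12)
  expect_error(detrend_pixels(array(1, dim = c(5, 4, 4))), "10 frames")
})

test_that("immobile noise-free scenes give exactly zero correlation", {
  opt <- tiny_optics(frames = 30L)
  win <- list(start = 0, frame_times = (0:29) / 30,
              frames = rep(list(matrix(c(2, 2, 1, 3), 2, 2)), 30L))
  stk <- render_stack(win, opt, noise_free_camera(), brightness = 5, seed = 1L)
  expect_identical(correlation_parameter(stk)$value, 0)
})

test_that("white detector noise cancels at lag >= 1", {
  set.seed(2)
  nt <- 100
  data <- array(100 + rnorm(nt * 64 * 64, 0, 5), dim = c(nt, 64, 64))
  C <- correlation_parameter(data, lag = 1, offset = 0)$value
  # mean removal leaves a small-sample bias of -sigma^2/T in the lag-1
  # autocovariance; around it the estimator scatters with
  # s.e. ~ sigma^2 / (mean^2 sqrt(n_pix n_pairs))
  bias <- -25 / nt / 100^2
  se <- 25 / (100^2 * sqrt(64 * 64 * (nt - 1)))
  expect_lt(abs(C - bias), 4 * se)
  expect_lt(abs(C), 5e-5)  # negligible against real-scene values of order 1
})

test_that("correlation is invariant under brightness rescaling", {
  opt <- tiny_optics(frames = 40L)
  win <- simulate_mixture_window(200, q = 1, D = 0.2, optics = opt,
                                 n_frames = 40L, seed = 3L)
  cam <- noise_free_camera(offset = 0)
  s1 <- render_stack(win, opt, cam, brightness = win$brightness, seed = 1L)
  C1 <- correlation_parameter(s1, offset = 0)$value
  # a*F: double the per-fluorophore yield
  cam2 <- noise_free_camera(offset = 0,
                            photons_per_fluorophore_per_frame = 200)
  s2 <- render_stack(win, opt, cam2, brightness = win$brightness, seed = 1L)
  C2 <- correlation_parameter(s2, offset = 0)$value
  expect_equal(C1, C2, tolerance = 1e-10)
  # a*F + b with the offset supplied to the normalization
  cam3 <- noise_free_camera(offset = 250,
                            photons_per_fluorophore_per_frame = 200)
  s3 <- render_stack(win, opt, cam3, brightness = win$brightness, seed = 1L)
  C3 <- correlation_parameter(s3, offset = 250)$value
  expect_equal(C1, C3, tolerance = 1e-10)
  expect_gt(C1, 0)
})

test_that("correlation rejects degenerate inputs", {
  data <- array(0, dim = c(30, 4, 4))
  expect_error(correlation_parameter(data), "undefined")
  data2 <- array(100, dim = c(30, 4, 4))
  expect_error(correlation_parameter(data2, lag = 20), "lag")
})

test_that("correlation scales inversely with particle density", {
  opt <- optics_config(field_size = 64)
  cam <- noise_free_camera(photons_per_fluorophore_per_frame = 50, offset = 0)
  Cs <- vapply(c(1, 2), function(mult) {
    win <- simulate_mixture_window(10000L * mult, q = 1, D = 0.2,
                                   optics = opt, n_frames = 80L,
                                   seed = 11L + mult)
    stk <- render_stack(win, opt, cam, brightness = win$brightness, seed = mult)
    correlation_parameter(stk, offset = 0)$value
  }, numeric(1))
  expect_equal(Cs[1] / Cs[2], 2, tolerance = 0.1)
})

test_that("regrouping monomers into oligomers raises the correlation", {
  opt <- tiny_optics(frames = 60L, field = 48L)
  cam <- noise_free_camera(offset = 0)
  tab <- validate_sensitivity(q_values = c(1L, 4L, 10L), phi_values = 1,
                              mobile_values = TRUE, n_fluorophores = 1500L,
                              optics = opt, camera = cam, n_frames = 60L,
                              seed = 5L)
  tab <- tab[order(tab$q), ]
  expect_true(all(diff(tab$C) > 0))
  # roughly proportional to oligomer size (number-fluctuation scaling)
  expect_equal(tab$C[tab$q == 10] / tab$C[tab$q == 1], 10, tolerance = 0.35)
})

test_that("phi = 0 reproduces the pure-monomer scene exactly under one seed", {
  opt <- tiny_optics(frames = 15L)
  ref <- simulate_mixture_window(300, q = 1, phi = 0, optics = opt,
                                 n_frames = 15L, seed = 9L)
  alt <- simulate_mixture_window(300, q = 10, phi = 0, optics = opt,
                                 n_frames = 15L, seed = 9L)
  expect_identical(ref$frames, alt$frames)
  expect_identical(ref$brightness, alt$brightness)
})

test_that("time courses are ordered, validated, and preserve values", {
  opt <- tiny_optics(frames = 20L)
  win <- list(start = 0, frame_times = (0:19) / 30,
              frames = rep(list(matrix(c(2, 2), 1, 2)), 20L))
  cam <- camera_config()
  s1 <- render_stack(win, opt, cam, brightness = 5, seed = 1L, window_time = 60)
  s2 <- render_stack(win, opt, cam, brightness = 5, seed = 1L, window_time = 10)
  tc <- correlation_timecourse(list(s1, s2))
  expect_identical(tc$time, c(10, 60))
  expect_equal(tc$value[1], tc$value[2])  # identical stacks, equal values
  expect_error(correlation_timecourse(list(s1)), "at least 2")
  s3 <- render_stack(win, opt, cam, brightness = 5, seed = 1L, window_time = 60)
  expect_error(correlation_timecourse(list(s1, s3)), "duplicate")
})

test_that("noiseless logistic decays are recovered to high precision", {
  t <- seq(0, 240, by = 10)
  truth <- list(C_peak = 2.4, C_base = 0.15, t_half = 130, width = 18)
  v <- truth$C_base + (truth$C_peak - truth$C_base) /
    (1 + exp((t - truth$t_half) / truth$width))
  fit <- fit_assembly_timescale(as_correlation_timecourse(t, v))
  expect_true(fit$fitted)
  expect_equal(fit$t_half, truth$t_half, tolerance = 1e-6)
  expect_equal(fit$width, truth$width, tolerance = 1e-6)
  expect_equal(fit$C_peak, truth$C_peak, tolerance = 1e-6)
  expect_equal(fit$C_base, truth$C_base, tolerance = 1e-6)
})

test_that("flat or insufficient traces report fitted = FALSE, never an error", {
  t <- seq(0, 100, by = 10)
  flat <- as_correlation_timecourse(t, rep(1, length(t)) + 1e-3 * sin(t))
  f1 <- fit_assembly_timescale(flat)
  expect_false(f1$fitted)
  expect_error(fit_assembly_timescale(as_correlation_timecourse(1:4, 4:1)),
               "6 time points")
})

test_that("the timescale fit is robust to multiplicative noise", {
  # 5% multiplicative noise, 24 points: t_half within 10% in >= 95% of
  # seeded replicates
  t <- seq(0, 230, by = 10)
  truth <- list(C_peak = 2.0, C_base = 0.1, t_half = 110, width = 20)
  clean <- truth$C_base + (truth$C_peak - truth$C_base) /
    (1 + exp((t - truth$t_half) / truth$width))
  set.seed(31)
  ok <- vapply(seq_len(200), function(i) {
    v <- clean * (1 + rnorm(length(t), 0, 0.05))
    fit <- fit_assembly_timescale(as_correlation_timecourse(t, v))
    fit$fitted && abs(fit$t_half - truth$t_half) / truth$t_half < 0.1
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("a simulated aggregation run yields a rise-then-fall time course", {
  sched <- data.frame(start = c(2, 8, 15, 23, 32, 42, 54, 68, 85, 105, 130,
                                160, 195),
                      n_frames = 60L, frame_rate = 30)
  cfg <- sim_config(domain_side = 8.32, n_monomers = 150L, D1 = 0.2,
                    dt = 0.015, capture_radius = 0.1, link_rate = 1.5,
                    branch_probability = 0.25, immobilize_above = 8,
                    rng_seed = 41L, total_time = 200,
                    observation_schedule = sched)
  traj <- run_assembly(cfg)
  opt <- optics_config(frames_per_window = 60L)
  cam <- camera_config()
  stacks <- lapply(seq_along(traj$windows), function(wi)
    render_stack(traj$windows[[wi]], opt, cam, brightness = 5,
                 seed = 500L + wi))
  tc <- correlation_timecourse(stacks)
  peak <- max(tc$value)
  expect_gt(peak, tc$value[1])
  expect_gt(peak, tc$value[nrow(tc)])
  # end state is essentially immobile: correlation near zero
  expect_lt(abs(tc$value[nrow(tc)]), 0.1 * peak)
})
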
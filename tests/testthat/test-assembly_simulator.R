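test_that("free monomers obey the 2D Brownian displacement law", {
  cfg <- sim_config(domain_side = 50, n_monomers = 5000L, D1 = 0.2,
                    dt = 0.01, link_rate = 0, rng_seed = 101L)
  set.seed(101)
  st <- init_cluster_state(cfg)
  p0 <- st$pos
  tau <- 0.5
  for (i in seq_len(50)) st <- advance(st, 0.01)
  msd <- mean(rowSums((st$pos - p0)^2))
  expect_equal(msd, 4 * cfg$D1 * tau, tolerance = 0.05)
})

test_that("zero diffusion leaves positions unchanged and dt must be positive", {
  cfg <- sim_config(D1 = 0, dt = 0.01, capture_radius = 1, n_monomers = 20L)
  set.seed(1)
  st <- init_cluster_state(cfg)
  p0 <- st$pos
  st <- advance(st, 0.01)
  expect_identical(st$pos, p0)
  expect_error(advance(st, 0))
})

test_that("cluster diffusion scalings are correct at n = 1 and non-increasing", {
  expect_equal(cluster_diffusion(1, 0.2, "inverse_n"), 0.2)
  expect_equal(cluster_diffusion(2, 0.2, "inverse_n"), 0.1)
  expect_equal(cluster_diffusion(1, 0.2, "saffman_delbruck_log"), 0.2)
  for (scal in c("inverse_n", "saffman_delbruck_log")) {
    d <- cluster_diffusion(1:100, 0.2, scal)
    expect_true(all(diff(d) <= 0))
    expect_true(all(d <= 0.2))
  }
  expect_error(cluster_diffusion(0, 0.2))
})

test_that("binding is a no-op at zero link rate", {
  cfg <- sim_config(domain_side = 2, n_monomers = 50L, dt = 0.005,
                    link_rate = 0, rng_seed = 3L)
  set.seed(3)
  st <- init_cluster_state(cfg)
  for (i in seq_len(100)) { st <- advance(st, 0.005); st <- detect_and_bind(st, 0.005) }
  expect_identical(length(unique(st$cluster_id)), 50L)
})

test_that("coincident monomers at extreme link rate dimerize in one step", {
  cfg <- sim_config(domain_side = 5, n_monomers = 2L, dt = 0.005,
                    link_rate = 1e9, rng_seed = 4L)
  set.seed(4)
  st <- init_cluster_state(cfg)
  st$pos <- matrix(2.5, 2L, 2L)
  st <- detect_and_bind(st, 0.005)
  expect_identical(length(unique(st$cluster_id)), 1L)
  expect_identical(unlist(st$edge_partners[[1]]), 2L)
  expect_identical(unlist(st$edge_partners[[2]]), 1L)
})

test_that("monomer conservation and bond symmetry hold along a trajectory", {
  sched <- data.frame(start = c(1, 5, 10, 15), n_frames = 5L, frame_rate = 30)
  cfg <- sim_config(domain_side = 4, n_monomers = 60L, dt = 0.01,
                    capture_radius = 0.12, link_rate = 5,
                    branch_probability = 0.5, rng_seed = 7L,
                    total_time = 16, observation_schedule = sched)
  traj <- run_assembly(cfg)
  for (dist in traj$size_distributions)
    expect_identical(sum(dist * seq_along(dist)), 60L)
  st <- traj$final_state
  expect_identical(sum(tabulate(st$cluster_id)), 60L)
  for (i in seq_along(st$edge_partners)) {
    for (j in unlist(st$edge_partners[[i]])) {
      expect_true(i %in% unlist(st$edge_partners[[j]]))
      expect_identical(st$cluster_id[i], st$cluster_id[j])
    }
  }
  # at least some assembly happened at this density and rate
  expect_lt(length(unique(st$cluster_id)), 60L)
})

test_that("scaffold rule forbids branching and anti-parallel bonds", {
  cfg <- sim_config(domain_side = 3, n_monomers = 80L, dt = 0.01,
                    capture_radius = 0.15, link_rate = 50,
                    orientation_rule = "parallel_only",
                    angular_tolerance = pi / 6,
                    rng_seed = 11L, total_time = 30,
                    observation_schedule = data.frame(start = 29, n_frames = 2L,
                                                      frame_rate = 30))
  traj <- run_assembly(cfg)
  st <- traj$final_state
  expect_lt(length(unique(st$cluster_id)), 80L)  # binding did occur
  for (i in seq_along(st$edge_partners)) {
    for (e in 1:2) {
      partners <- st$edge_partners[[i]][[e]]
      expect_lte(length(partners), 1L)
      for (j in partners) {
        dtheta <- abs(atan2(sin(st$polarity[i] - st$polarity[j]),
                            cos(st$polarity[i] - st$polarity[j])))
        expect_lte(dtheta, pi / 6 + 1e-12)
      }
    }
  }
})

test_that("trajectories are reproducible from the seed and time-zero runs are inert", {
  sched <- data.frame(start = c(0.5, 1.5), n_frames = 3L, frame_rate = 30)
  cfg <- sim_config(domain_side = 3, n_monomers = 40L, dt = 0.01,
                    link_rate = 10, rng_seed = 13L, total_time = 2,
                    observation_schedule = sched)
  t1 <- run_assembly(cfg)
  t2 <- run_assembly(cfg)
  expect_identical(t1$final_state$pos, t2$final_state$pos)
  expect_identical(t1$final_state$cluster_id, t2$final_state$cluster_id)
  cfg0 <- sim_config(n_monomers = 10L, total_time = 0, rng_seed = 13L)
  t0 <- run_assembly(cfg0)
  expect_identical(t0$final_state$time, 0)
  expect_identical(length(unique(t0$final_state$cluster_id)), 10L)
})

test_that("mean cluster size never decreases (bonds are permanent)", {
  sched <- data.frame(start = c(1, 4, 8, 12, 16), n_frames = 2L, frame_rate = 30)
  cfg <- sim_config(domain_side = 4, n_monomers = 80L, dt = 0.01,
                    capture_radius = 0.12, link_rate = 8, rng_seed = 17L,
                    total_time = 17, observation_schedule = sched)
  traj <- run_assembly(cfg)
  expect_true(all(diff(traj$summary$mean_size) >= 0))
})

test_that("immobile fraction counts monomers in effectively frozen clusters", {
  # free monomers travel far beyond a sub-resolution threshold: none immobile
  st <- make_state(rep(1L, 20), D1 = 0.2)
  expect_equal(immobile_fraction(st, displacement_threshold = 0.001,
                                 horizon = 10), 0)
  # one giant, essentially frozen cluster: all immobile
  stg <- make_state(2000L, D1 = 0.2)
  expect_equal(immobile_fraction(stg, 0.13, 10), 1)
  # 50:50 split between monomers and 100-mers at a threshold between their
  # r.m.s. displacements
  st2 <- make_state(c(rep(1L, 100), 100L), D1 = 0.2)
  rms1 <- sqrt(4 * 0.2 * 10)
  rms100 <- sqrt(4 * 0.2 / 100 * 10)
  thr <- sqrt(rms1 * rms100)
  expect_equal(immobile_fraction(st2, thr, 10), 0.5)
  # pinning overrides size scaling
  st3 <- make_state(c(rep(1L, 10), 10L), D1 = 0.2, immobilize_above = 8)
  expect_equal(immobile_fraction(st3, 1e-6, 10), 0.5)
  expect_error(immobile_fraction(st, -1, 10))
})

test_that("step-resolution condition is enforced", {
  expect_error(sim_config(D1 = 0.2, dt = 0.1, capture_radius = 0.1),
               "step-resolution")
})

test_that("dimer-formation times match a well-mixed stochastic birth process", {
  # spatially resolved simulation in a fast-mixing small domain vs. the
  # analytic first-event law of a well-mixed pairing process with per-pair
  # rate k = link_rate * (pi r^2 / A)
  L <- 3; r <- 0.1; lr <- 0.5; n <- 12L; dt <- 0.004
  k_pair <- lr * pi * r^2 / L^2
  rate_total <- k_pair * n * (n - 1) / 2
  n_rep <- 60L
  set.seed(23)
  times <- vapply(seq_len(n_rep), function(rep) {
    cfg <- sim_config(domain_side = L, n_monomers = n, D1 = 1, dt = dt,
                      capture_radius = r, link_rate = lr,
                      rng_seed = 1000L + rep)
    st <- init_cluster_state(cfg)
    t_elapsed <- 0
    while (length(unique(st$cluster_id)) == n && t_elapsed < 150) {
      st <- advance(st, dt)
      st <- detect_and_bind(st, dt)
      t_elapsed <- t_elapsed + dt
    }
    t_elapsed
  }, numeric(1))
  mean_expected <- 1 / rate_total
  # empirical s.e.: contact-time burstiness inflates the variance beyond the
  # exponential law, so the sample variance is the honest scale
  se <- sd(times) / sqrt(n_rep)
  expect_lt(abs(mean(times) - mean_expected), 3 * se)
})
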
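# Shared fixtures: small configurations used across test files.

tiny_optics <- function(frames = 40L, field = 32L)
  optics_config(frames_per_window = frames, field_size = field)

noise_free_camera <- function(...)
  camera_config(read_noise_sd = 0, shot_noise = FALSE, ...)

# Brute-force reading-frame oracle: slide the docking site along the sticker
# one offset at a time and count offsets at which every docking nucleotide
# lies inside the sticker.
brute_force_frames <- function(sticker, docking) {
  count <- 0L
  for (offset in seq(-docking, sticker)) {
    covered <- all(seq(offset + 1L, offset + docking) >= 1L &
                     seq(offset + 1L, offset + docking) <= sticker)
    if (covered) count <- count + 1L
  }
  count
}

# Brute-force non-overlapping interval packing: greedily place docking-site
# footprints on the connector and count how many fit.
brute_force_occupancy <- function(binding_len, docking) {
  count <- 0L
  pos <- 1L
  while (pos + docking - 1L <= binding_len) {
    count <- count + 1L
    pos <- pos + docking
  }
  count
}

# Hand-built cluster state: n-vector of cluster sizes, all monomers at the
# origin, default config fields overridable.
make_state <- function(sizes, ...) {
  cfg <- sim_config(n_monomers = sum(sizes), ...)
  n <- sum(sizes)
  cluster_id <- rep(seq_along(sizes), sizes)
  structure(
    list(time = 0, pos = matrix(0.5, n, 2L), polarity = rep(0, n),
         cluster_id = cluster_id,
         edge_partners = rep(list(list(integer(0), integer(0))), n),
         config = cfg),
    class = "cluster_state")
}

# The two-condition order-of-magnitude comparison used by the acceptance
# suite: link rates differing 10-fold, schedules matched to each condition's
# kinetics (observation continues until immobilization completes, as in
# experiments where slow conditions are simply observed longer).
ratio_experiment_config <- function(n_replicates, master_seed) {
  slow_sched <- data.frame(
    start = c(5, 30, 60, 95, 135, 180, 230, 285, 345, 410, 480, 555, 635, 700),
    n_frames = 60L, frame_rate = 30)
  fast_sched <- data.frame(
    start = c(2, 8, 15, 23, 32, 42, 54, 68, 85, 105, 130, 160, 195),
    n_frames = 60L, frame_rate = 30)
  base <- sim_config(domain_side = 8.32, n_monomers = 150L, D1 = 0.2,
                     dt = 0.015, capture_radius = 0.1, link_rate = 0,
                     branch_probability = 0.25, immobilize_above = 8,
                     total_time = 710, observation_schedule = slow_sched)
  cn <- connector_spec("repeat", total_length = 40L, concentration = 250)
  b <- 0.15 / (reading_frames(40L, 7L) * 250e-9)
  conds <- list(
    condition_spec("slow", cn, model = rate_model(b)),
    condition_spec("fast", cn, model = rate_model(10 * b),
                   sim_overrides = list(total_time = 200,
                                        observation_schedule = fast_sched)))
  experiment_config(conds, base,
                    optics = optics_config(frames_per_window = 60L),
                    n_replicates = n_replicates, master_seed = master_seed)
}
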
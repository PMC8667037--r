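#' Simulation configuration
#'
#' Parameters of the stochastic 2D diffusion-aggregation simulation of
#' membrane-anchored origami monomers. Monomers perform Brownian motion on a
#' periodic square domain and cross-link through connector-dependent edge
#' binding; bonded clusters move rigidly with a size-dependent diffusion
#' coefficient. Connectors are coarse-grained into a single per-edge-pair
#' `link_rate` (see [link_rate_from_connector()]).
#'
#' @param domain_side Side of the square periodic domain, in um.
#' @param n_monomers Number of monomers.
#' @param D1 Monomer diffusion coefficient in um^2/s (membrane-anchored
#'   origami diffuse at about 0.2 um^2/s).
#' @param dt Integration time step in s. Must satisfy
#'   `sqrt(2 * D1 * dt) < capture_radius` so that a particle cannot jump
#'   through the capture zone in one step.
#' @param capture_radius Contact distance in um below which an eligible edge
#'   pair is exposed to the binding hazard.
#' @param link_rate First-order bond-formation rate (per second) for an
#'   eligible edge pair in contact.
#' @param branch_probability Probability that an already-occupied edge
#'   accepts an additional partner (repeat connectors only; scaffold binding
#'   is strictly one partner per edge).
#' @param orientation_rule `"parallel_only"` (scaffold connectors: bonds only
#'   between near-parallel monomers, head edge to tail edge) or `"any"`
#'   (repeat connectors: any edge pair, any mutual orientation).
#' @param angular_tolerance Half-width, in radians, of the polarity window
#'   accepted as "parallel" under `orientation_rule = "parallel_only"`.
#' @param size_scaling Cluster diffusion rule, `"inverse_n"` (D1/n) or
#'   `"saffman_delbruck_log"` (weak logarithmic decay typical of membrane
#'   inclusions).
#' @param sd_length_ratio Ratio of the Saffman-Delbruck length to the monomer
#'   radius, used only by the logarithmic scaling.
#' @param immobilize_above Cluster size above which a cluster is pinned
#'   (diffusion coefficient 0): a coarse model of the crowding/jamming that
#'   immobilizes large membrane-bound assemblies, which pure size scaling
#'   cannot reproduce at desk-scale monomer counts. `Inf` (default) disables
#'   pinning. Pinned clusters still accept bonds from mobile ones.
#' @param rng_seed Integer seed making [run_assembly()] deterministic.
#' @param total_time Total simulated time in s.
#' @param observation_schedule Data frame with columns `start` (s),
#'   `n_frames`, `frame_rate` (Hz): the camera observation windows, matching
#'   shuttered-laser acquisition (imaging only during windows).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(domain_side = 20,
                       n_monomers = 100L,
                       D1 = 0.2,
                       dt = 0.001,
                       capture_radius = 0.1,
                       link_rate = 0,
                       branch_probability = 0.25,
                       orientation_rule = c("any", "parallel_only"),
                       angular_tolerance = pi / 6,
                       size_scaling = c("inverse_n", "saffman_delbruck_log"),
                       sd_length_ratio = 1000,
                       immobilize_above = Inf,
                       rng_seed = 1L,
                       total_time = 0,
                       observation_schedule = NULL) {
  orientation_rule <- match.arg(orientation_rule)
  size_scaling <- match.arg(size_scaling)
  if (domain_side <= 0 || n_monomers < 1 || D1 < 0 || dt <= 0 ||
      capture_radius <= 0 || link_rate < 0 || total_time < 0)
    stop("invalid simulation parameters")
  if (branch_probability < 0 || branch_probability > 1)
    stop("branch_probability must be in [0, 1]")
  if (sqrt(2 * D1 * dt) >= capture_radius)
    stop("step-resolution condition violated: sqrt(2*D1*dt) must be < capture_radius")
  if (!is.null(observation_schedule)) {
    stopifnot(is.data.frame(observation_schedule),
              all(c("start", "n_frames", "frame_rate") %in%
                    names(observation_schedule)))
    observation_schedule <-
      observation_schedule[order(observation_schedule$start), , drop = FALSE]
  }
  structure(
    list(domain_side = domain_side, n_monomers = as.integer(n_monomers),
         D1 = D1, dt = dt, capture_radius = capture_radius,
         link_rate = link_rate, branch_probability = branch_probability,
         orientation_rule = orientation_rule,
         angular_tolerance = angular_tolerance,
         size_scaling = size_scaling, sd_length_ratio = sd_length_ratio,
         immobilize_above = immobilize_above,
         rng_seed = as.integer(rng_seed), total_time = total_time,
         observation_schedule = observation_schedule),
    class = "sim_config")
}

#' Initial particle configuration
#'
#' Places monomers uniformly at random on the domain with uniform random
#' polarities; every monomer starts as its own cluster with all edges free.
#'
#' @param config A [sim_config()].
#' @return An object of class `cluster_state`: positions (um, unwrapped),
#'   polarity angles, cluster ids, per-edge partner lists and the config.
#' @export
init_cluster_state <- function(config) {
  n <- config$n_monomers
  pos <- matrix(stats::runif(2L * n, 0, config$domain_side), ncol = 2L)
  polarity <- stats::runif(n, -pi, pi)
  edges <- rep(list(list(integer(0), integer(0))), n)
  structure(
    list(time = 0, pos = pos, polarity = polarity,
         cluster_id = seq_len(n), edge_partners = edges, config = config),
    class = "cluster_state")
}

#' Cluster diffusion coefficient
#'
#' Size dependence of the rigid-cluster diffusion coefficient. `"inverse_n"`
#' uses D1/n (Stokes-like for compact aggregates); `"saffman_delbruck_log"`
#' uses the weak logarithmic decay of membrane-inclusion mobility,
#' `D_n = D1 * (ln(lambda) - gamma - ln(sqrt(n))) / (ln(lambda) - gamma)`
#' with `lambda` the Saffman-Delbruck length over the monomer radius and
#' gamma the Euler-Mascheroni constant, floored at 0. Both rules return D1 at
#' n = 1 and are non-increasing in n.
#'
#' @param n Cluster size (monomer count), >= 1.
#' @param D1 Monomer diffusion coefficient, um^2/s.
#' @param size_scaling `"inverse_n"` or `"saffman_delbruck_log"`.
#' @param sd_length_ratio Length-ratio proxy lambda for the logarithmic rule.
#' @return Diffusion coefficient(s) in um^2/s.
#' @export
cluster_diffusion <- function(n, D1,
                              size_scaling = c("inverse_n",
                                               "saffman_delbruck_log"),
                              sd_length_ratio = 1000) {
  size_scaling <- match.arg(size_scaling)
  if (any(n < 1)) stop("cluster size must be >= 1")
  if (size_scaling == "inverse_n") return(D1 / n)
  gamma_em <- 0.5772156649015329
  denom <- log(sd_length_ratio) - gamma_em
  if (denom <= 0) stop("sd_length_ratio too small for log scaling")
  pmax(0, D1 * (denom - 0.5 * log(n)) / denom)
}

# Size-scaled cluster diffusion coefficients including the optional
# crowding/jamming pin above `immobilize_above` monomers.
effective_cluster_D <- function(sizes, cfg) {
  Dn <- cluster_diffusion(pmax(sizes, 1L), cfg$D1, cfg$size_scaling,
                          cfg$sd_length_ratio)
  if (is.finite(cfg$immobilize_above)) Dn[sizes > cfg$immobilize_above] <- 0
  Dn
}

# Compact cluster ids to 1..n_clusters (stable order).
compact_clusters <- function(cluster_id) match(cluster_id, unique(cluster_id))

cluster_sizes <- function(state) {
  tabulate(state$cluster_id, nbins = max(state$cluster_id))
}

#' Brownian step for all clusters
#'
#' Translates every cluster rigidly by an isotropic Gaussian displacement
#' with per-component variance `2 * D_n * dt`; positions are kept unwrapped
#' (periodic wrapping is applied only when distances or images are needed).
#' No binding occurs here.
#'
#' @param state A `cluster_state`.
#' @param dt Time step in s.
#' @return The advanced `cluster_state`.
#' @export
advance <- function(state, dt) {
  if (dt <= 0) stop("dt must be > 0")
  cfg <- state$config
  sizes <- cluster_sizes(state)
  nc <- length(sizes)
  Dn <- effective_cluster_D(sizes, cfg)
  sd_step <- sqrt(2 * Dn * dt)
  disp <- matrix(stats::rnorm(2L * nc), ncol = 2L) * sd_step
  state$pos <- state$pos + disp[state$cluster_id, , drop = FALSE]
  state$time <- state$time + dt
  state
}

# Wrapped (periodic) positions for distance computation and rendering.
wrapped_positions <- function(state) {
  state$pos %% state$config$domain_side
}

# Pick a binding edge for monomer `i` under the repeat rule. Returns
# list(edge, gate): a uniformly chosen free edge with gate 1, or, when all
# edges are occupied and branching is allowed, a random edge gated by
# branch_probability. NULL when no edge can bind.
pick_repeat_edge <- function(edges_i, branch_probability) {
  free <- which(lengths(edges_i) == 0L)
  if (length(free) > 0L) {
    e <- if (length(free) == 1L) free else sample(free, 1L)
    return(list(edge = e, gate = 1))
  }
  if (branch_probability > 0) {
    e <- sample(length(edges_i), 1L)
    return(list(edge = e, gate = branch_probability))
  }
  NULL
}

#' Contact detection and stochastic bond formation
#'
#' Every pair of monomers on distinct clusters within `capture_radius`
#' (minimum-image distance) is an eligible contact. A contact forms a bond
#' with probability `1 - exp(-link_rate * dt)`, modulated by the connector
#' rule: under `"parallel_only"` (scaffold connectors) the two polarities
#' must agree within `angular_tolerance` and the bond joins the head edge of
#' one monomer to the tail edge of the other, one partner per edge; under
#' `"any"` (repeat connectors) any edge pair binds regardless of orientation,
#' and a fully occupied edge accepts an extra partner with
#' `branch_probability`. Bonded clusters merge and subsequently move
#' rigidly; bonds are permanent (assemblies survive connector washout, so no
#' off-rate is applied).
#'
#' @param state A `cluster_state`.
#' @param dt Time step in s over which the binding hazard is integrated.
#' @return The updated `cluster_state`.
#' @export
detect_and_bind <- function(state, dt) {
  cfg <- state$config
  if (cfg$link_rate <= 0) return(state)
  L <- cfg$domain_side
  w <- wrapped_positions(state)
  cand <- .close_pairs(w[, 1L], w[, 2L], L, cfg$capture_radius)
  if (nrow(cand) > 0L)
    cand <- cand[state$cluster_id[cand[, 1L]] !=
                   state$cluster_id[cand[, 2L]], , drop = FALSE]
  if (nrow(cand) == 0L) return(state)
  p_bind <- 1 - exp(-cfg$link_rate * dt)
  ord <- sample.int(nrow(cand))
  parallel_only <- cfg$orientation_rule == "parallel_only"
  for (k in ord) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    if (state$cluster_id[i] == state$cluster_id[j]) next  # merged this step
    if (parallel_only) {
      if (abs(angle_diff(state$polarity[i], state$polarity[j])) >
            cfg$angular_tolerance) next
      # head (edge 1) of one monomer binds tail (edge 2) of the other
      combos <- list(c(1L, 2L), c(2L, 1L))
      open <- vapply(combos, function(co) {
        length(state$edge_partners[[i]][[co[1L]]]) == 0L &&
          length(state$edge_partners[[j]][[co[2L]]]) == 0L
      }, logical(1L))
      if (!any(open)) next
      co <- combos[[if (all(open)) sample(2L, 1L) else which(open)]]
      ei <- co[1L]; ej <- co[2L]; gate <- 1
    } else {
      pi_edge <- pick_repeat_edge(state$edge_partners[[i]],
                                  cfg$branch_probability)
      pj_edge <- pick_repeat_edge(state$edge_partners[[j]],
                                  cfg$branch_probability)
      if (is.null(pi_edge) || is.null(pj_edge)) next
      ei <- pi_edge$edge; ej <- pj_edge$edge
      gate <- pi_edge$gate * pj_edge$gate
    }
    if (stats::runif(1L) >= p_bind * gate) next
    state$edge_partners[[i]][[ei]] <- c(state$edge_partners[[i]][[ei]], j)
    state$edge_partners[[j]][[ej]] <- c(state$edge_partners[[j]][[ej]], i)
    ci <- state$cluster_id[i]; cj <- state$cluster_id[j]
    state$cluster_id[state$cluster_id == cj] <- ci
  }
  state$cluster_id <- compact_clusters(state$cluster_id)
  state
}

#' Fraction of effectively immobilized monomers
#'
#' A monomer counts as immobile when the expected root-mean-square
#' displacement of its cluster over the horizon, `sqrt(4 * D_n * horizon)`,
#' falls below `displacement_threshold`. This mirrors the experimental
#' observation that large assemblies appear frozen within a 10 s
#' observation window.
#'
#' @param state A `cluster_state`.
#' @param displacement_threshold Threshold in um (a sensible default is one
#'   camera pixel, 0.13 um).
#' @param horizon Time horizon in s.
#' @return Fraction in [0, 1] of monomers belonging to immobile clusters.
#' @export
immobile_fraction <- function(state, displacement_threshold = 0.13,
                              horizon = 10) {
  if (displacement_threshold <= 0 || horizon <= 0)
    stop("threshold and horizon must be positive")
  cfg <- state$config
  sizes <- cluster_sizes(state)
  Dn <- effective_cluster_D(sizes, cfg)
  rms <- sqrt(4 * Dn * horizon)
  immob <- rms < displacement_threshold
  mean(immob[state$cluster_id])
}

#' Run an assembly simulation
#'
#' Integrates diffusion and binding from time 0 to `total_time`, recording
#' particle positions at every frame time of every observation window in the
#' schedule (the laser is shuttered between windows, so only scheduled
#' frames are ever rendered). Deterministic given `rng_seed`.
#'
#' @param config A [sim_config()].
#' @return An object of class `assembly_trajectory` with elements
#'   `config`, `windows` (per window: `start`, `frame_times`, `frames` — a
#'   list of wrapped N x 2 position matrices — and the `cluster_id` vector
#'   at window start), `summary` (per-window data frame: time, n_clusters,
#'   mean cluster size, max size, immobile fraction),
#'   `size_distributions` (per-window size tabulation) and `final_state`.
#' @export
run_assembly <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$rng_seed, {
    state <- init_cluster_state(config)
    sched <- config$observation_schedule
    frame_times <- list(); window_of <- integer(0)
    if (!is.null(sched) && nrow(sched) > 0L) {
      for (wi in seq_len(nrow(sched))) {
        ft <- sched$start[wi] +
          (seq_len(sched$n_frames[wi]) - 1L) / sched$frame_rate[wi]
        frame_times[[wi]] <- ft
        window_of <- c(window_of, rep(wi, length(ft)))
      }
    }
    all_ft <- unlist(frame_times)
    if (length(all_ft) > 0L && max(all_ft) > config$total_time)
      stop("observation schedule extends beyond total_time")
    sample_times <- if (length(all_ft)) all_ft else numeric(0)
    ord <- order(sample_times)
    sample_times <- sample_times[ord]; window_of <- window_of[ord]

    windows <- lapply(seq_along(frame_times), function(wi) {
      list(start = sched$start[wi], frame_rate = sched$frame_rate[wi],
           frame_times = frame_times[[wi]], frames = vector("list", 0L),
           cluster_id = NULL)
    })
    summary_rows <- list()

    step_to <- function(state, t_target) {
      while (state$time < t_target - 1e-12) {
        h <- min(config$dt, t_target - state$time)
        state <- advance(state, h)
        state <- detect_and_bind(state, h)
      }
      state
    }

    for (k in seq_along(sample_times)) {
      state <- step_to(state, sample_times[k])
      wi <- window_of[k]
      windows[[wi]]$frames[[length(windows[[wi]]$frames) + 1L]] <-
        wrapped_positions(state)
      if (is.null(windows[[wi]]$cluster_id)) {
        windows[[wi]]$cluster_id <- state$cluster_id
        sizes <- cluster_sizes(state)
        horizon <- sched$n_frames[wi] / sched$frame_rate[wi]
        summary_rows[[wi]] <- data.frame(
          time = sched$start[wi],
          n_clusters = length(sizes),
          mean_size = mean(sizes),
          max_size = max(sizes),
          immobile_fraction = immobile_fraction(state, horizon = horizon))
      }
    }
    state <- step_to(state, config$total_time)

    size_distributions <- lapply(windows, function(w) {
      if (is.null(w$cluster_id)) return(integer(0))
      tabulate(tabulate(w$cluster_id))
    })
    structure(
      list(config = config, windows = windows,
           summary = if (length(summary_rows))
             do.call(rbind, summary_rows) else NULL,
           size_distributions = size_distributions,
           final_state = state),
      class = "assembly_trajectory")
  })
}

#' @export
print.assembly_trajectory <- function(x, ...) {
  cat(sprintf("<assembly_trajectory> %d monomers, %.1f s, %d windows, %d final clusters\n",
              x$config$n_monomers, x$final_state$time, length(x$windows),
              length(unique(x$final_state$cluster_id))))
  invisible(x)
}
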
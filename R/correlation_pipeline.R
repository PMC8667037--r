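#' Per-pixel temporal detrending
#'
#' Removes each pixel's temporal mean (order 0) or best-fit line over time
#' (order 1) from an image stack, leaving the fluctuation signal. Order 1
#' guards against slow drifts and residual photobleaching.
#'
#' @param stack An `image_stack` or a (frame, row, column) array.
#' @param order 0 (mean removal) or 1 (linear detrend).
#' @return A (frame, row, column) array of fluctuations with per-pixel
#'   temporal mean 0.
#' @export
detrend_pixels <- function(stack, order = 0L) {
  data <- if (inherits(stack, "image_stack")) stack$data else stack
  stopifnot(length(dim(data)) == 3L)
  nt <- dim(data)[1L]
  if (nt < 10L) stop("need at least 10 frames to detrend")
  if (!order %in% c(0L, 1L)) stop("order must be 0 or 1")
  M <- matrix(data, nrow = nt)  # frames x pixels
  if (order == 0L) {
    resid <- sweep(M, 2L, colMeans(M))
  } else {
    tt <- seq_len(nt)
    X <- cbind(1, tt)
    beta <- solve(crossprod(X), crossprod(X, M))
    resid <- M - X %*% beta
  }
  array(resid, dim = dim(data))
}

#' Temporal image-correlation parameter
#'
#' The fluctuation-amplitude statistic used to follow oligomerization: the
#' lag-`lag` temporal autocovariance of per-pixel-detrended intensity,
#' averaged over all pixels and valid frame pairs, normalized by the squared
#' offset-corrected global mean intensity:
#' \deqn{C = \langle \delta F(x, t)\,\delta F(x, t+\mathrm{lag}) \rangle /
#'       \langle F - \mathrm{offset} \rangle^2.}
#' Fluctuations are larger when few bright particles diffuse through a pixel
#' than when many dim ones do, so C rises as monomers oligomerize at
#' constant total brightness; it falls to zero when assemblies immobilize
#' (constant signal) — and, because the lag is at least 1 frame, temporally
#' uncorrelated detector noise cancels in expectation instead of inflating C.
#'
#' @param stack An `image_stack` (camera offset is taken from its metadata)
#'   or a 3D array.
#' @param lag Frame lag >= 1; must be < half the frame count.
#' @param detrend_order Passed to [detrend_pixels()].
#' @param offset Camera count offset subtracted before normalization;
#'   defaults to the stack's camera metadata (0 for bare arrays).
#' @param window_time Incubation time stamp carried into the result.
#' @return An object of class `correlation_result` with fields `value`,
#'   `lag`, `n_pixels`, `window_time`, `detrend_order`.
#' @export
correlation_parameter <- function(stack, lag = 1L, detrend_order = 0L,
                                  offset = NULL, window_time = NULL) {
  data <- if (inherits(stack, "image_stack")) stack$data else stack
  stopifnot(length(dim(data)) == 3L)
  nt <- dim(data)[1L]
  lag <- as.integer(lag)
  if (lag < 1L || lag >= nt / 2) stop("lag must satisfy 1 <= lag < n_frames/2")
  if (is.null(offset))
    offset <- if (inherits(stack, "image_stack") && !is.null(stack$camera))
      stack$camera$offset else 0
  if (is.null(window_time) && inherits(stack, "image_stack"))
    window_time <- stack$window_time
  mean_excess <- mean(data) - offset
  if (mean_excess <= 0)
    stop("undefined statistic: mean intensity does not exceed the offset")
  dF <- detrend_pixels(data, detrend_order)
  M <- matrix(dF, nrow = nt)
  value <- mean(M[seq_len(nt - lag), , drop = FALSE] *
                  M[(1L + lag):nt, , drop = FALSE]) / mean_excess^2
  structure(
    list(value = value, lag = lag, n_pixels = prod(dim(data)[2:3]),
         window_time = if (is.null(window_time)) NA_real_ else window_time,
         detrend_order = detrend_order),
    class = "correlation_result")
}

#' Correlation time course across observation windows
#'
#' Computes one correlation parameter per observation window and orders the
#' results by incubation time. Windows are analyzed independently (the laser
#' is shuttered between windows, so no cross-window detrending is
#' meaningful).
#'
#' @param stacks List of `image_stack`s.
#' @param window_times Optional numeric vector of incubation times (s); by
#'   default each stack's own `window_time` metadata is used.
#' @param condition Condition label attached to the time course.
#' @param ... Passed to [correlation_parameter()].
#' @return An object of class `correlation_timecourse`: a data frame with
#'   columns `time` (s) and `value`, sorted by time, with the condition
#'   label as an attribute.
#' @export
correlation_timecourse <- function(stacks, window_times = NULL,
                                   condition = "condition", ...) {
  if (length(stacks) < 2L) stop("need at least 2 observation windows")
  if (is.null(window_times))
    window_times <- vapply(stacks, function(s)
      if (is.null(s$window_time)) NA_real_ else s$window_time, numeric(1L))
  if (anyNA(window_times)) stop("missing window times")
  if (anyDuplicated(window_times)) stop("duplicate window times")
  values <- vapply(seq_along(stacks), function(i) {
    correlation_parameter(stacks[[i]], window_time = window_times[i],
                          ...)$value
  }, numeric(1L))
  ord <- order(window_times)
  tc <- data.frame(time = window_times[ord], value = values[ord])
  structure(tc, class = c("correlation_timecourse", "data.frame"),
            condition = condition)
}

#' Build a time course from bare (time, value) pairs
#'
#' Convenience constructor used when correlation values come from files or
#' external computation rather than in-memory stacks.
#'
#' @param time Incubation times in s (must be unique).
#' @param value Correlation-parameter values.
#' @param condition Condition label.
#' @return A `correlation_timecourse`.
#' @export
as_correlation_timecourse <- function(time, value, condition = "condition") {
  stopifnot(length(time) == length(value))
  if (anyDuplicated(time)) stop("duplicate window times")
  ord <- order(time)
  structure(data.frame(time = time[ord], value = value[ord]),
            class = c("correlation_timecourse", "data.frame"),
            condition = condition)
}

#' Characteristic assembly-timescale fit
#'
#' Fits the decaying phase of a correlation time course with a logistic
#' decay
#' \deqn{C(t) = C_{base} + (C_{peak} - C_{base}) / (1 + e^{(t - t_{1/2})/w})}
#' and reports the half-decay time `t_half` as the characteristic
#' immobilization timescale, a surrogate for superstructure assembly. A fit
#' is only attempted when the trace actually decays: the relative drop from
#' the peak to the post-peak minimum must reach `drop_fraction` (default
#' 50%); otherwise `fitted = FALSE` — the bookkeeping used to count data
#' sets "for which an assembly time scale could be fitted". Fitting is by
#' bounded Levenberg-Marquardt least squares, initialized at the observed
#' peak and the time of half-drop, with `t_half` constrained to the observed
#' time range. Fit failures are reported through `fitted = FALSE`, never as
#' exceptions.
#'
#' @param tc A `correlation_timecourse` (>= 6 time points).
#' @param drop_fraction Minimum relative drop from the peak for a decay to
#'   be declared.
#' @return An object of class `kinetics_fit`: `C_peak`, `C_base`, `t_half`
#'   (s), `width` (s), `fitted`, `residual_norm`, `diagnostic`.
#' @export
fit_assembly_timescale <- function(tc, drop_fraction = 0.5) {
  stopifnot(inherits(tc, "correlation_timecourse") || is.data.frame(tc))
  t <- tc$time; v <- tc$value
  if (length(t) < 6L) stop("need at least 6 time points")
  no_fit <- function(msg) {
    structure(list(C_peak = NA_real_, C_base = NA_real_, t_half = NA_real_,
                   width = NA_real_, fitted = FALSE,
                   residual_norm = NA_real_, diagnostic = msg),
              class = "kinetics_fit")
  }
  # peak detection on a light 3-point running mean so that a single noisy
  # window cannot anchor the decay segment; the fit itself uses raw values
  v_smooth <- if (length(v) >= 3L)
    stats::filter(v, rep(1 / 3, 3L), sides = 2L) else v
  v_smooth[is.na(v_smooth)] <- v[is.na(v_smooth)]
  ip <- which.max(v_smooth)
  v_peak <- max(v[ip], v_smooth[ip])
  post <- ip:length(v)
  if (length(post) < 4L) return(no_fit("too few post-peak points"))
  tail_min <- min(v[post])
  if (v_peak <= 0 || (v_peak - tail_min) / v_peak < drop_fraction)
    return(no_fit("no decay detected"))
  td <- t[post]; vd <- v[post]
  span <- max(td) - min(td)
  amp <- v_peak - tail_min
  mid <- (v_peak + tail_min) / 2
  below <- which(vd <= mid)
  t_half0 <- if (length(below)) td[below[1L]] else mean(range(td))
  lower <- c(C_peak = tail_min, C_base = tail_min - 0.5 * amp,
             t_half = min(td), width = span * 1e-6)
  upper <- c(C_peak = v_peak + 0.05 * amp, C_base = tail_min + 0.3 * amp,
             t_half = max(td), width = span)
  fit <- NULL; last_err <- "no attempt"
  for (th0 in unique(c(t_half0, stats::median(td)))) {
    for (w0 in c(span / 10, span / 4, span / 30)) {
      cand <- tryCatch(
        minpack.lm::nlsLM(
          vd ~ C_base + (C_peak - C_base) / (1 + exp((td - t_half) / width)),
          start = list(C_peak = v_peak, C_base = tail_min,
                       t_half = th0, width = max(w0, 1e-6)),
          lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-13,
                                               ptol = 1e-13)),
        error = function(e) e)
      if (inherits(cand, "error")) { last_err <- conditionMessage(cand); next }
      if (is.null(fit) ||
          sum(stats::resid(cand)^2) < sum(stats::resid(fit)^2)) fit <- cand
    }
  }
  if (is.null(fit))
    return(no_fit(paste("fit failed:", last_err)))
  cf <- stats::coef(fit)
  if (cf[["C_peak"]] <= cf[["C_base"]])
    return(no_fit("degenerate fit: no amplitude"))
  structure(
    list(C_peak = unname(cf[["C_peak"]]), C_base = unname(cf[["C_base"]]),
         t_half = unname(cf[["t_half"]]), width = unname(cf[["width"]]),
         fitted = TRUE,
         residual_norm = sqrt(sum(stats::resid(fit)^2)),
         diagnostic = "ok"),
    class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  if (x$fitted)
    cat(sprintf("<kinetics_fit> t_half = %.3g s (width %.3g s), C %.3g -> %.3g\n",
                x$t_half, x$width, x$C_peak, x$C_base))
  else cat(sprintf("<kinetics_fit> not fitted (%s)\n", x$diagnostic))
  invisible(x)
}

#' Simulate one observation window of a monomer/oligomer mixture
#'
#' Free-diffusion scene generator used for sensitivity validation: a fixed
#' total fluorophore budget is split between monomers and q-mers (a q-mer is
#' a point particle carrying q monomers' labels), all diffusing with
#' coefficient `D` (or frozen when `mobile = FALSE`) on a periodic domain
#' matched to the camera field. Monomer positions are drawn before oligomer
#' positions, so the `phi = 0` cell reproduces the pure-monomer scene
#' exactly under the same seed.
#'
#' @param n_fluorophores Total fluorophore budget (label units; one monomer
#'   carries one unit here).
#' @param q Oligomer size.
#' @param phi Fraction of the fluorophore budget packaged into q-mers.
#' @param D Diffusion coefficient, um^2/s.
#' @param mobile If `FALSE`, particles are frozen in place.
#' @param optics An [optics_config()] (defines field and frame times).
#' @param n_frames Number of frames to simulate.
#' @param seed Optional seed.
#' @return A window list (`start`, `frame_times`, `frames`, `brightness`)
#'   renderable by [render_stack()].
#' @export
simulate_mixture_window <- function(n_fluorophores, q = 1L, phi = 0,
                                    D = 0.2, mobile = TRUE,
                                    optics = optics_config(),
                                    n_frames = optics$frames_per_window,
                                    seed = NULL) {
  stopifnot(q >= 1L, phi >= 0, phi <= 1)
  n_oligo <- floor(phi * n_fluorophores / q)
  n_mono <- n_fluorophores - n_oligo * q
  L <- optics$field_size * optics$pixel_size_nm / 1000
  dt <- 1 / optics$frame_rate
  with_seed(seed, {
    pos_mono <- matrix(stats::runif(2L * n_mono, 0, L), ncol = 2L)
    pos_oligo <- matrix(stats::runif(2L * n_oligo, 0, L), ncol = 2L)
    pos <- rbind(pos_mono, pos_oligo)
    brightness <- c(rep(1, n_mono), rep(q, n_oligo))
    n <- nrow(pos)
    frames <- vector("list", n_frames)
    frames[[1L]] <- pos %% L
    sd_step <- if (mobile) sqrt(2 * D * dt) else 0
    for (f in seq_len(n_frames - 1L)) {
      if (sd_step > 0)
        pos <- pos + matrix(stats::rnorm(2L * n, 0, sd_step), ncol = 2L)
      frames[[f + 1L]] <- pos %% L
    }
    list(start = 0, frame_times = (seq_len(n_frames) - 1L) * dt,
         frames = frames, brightness = brightness)
  })
}

#' Sensitivity of the correlation parameter to oligomerization
#'
#' Renders synthetic mixtures over a grid of oligomer size, oligomer
#' fraction and mobility at a fixed total fluorophore count, and computes
#' the correlation parameter for each cell — the in-silico accuracy check
#' of the statistic: C must increase with oligomer size for mobile scenes
#' and collapse toward the noise baseline for immobile ones.
#'
#' @param q_values Oligomer sizes to test.
#' @param phi_values Oligomer fluorophore fractions.
#' @param mobile_values Logical vector of mobility settings.
#' @param n_fluorophores Total fluorophore budget per cell.
#' @param D Diffusion coefficient for mobile cells, um^2/s.
#' @param optics,camera Imaging configuration.
#' @param n_frames Frames per rendered window.
#' @param seed Seed applied identically to every cell, so that cells
#'   differing only in unused draws are exactly comparable.
#' @param check If `TRUE`, error unless C is strictly increasing in q at
#'   phi = 1 (mobile) and immobile C falls below `immobile_ceiling` times
#'   the matched mobile C.
#' @param immobile_ceiling Fraction of the mobile value that immobile cells
#'   must stay below when `check = TRUE`.
#' @return Data frame with columns `q`, `phi`, `mobile`, `C`.
#' @export
validate_sensitivity <- function(q_values = c(1L, 2L, 5L, 10L),
                                 phi_values = 1,
                                 mobile_values = c(TRUE, FALSE),
                                 n_fluorophores = 2000L,
                                 D = 0.2,
                                 optics = optics_config(),
                                 camera = camera_config(),
                                 n_frames = 100L,
                                 seed = 1L,
                                 check = FALSE,
                                 immobile_ceiling = 0.1) {
  grid <- expand.grid(q = q_values, phi = phi_values, mobile = mobile_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$C <- vapply(seq_len(nrow(grid)), function(i) {
    win <- simulate_mixture_window(
      n_fluorophores, q = grid$q[i], phi = grid$phi[i], D = D,
      mobile = grid$mobile[i], optics = optics, n_frames = n_frames,
      seed = seed)
    stk <- render_stack(win, optics, camera, brightness = win$brightness,
                        seed = derive_seed(seed, i), window_time = 0)
    correlation_parameter(stk)$value
  }, numeric(1L))
  if (check) {
    if (any(phi_values == 1) && any(mobile_values)) {
      sub <- grid[grid$phi == 1 & grid$mobile, ]
      sub <- sub[order(sub$q), ]
      if (nrow(sub) > 1L && any(diff(sub$C) <= 0))
        stop("C is not strictly increasing in oligomer size")
    }
    if (any(mobile_values) && any(!mobile_values)) {
      for (qv in q_values) for (pv in phi_values) {
        cm <- grid$C[grid$q == qv & grid$phi == pv & grid$mobile]
        ci <- grid$C[grid$q == qv & grid$phi == pv & !grid$mobile]
        if (length(cm) && length(ci) && any(ci > immobile_ceiling * cm))
          stop("immobile C not below the configured baseline fraction")
      }
    }
  }
  grid
}
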
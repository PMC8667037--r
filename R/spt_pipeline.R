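#' Simulate 2D Brownian single-particle tracks
#'
#' Ground-truth track generator for validating the SPT stage: independent
#' 2D Brownian walks sampled at `1/dt` Hz with optional Gaussian
#' localization noise added per coordinate. Tracks are continuously visible
#' (the imager-exchange labeling used experimentally defeats bleaching).
#'
#' @param n_tracks Number of tracks.
#' @param n_steps Steps per track (track length is `n_steps + 1` points).
#' @param D Diffusion coefficient, um^2/s.
#' @param dt Frame interval, s.
#' @param loc_noise_sd Localization error standard deviation per coordinate,
#'   um.
#' @param domain_side Optional periodic domain; `Inf` (default) gives free
#'   diffusion in the plane.
#' @param seed Optional seed.
#' @return A list of data frames with columns `frame`, `x`, `y` (um).
#' @export
simulate_tracks <- function(n_tracks, n_steps, D, dt = 0.05,
                            loc_noise_sd = 0, domain_side = Inf,
                            seed = NULL) {
  stopifnot(n_tracks >= 1, n_steps >= 1, D >= 0, dt > 0, loc_noise_sd >= 0)
  with_seed(seed, {
    sd_step <- sqrt(2 * D * dt)
    lapply(seq_len(n_tracks), function(i) {
      x0 <- if (is.finite(domain_side))
        stats::runif(2L, 0, domain_side) else c(0, 0)
      steps <- matrix(stats::rnorm(2L * n_steps, 0, sd_step), ncol = 2L)
      cs <- apply(steps, 2L, cumsum)
      if (is.null(dim(cs))) cs <- matrix(cs, ncol = 2L)
      path <- rbind(x0, sweep(cs, 2L, -x0))
      if (loc_noise_sd > 0)
        path <- path + matrix(stats::rnorm(2L * (n_steps + 1L), 0,
                                           loc_noise_sd), ncol = 2L)
      data.frame(frame = seq_len(n_steps + 1L),
                 x = path[, 1L], y = path[, 2L])
    })
  })
}

#' Detect sparse emitters in a single frame
#'
#' Local-maximum spot detection with intensity-weighted sub-pixel centroids.
#' The background level and noise scale are estimated robustly (median and
#' MAD of the frame); pixels above `background + threshold_sd * sd` that are
#' local maxima within the centroid window are accepted, with a minimum
#' separation of one window between detections (brightest kept).
#'
#' @param frame_img 2D matrix of camera counts (rows y, columns x).
#' @param threshold_sd Detection threshold in multiples of the background
#'   standard deviation.
#' @param window Odd window size in pixels for both non-maximum suppression
#'   and centroiding.
#' @param pixel_size_um Pixel width, um.
#' @return Data frame with columns `x`, `y` (um, in field coordinates),
#'   `intensity` (background-subtracted counts in the window). Possibly
#'   empty.
#' @export
localize <- function(frame_img, threshold_sd = 5, window = 5L,
                     pixel_size_um = 0.13) {
  stopifnot(is.matrix(frame_img), window %% 2L == 1L)
  bg <- stats::median(frame_img)
  noise <- stats::mad(frame_img)
  if (noise == 0) noise <- stats::sd(frame_img)
  thr <- bg + threshold_sd * noise
  cand <- which(frame_img > thr, arr.ind = TRUE)
  empty <- data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0))
  if (nrow(cand) == 0L) return(empty)
  nr <- nrow(frame_img); nc <- ncol(frame_img)
  w <- (window - 1L) %/% 2L
  # local-maximum test within the window
  is_max <- vapply(seq_len(nrow(cand)), function(k) {
    r <- cand[k, 1L]; c <- cand[k, 2L]
    rr <- max(1L, r - w):min(nr, r + w)
    cc <- max(1L, c - w):min(nc, c + w)
    frame_img[r, c] >= max(frame_img[rr, cc])
  }, logical(1L))
  cand <- cand[is_max, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  # enforce minimum separation: keep brightest first
  vals <- frame_img[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!keep[k]) next
    if (k < nrow(cand)) {
      later <- (k + 1L):nrow(cand)
      clash <- abs(cand[later, 1L] - cand[k, 1L]) < window &
               abs(cand[later, 2L] - cand[k, 2L]) < window
      keep[later][clash] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- lapply(seq_len(nrow(cand)), function(k) {
    r <- cand[k, 1L]; c <- cand[k, 2L]
    rr <- max(1L, r - w):min(nr, r + w)
    cc <- max(1L, c - w):min(nc, c + w)
    patch <- pmax(frame_img[rr, cc, drop = FALSE] - bg, 0)
    tot <- sum(patch)
    cy <- sum(rowSums(patch) * rr) / tot
    cx <- sum(colSums(patch) * cc) / tot
    # pixel centers sit at (index - 0.5) * pixel_size
    data.frame(x = (cx - 0.5) * pixel_size_um,
               y = (cy - 0.5) * pixel_size_um, intensity = tot)
  })
  do.call(rbind, out)
}

#' Localize every frame of a stack
#'
#' @param stack An `image_stack`.
#' @param ... Passed to [localize()] (the pixel size defaults to the stack's
#'   optics metadata).
#' @return Data frame with columns `frame`, `x`, `y`, `intensity`.
#' @export
localize_stack <- function(stack, ...) {
  stopifnot(inherits(stack, "image_stack"))
  args <- list(...)
  if (is.null(args$pixel_size_um) && !is.null(stack$optics))
    args$pixel_size_um <- stack$optics$pixel_size_nm / 1000
  nf <- dim(stack$data)[1L]
  res <- lapply(seq_len(nf), function(f) {
    locs <- do.call(localize, c(list(frame_img = stack$data[f, , ]), args))
    if (nrow(locs)) cbind(frame = f, locs) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      intensity = numeric(0))
  out
}

#' Link localizations into tracks
#'
#' Greedy mutual-nearest-neighbor linking between consecutive frames: a pair
#' is linked only if each localization is the other's nearest neighbor in
#' the adjacent frame and their distance is below `max_displacement`.
#' Ambiguous (non-mutual) pairs stay unlinked, there is no gap closing, and
#' a track ends at its last detection — appropriate for the sparse labeling
#' regime (roughly 1 labeled particle in 20).
#'
#' @param locs Data frame with columns `frame`, `x`, `y` (as from
#'   [localize_stack()]).
#' @param max_displacement Maximum frame-to-frame displacement, um.
#' @param min_length Minimum number of points for a track to be returned.
#' @return List of data frames (`frame`, `x`, `y`), each a track.
#' @export
link_tracks <- function(locs, max_displacement, min_length = 2L) {
  if (nrow(locs) == 0L) return(list())
  frames <- sort(unique(locs$frame))
  by_frame <- split(locs, locs$frame)
  # active tracks: list of data frames; `open` maps row in current frame ->
  # track index
  tracks <- list()
  prev <- by_frame[[as.character(frames[1L])]]
  prev_track <- integer(nrow(prev))
  for (r in seq_len(nrow(prev))) {
    tracks[[length(tracks) + 1L]] <- prev[r, c("frame", "x", "y")]
    prev_track[r] <- length(tracks)
  }
  if (length(frames) > 1L) {
    for (fi in 2L:length(frames)) {
      cur <- by_frame[[as.character(frames[fi])]]
      cur_track <- integer(nrow(cur))
      contiguous <- frames[fi] == frames[fi - 1L] + 1L
      if (contiguous && nrow(prev) > 0L && nrow(cur) > 0L) {
        d <- sqrt(outer(prev$x, cur$x, "-")^2 + outer(prev$y, cur$y, "-")^2)
        nn_fwd <- apply(d, 1L, which.min)   # for each prev, nearest cur
        nn_bwd <- apply(d, 2L, which.min)   # for each cur, nearest prev
        for (p in seq_len(nrow(prev))) {
          cidx <- nn_fwd[p]
          if (nn_bwd[cidx] == p && d[p, cidx] <= max_displacement) {
            ti <- prev_track[p]
            tracks[[ti]] <- rbind(tracks[[ti]], cur[cidx, c("frame", "x", "y")])
            cur_track[cidx] <- ti
          }
        }
      }
      for (r in which(cur_track == 0L)) {
        tracks[[length(tracks) + 1L]] <- cur[r, c("frame", "x", "y")]
        cur_track[r] <- length(tracks)
      }
      prev <- cur; prev_track <- cur_track
    }
  }
  tracks <- lapply(tracks, function(tr) { rownames(tr) <- NULL; tr })
  tracks[vapply(tracks, nrow, integer(1L)) >= min_length]
}

#' Mean-squared displacement of a track ensemble
#'
#' Time-averaged MSD per track (all point pairs at each lag), then
#' ensemble-averaged across tracks, for lags 1..`max_lag`.
#'
#' @param tracks List of track data frames (`frame`, `x`, `y`).
#' @param max_lag Largest lag, in frames.
#' @param dt Frame interval, s.
#' @return An object of class `msd_result`: data frame columns `lag`, `tau`
#'   (s), `msd` (um^2), `n_tracks` attribute.
#' @export
msd_tracks <- function(tracks, max_lag = 10L, dt = 0.05) {
  eligible <- tracks[vapply(tracks, nrow, integer(1L)) > max_lag]
  if (length(eligible) == 0L)
    stop("no track longer than max_lag frames")
  per_lag <- matrix(NA_real_, nrow = length(eligible), ncol = max_lag)
  for (i in seq_along(eligible)) {
    tr <- eligible[[i]]
    n <- nrow(tr)
    for (lag in seq_len(max_lag)) {
      dxy <- (tr$x[(1L + lag):n] - tr$x[seq_len(n - lag)])^2 +
             (tr$y[(1L + lag):n] - tr$y[seq_len(n - lag)])^2
      per_lag[i, lag] <- mean(dxy)
    }
  }
  res <- data.frame(lag = seq_len(max_lag),
                    tau = seq_len(max_lag) * dt,
                    msd = colMeans(per_lag))
  structure(res, class = c("msd_result", "data.frame"),
            n_tracks = length(eligible))
}

#' Diffusion coefficient from an MSD curve
#'
#' Ordinary least-squares line through the first `n_fit_lags` points of
#' MSD versus lag time; in 2D, `D = slope / 4`. The intercept is left free
#' and reported (it absorbs the static localization-error term
#' `4 * sigma_loc^2`) rather than constrained through the origin. A
#' negative fitted slope is reported as `D = 0` with `immobile = TRUE`.
#'
#' @param msd_result An `msd_result`.
#' @param n_fit_lags Number of initial lags to fit.
#' @return List of class `diffusion_fit`: `D` (um^2/s), `intercept` (um^2),
#'   `immobile`, `n_fit_lags`, `n_tracks`.
#' @export
estimate_D <- function(msd_result, n_fit_lags = 4L) {
  stopifnot(inherits(msd_result, "msd_result"))
  if (nrow(msd_result) < n_fit_lags)
    stop("fewer lags available than n_fit_lags")
  sub <- msd_result[seq_len(n_fit_lags), ]
  fit <- stats::lm(msd ~ tau, data = sub)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  immobile <- slope <= 0
  structure(
    list(D = if (immobile) 0 else slope / 4, intercept = intercept,
         immobile = immobile, n_fit_lags = n_fit_lags,
         n_tracks = attr(msd_result, "n_tracks")),
    class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.4g um^2/s (intercept %.3g um^2, %d tracks%s)\n",
              x$D, x$intercept, x$n_tracks,
              if (x$immobile) ", immobile" else ""))
  invisible(x)
}
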
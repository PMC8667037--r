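#' Optical configuration of the synthetic TIRF microscope
#'
#' Defaults reproduce the acquisition geometry used for correlation imaging:
#' 130 nm effective pixels and 300-frame windows at 30 Hz. The point-spread
#' function is an isotropic 2D Gaussian; its width is a generic high-NA
#' visible-light value since it only needs to be realistic, not
#' instrument-matched.
#'
#' @param pixel_size_nm Effective camera pixel width in nm.
#' @param psf_sigma_nm Gaussian PSF standard deviation in nm; must be at
#'   least `pixel_size_nm / 3` for adequate sampling.
#' @param frame_rate Acquisition rate in Hz.
#' @param frames_per_window Frames per observation window.
#' @param field_size Field of view in pixels (square).
#' @return An object of class `optics_config`.
#' @export
optics_config <- function(pixel_size_nm = 130, psf_sigma_nm = 150,
                          frame_rate = 30, frames_per_window = 300L,
                          field_size = 64L) {
  if (pixel_size_nm <= 0 || psf_sigma_nm <= 0 || frame_rate <= 0 ||
      frames_per_window < 1 || field_size < 1)
    stop("optics parameters must be positive")
  if (psf_sigma_nm < pixel_size_nm / 3)
    stop("psf_sigma_nm must be >= pixel_size_nm / 3 (undersampled PSF)")
  structure(
    list(pixel_size_nm = pixel_size_nm, psf_sigma_nm = psf_sigma_nm,
         frame_rate = frame_rate,
         frames_per_window = as.integer(frames_per_window),
         field_size = as.integer(field_size)),
    class = "optics_config")
}

#' Camera model
#'
#' Simple photon-counting camera: expected pixel signal is
#' `offset + gain * photons`; realized counts are
#' `offset + gain * Poisson(photons) + N(0, read_noise_sd)`, clipped at 0.
#' Shot noise can be disabled for noise-free reference images. The real
#' instrument's gain, offset and noise are not published, so these defaults
#' are generic and are recorded in every stack's metadata.
#'
#' @param photons_per_fluorophore_per_frame Expected photon yield of one
#'   fluorophore in one frame.
#' @param gain Camera counts per photon.
#' @param offset Constant count offset.
#' @param read_noise_sd Gaussian read-noise standard deviation, in counts.
#' @param bleach_rate Photobleaching rate per second of illuminated time
#'   (0 disables bleaching; imager-exchange labeling largely defeats it).
#' @param shot_noise Apply Poisson shot noise (`FALSE` gives the expected
#'   image plus read noise only).
#' @return An object of class `camera_config`.
#' @export
camera_config <- function(photons_per_fluorophore_per_frame = 100,
                          gain = 2, offset = 100, read_noise_sd = 2,
                          bleach_rate = 0, shot_noise = TRUE) {
  if (photons_per_fluorophore_per_frame < 0 || gain <= 0 || offset < 0 ||
      read_noise_sd < 0 || bleach_rate < 0)
    stop("camera parameters must be non-negative (gain > 0)")
  structure(
    list(photons_per_fluorophore_per_frame = photons_per_fluorophore_per_frame,
         gain = gain, offset = offset, read_noise_sd = read_noise_sd,
         bleach_rate = bleach_rate, shot_noise = isTRUE(shot_noise)),
    class = "camera_config")
}

# Expected photon image (field x field) for point emitters at `positions`
# (um, in field coordinates) with per-emitter expected photon counts
# `photons`. PSF mass is integrated exactly per pixel via Gaussian CDFs over
# a +-4 sigma patch; contributions are accumulated with rowsum so that
# thousands of emitters stay vectorized.
expected_photon_image <- function(positions, photons, optics) {
  fs <- optics$field_size
  px <- optics$pixel_size_nm / 1000
  sigma <- optics$psf_sigma_nm / 1000
  img <- matrix(0, fs, fs)
  if (length(photons) == 0L || nrow(positions) == 0L) return(img)
  margin <- 4 * sigma
  keep <- positions[, 1L] > -margin & positions[, 1L] < fs * px + margin &
          positions[, 2L] > -margin & positions[, 2L] < fs * px + margin
  if (!any(keep)) return(img)
  xs <- positions[keep, 1L]; ys <- positions[keep, 2L]
  b <- photons[keep]
  w <- ceiling(4 * sigma / px)
  offs <- (-w):w
  K <- length(offs)
  cx <- floor(xs / px)  # 0-based pixel column of the emitter
  cy <- floor(ys / px)
  # Gaussian mass per pixel column/row: P x K matrices
  gx <- vapply(offs, function(o) {
    lo <- (cx + o) * px; hi <- lo + px
    stats::pnorm(hi, xs, sigma) - stats::pnorm(lo, xs, sigma)
  }, numeric(length(xs)))
  gy <- vapply(offs, function(o) {
    lo <- (cy + o) * px; hi <- lo + px
    stats::pnorm(hi, ys, sigma) - stats::pnorm(lo, ys, sigma)
  }, numeric(length(ys)))
  if (is.null(dim(gx))) { gx <- matrix(gx, nrow = 1L); gy <- matrix(gy, nrow = 1L) }
  idx_all <- vector("list", K * K)
  val_all <- vector("list", K * K)
  m <- 1L
  for (i in seq_len(K)) {
    col0 <- cx + offs[i]          # 0-based column index
    okc <- col0 >= 0L & col0 < fs
    for (j in seq_len(K)) {
      row0 <- cy + offs[j]
      ok <- okc & row0 >= 0L & row0 < fs
      if (!any(ok)) next
      idx_all[[m]] <- row0[ok] + 1L + col0[ok] * fs  # column-major linear index
      val_all[[m]] <- b[ok] * gx[ok, i] * gy[ok, j]
      m <- m + 1L
    }
  }
  idx <- unlist(idx_all); val <- unlist(val_all)
  if (length(idx)) {
    sums <- rowsum(val, idx)
    img[as.integer(rownames(sums))] <- sums[, 1L]
  }
  img
}

#' Render one camera frame
#'
#' @param positions N x 2 matrix of emitter positions in um, in field
#'   coordinates (the field spans `field_size * pixel_size` um on each side;
#'   emitters outside the field contribute nothing).
#' @param brightness Per-emitter fluorophore count (may be fractional for
#'   partial label occupancy).
#' @param optics An [optics_config()].
#' @param camera A [camera_config()].
#' @return A `field_size` x `field_size` matrix of camera counts (rows are
#'   y, columns are x), clipped at 0.
#' @export
render_frame <- function(positions, brightness, optics, camera) {
  stopifnot(inherits(optics, "optics_config"),
            inherits(camera, "camera_config"))
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2L)
  if (nrow(positions) != length(brightness))
    stop("positions and brightness lengths differ")
  photons <- brightness * camera$photons_per_fluorophore_per_frame
  lam <- expected_photon_image(positions, photons, optics)
  fs <- optics$field_size
  sig <- if (camera$shot_noise) {
    matrix(stats::rpois(fs * fs, lam), fs, fs)
  } else lam
  counts <- camera$offset + camera$gain * sig
  if (camera$read_noise_sd > 0)
    counts <- counts + stats::rnorm(fs * fs, 0, camera$read_noise_sd)
  pmax(counts, 0)
}

#' Render an observation window into an image stack
#'
#' Renders every frame of one simulator observation window (or any object
#' with `frame_times` and a `frames` list of position matrices). Per-monomer
#' brightness defaults to 5 fluorophores (a 5x docking site quasi-
#' irreversibly labeled); cluster brightness is additive over members since
#' each monomer keeps its own labels. One mid-frame position is used per
#' frame — at 0.2 um^2/s and 33 ms exposures, motion blur is sub-pixel.
#'
#' @param window A window element of an `assembly_trajectory` (or a list
#'   with `frame_times` and `frames`).
#' @param optics An [optics_config()] (its `frames_per_window` is not
#'   enforced here; the window defines the frame count).
#' @param camera A [camera_config()].
#' @param brightness Scalar or per-monomer fluorophore count.
#' @param field_origin Length-2 offset (um) of the camera field within the
#'   simulation domain.
#' @param seed Optional integer seed; the stack is deterministic given it.
#' @param window_time Incubation time stamp (s) attached to the stack;
#'   defaults to the window start.
#' @return An object of class `image_stack`: `data` is a (frame, row,
#'   column) array of counts, plus acquisition metadata.
#' @export
render_stack <- function(window, optics, camera, brightness = 5,
                         field_origin = c(0, 0), seed = NULL,
                         window_time = NULL) {
  nf <- length(window$frames)
  if (nf == 0L) stop("window contains no frames")
  n_mono <- nrow(window$frames[[1L]])
  if (length(brightness) == 1L) brightness <- rep(brightness, n_mono)
  fs <- optics$field_size
  t0 <- window$frame_times[1L]
  with_seed(seed, {
    data <- array(0, dim = c(nf, fs, fs))
    for (f in seq_len(nf)) {
      pos <- sweep(window$frames[[f]], 2L, field_origin)
      b <- brightness
      if (camera$bleach_rate > 0)
        b <- b * exp(-camera$bleach_rate * (window$frame_times[f] - t0))
      data[f, , ] <- render_frame(pos, b, optics, camera)
    }
    structure(
      list(data = data, optics = optics, camera = camera,
           frame_times = window$frame_times,
           window_time = if (is.null(window_time)) window$start else window_time,
           seed = seed),
      class = "image_stack")
  })
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d frames of %d x %d px, t = %.1f s, mean %.1f counts\n",
              d[1L], d[2L], d[3L],
              if (is.null(x$window_time)) NA_real_ else x$window_time,
              mean(x$data)))
  invisible(x)
}

#' Write / read an image stack as multi-page TIFF
#'
#' Stacks are written as 16-bit unsigned grayscale multi-page TIFF; counts
#' are rounded to integers and values above 65535 saturate (clip). Metadata
#' (optics, camera, frame times, seed) is stored in a JSON sidecar at
#' `<path>.json` and restored by [read_stack()], so a write/read cycle
#' round-trips both pixel data (for in-range integer counts) and metadata.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns the
#'   `image_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- dim(stack$data)[1L]
  pages <- lapply(seq_len(nf), function(f) {
    pmin(pmax(round(stack$data[f, , ]), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(
    optics = unclass(stack$optics), camera = unclass(stack$camera),
    frame_times = stack$frame_times, window_time = stack$window_time,
    seed = stack$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("cannot read TIFF '", path,
                                             "': ", conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  nf <- length(pages)
  fs1 <- nrow(pages[[1L]]); fs2 <- ncol(pages[[1L]])
  data <- array(0, dim = c(nf, fs1, fs2))
  for (f in seq_len(nf)) data[f, , ] <- round(pages[[f]] * 65535)
  meta_path <- paste0(path, ".json")
  optics <- NULL; camera <- NULL; frame_times <- NULL
  window_time <- NULL; seed <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    optics <- structure(meta$optics, class = "optics_config")
    camera <- structure(meta$camera, class = "camera_config")
    frame_times <- meta$frame_times
    window_time <- meta$window_time
    seed <- meta$seed
  }
  structure(
    list(data = data, optics = optics, camera = camera,
         frame_times = frame_times, window_time = window_time, seed = seed),
    class = "image_stack")
}
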
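## Synthetic diffraction-limited spot movies with exact ground truth.
##
## Pixel convention: 0-based coordinates with pixel centers at integer
## positions, so a spot at (20.3, 41.7) px sits 0.3 px right of the center of
## column 21 (1-based). Positions live in um everywhere else; conversion to
## px happens only here, via the trackset's pixel_size.

#' Render a trackset into a synthetic fluorescence image stack
#'
#' Each particle is drawn as an isotropic 2D Gaussian of width `psf_sigma`
#' (px) and peak `amplitude` (counts) on a constant `background`, one frame
#' per time point. The noiseless integrated spot intensity above background
#' is `amplitude * 2 * pi * psf_sigma^2`. Spots whose centers fall outside
#' the frame are omitted from the render and flagged in the ground truth.
#'
#' @param tracks A [trackset()]; positions (um) are converted to px with
#'   `tracks$pixel_size`.
#' @param psf_sigma Gaussian PSF sd in px, > 0.
#' @param amplitude Peak spot intensity in counts, >= 0.
#' @param background Constant background in counts, >= 0.
#' @param noise_model One of `"none"`, `"poisson"`, `"gaussian"`.
#' @param noise_sd Gaussian read-noise sd (counts); only for
#'   `noise_model = "gaussian"`.
#' @param shape `c(H, W)` frame size in px.
#' @param seed Integer seed (used only when noise is enabled).
#' @return A list with `stack` (an `image_stack`: T x H x W array plus
#'   `pixel_size`, `frame_interval`) and `truth` (data frame
#'   `frame,id,x_px,y_px,off_frame`, frames 0-based).
#' @export
render_image_stack <- function(tracks, psf_sigma = 1.5, amplitude = 100,
                               background = 10,
                               noise_model = c("none", "poisson", "gaussian"),
                               noise_sd = 1, shape = c(64L, 64L),
                               seed = NULL) {
  stopifnot(inherits(tracks, "trackset"))
  noise_model <- match.arg(noise_model)
  if (!is.finite(psf_sigma) || psf_sigma <= 0) stop("psf_sigma must be > 0")
  if (amplitude < 0 || background < 0)
    stop("amplitude and background must be >= 0")
  if (length(shape) != 2L || any(shape < 1L))
    stop("shape must be two positive integers (H, W)")
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  px <- tracks$pixel_size
  n_frames <- max(vapply(tracks$trajectories, nrow, integer(1)))

  truth <- list()
  frames <- array(background, dim = c(n_frames, H, W))
  # pixel center grids (0-based)
  xc <- matrix(rep(0:(W - 1L), each = H), H, W)
  yc <- matrix(rep(0:(H - 1L), times = W), H, W)
  for (tr in tracks$trajectories) {
    id <- attr(tr, "id")
    for (k in seq_len(nrow(tr))) {
      sx <- tr$x_um[k] / px
      sy <- tr$y_um[k] / px
      off <- sx < 0 || sx > W - 1L || sy < 0 || sy > H - 1L
      truth[[length(truth) + 1L]] <-
        data.frame(frame = k - 1L, id = id, x_px = sx, y_px = sy,
                   off_frame = off)
      if (!off && amplitude > 0) {
        # render a local window only (8 sigma) for speed
        r <- ceiling(8 * psf_sigma)
        ix <- max(0L, floor(sx) - r):min(W - 1L, ceiling(sx) + r)
        iy <- max(0L, floor(sy) - r):min(H - 1L, ceiling(sy) + r)
        gx <- exp(-(ix - sx)^2 / (2 * psf_sigma^2))
        gy <- exp(-(iy - sy)^2 / (2 * psf_sigma^2))
        frames[k, iy + 1L, ix + 1L] <-
          frames[k, iy + 1L, ix + 1L] + amplitude * outer(gy, gx)
      }
    }
  }
  if (noise_model != "none") {
    frames <- with_seed(seed, {
      if (noise_model == "poisson")
        array(stats::rpois(length(frames), lambda = frames), dim = dim(frames))
      else
        pmax(frames + stats::rnorm(length(frames), sd = noise_sd), 0)
    })
  }
  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$frame, truth$id), ]
  rownames(truth) <- NULL
  stack <- structure(list(frames = frames, pixel_size = px,
                          frame_interval = tracks$frame_interval),
                     class = "image_stack")
  list(stack = stack, truth = truth)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack: %d frames of %dx%d px, %g um/px, dt = %g s>\n",
              d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Write / read an image stack as multi-page 16-bit TIFF
#'
#' Intensities are stored as 16-bit unsigned counts (clamped to 0..65535).
#'
#' @param stack An `image_stack`.
#' @param path TIFF path.
#' @param pixel_size,frame_interval Acquisition metadata to attach on read.
#' @return `path` (write) or an `image_stack` (read).
#' @export
write_image_stack <- function(stack, path) {
  d <- dim(stack$frames)
  pages <- lapply(seq_len(d[1]), function(k) {
    m <- pmin(pmax(stack$frames[k, , ], 0), 65535)
    m / 65535   # tiff package expects [0,1]
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path, pixel_size = 0.1067, frame_interval = 0.5) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  frames <- array(0, dim = c(length(pages), d[1], d[2]))
  for (k in seq_along(pages)) frames[k, , ] <- pages[[k]] * 65535
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval), class = "image_stack")
}

#' Write ground-truth spot positions as CSV
#'
#' Schema: `frame,id,x_px,y_px,off_frame`.
#' @param truth Ground-truth data frame from [render_image_stack()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
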
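## Centroid-based 2D feature finding and frame-to-frame linking, in the
## Crocker-Grier style: bandpass (Gaussian smooth minus boxcar background),
## local-maximum candidates, intensity-weighted centroid refinement within a
## circular mask, then globally optimal nearest-neighbour assignment between
## consecutive frames.

# separable convolution with replicate (edge-extend) padding; kernel is a
# normalized numeric vector of odd length
conv_sep <- function(img, kx, ky = kx) {
  conv1 <- function(m, k, along_rows) {
    r <- (length(k) - 1L) %/% 2L
    if (along_rows) m <- t(m)
    n <- nrow(m)
    idx <- pmin(pmax(outer(seq_len(n), -r:r, "+"), 1L), n)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * m[idx[, j], , drop = FALSE]
    if (along_rows) t(out) else out
  }
  conv1(conv1(img, ky, FALSE), kx, TRUE)
}

gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

box_kernel <- function(width) {
  w <- 2L * floor(width / 2) + 1L   # force odd
  rep(1 / w, w)
}

#' Bandpass filter an image for spot detection
#'
#' Gaussian smoothing (sd `noise_scale` px) suppresses pixel noise; a boxcar
#' average of width `feature_diameter` px estimates the slowly varying
#' background, which is subtracted. Negative values are clipped to zero.
#' Boundaries use replicate padding, so a constant image maps to zeros.
#'
#' @param image Numeric matrix of intensities.
#' @param noise_scale Noise correlation length in px, >= 0.
#' @param feature_diameter Spot diameter in px, > `noise_scale`.
#' @return Filtered matrix, same shape.
#' @export
bandpass_filter <- function(image, noise_scale = 1, feature_diameter = 9) {
  stopifnot(is.matrix(image))
  if (!(feature_diameter > noise_scale) || noise_scale < 0)
    stop("need feature_diameter > noise_scale >= 0")
  smoothed <- conv_sep(image, gauss_kernel(noise_scale))
  background <- conv_sep(image, box_kernel(feature_diameter))
  pmax(smoothed - background, 0)
}

#' Detect diffraction-limited spots in one image
#'
#' Bandpass-filters the image, keeps local maxima above the `threshold`
#' percentile of the filtered nonzero pixels separated by at least
#' `mask_radius` px, then refines each candidate by the intensity-weighted
#' centroid within a circular mask of radius `mask_radius` on the filtered
#' image. Mass (integrated intensity), squared radius of gyration and
#' eccentricity come from the same mask.
#'
#' @param image Numeric matrix (raw intensities).
#' @param threshold Percentile (0-100, exclusive) of filtered nonzero pixels.
#' @param mask_radius Centroid mask radius in px, >= 1.
#' @param noise_scale,feature_diameter Passed to [bandpass_filter()].
#' @return Data frame `x_px,y_px,mass,rg2,ecc` (0-based sub-pixel positions),
#'   one row per detection; zero rows when nothing is found.
#' @export
detect_spots <- function(image, threshold = 70, mask_radius = 4,
                         noise_scale = 1, feature_diameter = 9) {
  stopifnot(is.matrix(image))
  if (!(threshold > 0 && threshold < 100))
    stop("threshold must be a percentile strictly between 0 and 100")
  if (mask_radius < 1) stop("mask_radius must be >= 1")
  filt <- bandpass_filter(image, noise_scale, feature_diameter)
  nz <- filt[filt > 0]
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      mass = numeric(0), rg2 = numeric(0), ecc = numeric(0))
  if (length(nz) == 0L) return(empty)
  thr <- stats::quantile(nz, threshold / 100, names = FALSE)
  H <- nrow(filt); W <- ncol(filt)
  r <- as.integer(ceiling(mask_radius))
  cand <- which(filt >= thr & filt > 0, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  # local maximum within the mask radius
  is_max <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ri <- cand[i, 1]; ci <- cand[i, 2]
    rows <- max(1L, ri - r):min(H, ri + r)
    cols <- max(1L, ci - r):min(W, ci + r)
    nb <- filt[rows, cols]
    is_max[i] <- filt[ri, ci] >= max(nb)
  }
  cand <- cand[is_max, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  # deterministic order: brightest first, ties by (row, col)
  o <- order(-filt[cand], cand[, 1], cand[, 2])
  cand <- cand[o, , drop = FALSE]
  # enforce min separation between accepted peaks
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      later <- (i + 1L):nrow(cand)
      d2 <- (cand[later, 1] - cand[i, 1])^2 + (cand[later, 2] - cand[i, 2])^2
      keep[later][d2 < mask_radius^2] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  # circular-mask centroid refinement and moments (0-based coordinates)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs <- offs[offs$dr^2 + offs$dc^2 <= mask_radius^2, ]
  res <- lapply(seq_len(nrow(cand)), function(i) {
    ri <- cand[i, 1]; ci <- cand[i, 2]
    rr <- ri + offs$dr; cc <- ci + offs$dc
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    rr <- rr[ok]; cc <- cc[ok]
    w <- filt[cbind(rr, cc)]
    mass <- sum(w)
    if (mass <= 0) return(NULL)
    # x = column index - 1, y = row index - 1 (0-based pixel centers)
    xs <- cc - 1L; ys <- rr - 1L
    x0 <- sum(w * xs) / mass
    y0 <- sum(w * ys) / mass
    dx <- xs - x0; dy <- ys - y0
    rg2 <- sum(w * (dx^2 + dy^2)) / mass
    # eccentricity from second central moments
    mxx <- sum(w * dx^2) / mass; myy <- sum(w * dy^2) / mass
    mxy <- sum(w * dx * dy) / mass
    tr2 <- (mxx + myy) / 2
    dis <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
    l1 <- tr2 + dis; l2 <- max(tr2 - dis, 0)
    ecc <- if (l1 > 0) sqrt(1 - l2 / l1) else 0
    data.frame(x_px = x0, y_px = y0, mass = mass, rg2 = rg2, ecc = ecc)
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res)) empty else res
}

#' Detect spots in every frame of an image stack
#'
#' @param stack An `image_stack`.
#' @inheritParams detect_spots
#' @return Data frame `frame,x_px,y_px,mass,rg2,ecc` (frames 0-based).
#' @export
detect_stack <- function(stack, threshold = 70, mask_radius = 4,
                         noise_scale = 1, feature_diameter = 9) {
  stopifnot(inherits(stack, "image_stack"))
  n <- dim(stack$frames)[1]
  out <- lapply(seq_len(n), function(k) {
    d <- detect_spots(stack$frames[k, , ], threshold, mask_radius,
                      noise_scale, feature_diameter)
    if (nrow(d)) cbind(frame = k - 1L, d) else NULL
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    data.frame(frame = integer(0), x_px = numeric(0), y_px = numeric(0),
               mass = numeric(0), rg2 = numeric(0), ecc = numeric(0))
  else out
}

# Optimal assignment between previous-frame heads and current detections:
# among assignments using only pairs with squared distance <= max_d2 that
# maximize the number of links, pick the minimum total squared displacement;
# ties broken lexicographically by candidate order (heads sorted by id).
# Exact search inside connected components of the allowed-pair graph.
assign_links <- function(prev_xy, cur_xy, max_d2, max_component = 12L) {
  np <- nrow(prev_xy); nc <- nrow(cur_xy)
  link <- rep(NA_integer_, np)
  if (np == 0L || nc == 0L) return(link)
  d2 <- outer(prev_xy[, 1], cur_xy[, 1], "-")^2 +
        outer(prev_xy[, 2], cur_xy[, 2], "-")^2
  allowed <- d2 <= max_d2
  # connected components over the bipartite allowed graph
  comp_p <- rep(0L, np); comp_c <- rep(0L, nc); ncomp <- 0L
  for (s in seq_len(np)) {
    if (comp_p[s] != 0L || !any(allowed[s, ])) next
    ncomp <- ncomp + 1L
    qp <- s
    while (length(qp)) {
      p <- qp[1]; qp <- qp[-1]
      if (comp_p[p] != 0L) next
      comp_p[p] <- ncomp
      for (cc in which(allowed[p, ] & comp_c == 0L)) {
        comp_c[cc] <- ncomp
        qp <- c(qp, which(allowed[, cc] & comp_p == 0L))
      }
    }
  }
  for (g in seq_len(ncomp)) {
    ps <- which(comp_p == g); cs <- which(comp_c == g)
    if (length(ps) > max_component || length(cs) > max_component)
      stop("linking component exceeds the exact-search cap (", max_component,
           "); reduce spot density or max_displacement")
    best <- NULL; best_nlink <- -1L; best_cost <- Inf
    # depth-first enumeration over ps in order (deterministic tie-break)
    rec <- function(i, used, cur, nlink, cost) {
      # prune only when even linking every remaining head cannot win
      if (nlink + (length(ps) - i + 1L) < best_nlink) return()
      if (i > length(ps)) {
        if (nlink > best_nlink ||
            (nlink == best_nlink && cost < best_cost - 1e-15)) {
          best <<- cur; best_nlink <<- nlink; best_cost <<- cost
        }
        return()
      }
      p <- ps[i]
      opts <- cs[allowed[p, cs] & !(cs %in% used)]
      for (cc in opts)
        rec(i + 1L, c(used, cc), c(cur, cc), nlink + 1L,
            cost + d2[p, cc])
      rec(i + 1L, used, c(cur, NA_integer_), nlink, cost)  # leave unmatched
    }
    rec(1L, integer(0), integer(0), 0L, 0)
    link[ps] <- best
  }
  link
}

#' Link per-frame detections into trajectories
#'
#' Frame-to-frame correspondence is the globally optimal assignment within
#' `max_displacement`: among pairings that maximize the number of links, the
#' one minimizing total squared displacement is chosen (exact search inside
#' connected components of the candidate graph; no gap closing). Unmatched
#' detections start new tracks; tracks shorter than `min_track_length` frames
#' are discarded. Output positions are converted to um.
#'
#' @param detections Data frame `frame,x_px,y_px,...` (frames 0-based,
#'   consecutive).
#' @param max_displacement Maximum per-frame displacement in px, > 0.
#' @param min_track_length Minimum track length in frames, >= 2.
#' @param pixel_size um per px.
#' @param frame_interval Seconds per frame.
#' @param condition_label Label for the resulting trackset.
#' @return A [trackset()], or `NULL` when no track survives the length filter.
#' @export
link_trajectories <- function(detections, max_displacement = 5,
                              min_track_length = 20L, pixel_size = 0.1067,
                              frame_interval = 0.5, condition_label = "") {
  if (!(max_displacement > 0)) stop("max_displacement must be > 0")
  if (min_track_length < 2L) stop("min_track_length must be >= 2")
  if (nrow(detections) == 0L) return(NULL)
  detections <- detections[order(detections$frame, detections$x_px,
                                 detections$y_px), ]
  frames <- sort(unique(detections$frame))
  by_frame <- split(detections, detections$frame)
  next_id <- 1L
  # active tracks: list of (id, rows = list of (frame, x, y))
  active <- list()
  done <- list()
  prev_frame <- NULL
  for (f in frames) {
    det <- by_frame[[as.character(f)]]
    cur_xy <- cbind(det$x_px, det$y_px)
    if (!is.null(prev_frame) && f == prev_frame + 1L && length(active)) {
      ids <- vapply(active, function(a) a$id, integer(1))
      ord <- order(ids)   # deterministic: heads sorted by id
      active <- active[ord]
      prev_xy <- do.call(rbind, lapply(active, function(a) a$head))
      link <- assign_links(prev_xy, cur_xy, max_displacement^2)
    } else {
      # non-consecutive frame (or no active tracks): everything ends
      done <- c(done, active)
      active <- list()
      link <- integer(0)
    }
    new_active <- list()
    used <- rep(FALSE, nrow(det))
    for (i in seq_along(link)) {
      if (is.na(link[i])) { done <- c(done, active[i]); next }
      j <- link[i]
      used[j] <- TRUE
      a <- active[[i]]
      a$frames <- c(a$frames, f)
      a$x <- c(a$x, det$x_px[j]); a$y <- c(a$y, det$y_px[j])
      a$head <- c(det$x_px[j], det$y_px[j])
      new_active[[length(new_active) + 1L]] <- a
    }
    for (j in which(!used)) {
      new_active[[length(new_active) + 1L]] <-
        list(id = next_id, frames = f, x = det$x_px[j], y = det$y_px[j],
             head = c(det$x_px[j], det$y_px[j]))
      next_id <- next_id + 1L
    }
    active <- new_active
    prev_frame <- f
  }
  done <- c(done, active)
  done <- done[vapply(done, function(a) length(a$frames), integer(1)) >=
               min_track_length]
  if (length(done) == 0L) return(NULL)
  done <- done[order(vapply(done, function(a) a$id, integer(1)))]
  trs <- lapply(seq_along(done), function(i) {
    a <- done[[i]]
    trajectory(i, a$frames * frame_interval,
               a$x * pixel_size, a$y * pixel_size)
  })
  trackset(trs, frame_interval = frame_interval, pixel_size = pixel_size,
           condition_label = condition_label)
}

#' Track an image stack end to end
#'
#' Convenience wrapper: [detect_stack()] then [link_trajectories()].
#'
#' @param stack An `image_stack`.
#' @param threshold,mask_radius,noise_scale,feature_diameter Detection
#'   parameters (see [detect_spots()]).
#' @param max_displacement,min_track_length Linking parameters.
#' @param condition_label Label for the resulting trackset.
#' @return A [trackset()] or `NULL`.
#' @export
track_stack <- function(stack, threshold = 70, mask_radius = 4,
                        noise_scale = 1, feature_diameter = 9,
                        max_displacement = 5, min_track_length = 20L,
                        condition_label = "") {
  det <- detect_stack(stack, threshold, mask_radius, noise_scale,
                      feature_diameter)
  link_trajectories(det, max_displacement, min_track_length,
                    pixel_size = stack$pixel_size,
                    frame_interval = stack$frame_interval,
                    condition_label = condition_label)
}
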
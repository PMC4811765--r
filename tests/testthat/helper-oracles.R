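# Independent oracles and small fixture builders shared across tests.

# Exhaustive O(N^2) MSD reference: double loop over all start times.
brute_msd <- function(traj, max_lag) {
  n <- nrow(traj)
  vapply(seq_len(max_lag), function(m) {
    acc <- 0
    for (t in 1:(n - m))
      acc <- acc + (traj$x_um[t + m] - traj$x_um[t])^2 +
                   (traj$y_um[t + m] - traj$y_um[t])^2
    acc / (n - m)
  }, numeric(1))
}

# Brute-force optimal frame-to-frame assignment: enumerate every injective
# mapping of previous heads to current detections (NA = unmatched), maximize
# link count then minimize total squared displacement.
brute_assign <- function(prev_xy, cur_xy, max_d2) {
  np <- nrow(prev_xy); nc <- nrow(cur_xy)
  d2 <- outer(prev_xy[, 1], cur_xy[, 1], "-")^2 +
        outer(prev_xy[, 2], cur_xy[, 2], "-")^2
  best <- rep(NA_integer_, np); best_n <- -1L; best_cost <- Inf
  choices <- c(NA_integer_, seq_len(nc))
  grid <- do.call(expand.grid, rep(list(choices), np))
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    links <- !is.na(a)
    if (anyDuplicated(a[links])) next
    if (any(d2[cbind(which(links), a[links])] > max_d2)) next
    cost <- sum(d2[cbind(which(links), a[links])])
    n <- sum(links)
    if (n > best_n || (n == best_n && cost < best_cost - 1e-15)) {
      best <- a; best_n <- n; best_cost <- cost
    }
  }
  best
}

# Build a trackset from explicit position matrices (rows = frames).
tracks_from_xy <- function(x, y, dt = 0.5, pixel_size = 0.1067) {
  times <- (seq_len(nrow(x)) - 1) * dt
  trs <- lapply(seq_len(ncol(x)), function(i)
    trajectory(i, times, x[, i], y[, i]))
  trackset(trs, frame_interval = dt, pixel_size = pixel_size)
}

# Static trackset: n spots fixed at given um positions for n_frames
# (trajectories need >= 2 points, so single-frame fixtures get two identical
# frames; render consumers read frame 1).
static_tracks <- function(pos_um, n_frames, dt = 0.5, pixel_size = 0.1067) {
  pos_um <- matrix(pos_um, ncol = 2)
  n_frames <- max(n_frames, 2L)
  x <- matrix(rep(pos_um[, 1], each = n_frames), n_frames)
  y <- matrix(rep(pos_um[, 2], each = n_frames), n_frames)
  tracks_from_xy(x, y, dt, pixel_size)
}

# Ensemble MSD values only (numeric vector) for terse assertions.
emsd <- function(tracks, max_lag) ensemble_msd(tracks, max_lag)$msd_um2
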
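## Trajectory generators with known ground truth.
##
## Conventions follow the study's MSD definition: the effective diffusion
## coefficient K is the raw slope of the 2D ensemble MSD (no factor of 4
## divided out), so Brownian tracks with msd_slope = K have per-axis
## increment variance K*dt/2 and expected 2D MSD exactly K*tau.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop("seed must be a single integer")
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Build a trackset from per-trajectory increment matrices (rows = steps,
# cols = trajectories); positions start at the origin.
tracks_from_increments <- function(dx, dy, dt, condition_label, start_xy = NULL) {
  n_traj <- ncol(dx)
  n_frames <- nrow(dx) + 1L
  times <- (seq_len(n_frames) - 1L) * dt
  x <- rbind(0, apply(dx, 2L, cumsum))
  y <- rbind(0, apply(dy, 2L, cumsum))
  if (!is.null(start_xy)) {
    x <- sweep(x, 2L, start_xy[1L, ], "+")
    y <- sweep(y, 2L, start_xy[2L, ], "+")
  }
  trs <- lapply(seq_len(n_traj), function(i)
    trajectory(i, times, x[, i], y[, i]))
  trackset(trs, frame_interval = dt, condition_label = condition_label)
}

#' Simulate 2D Brownian trajectories with a prescribed MSD slope
#'
#' Generates pure Brownian motion parameterized directly by the slope of the
#' 2D ensemble MSD, i.e. the effective diffusion coefficient K of the study's
#' convention: per-axis increments are i.i.d. Gaussian with variance
#' `msd_slope * dt / 2`, so E\[MSD(tau)\] = `msd_slope * tau` exactly.
#'
#' @param n_traj Number of trajectories.
#' @param n_frames Frames per trajectory (>= 2); default 121 matches a 60 s
#'   acquisition at 0.5 s intervals, inclusive of t = 0.
#' @param dt Frame interval in seconds.
#' @param msd_slope Target 2D MSD slope in um^2/s (>= 0).
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @return A [trackset()].
#' @examples
#' ts <- simulate_brownian(20, 121, 0.5, 0.0057, seed = 1)
#' @export
simulate_brownian <- function(n_traj, n_frames = 121L, dt = 0.5,
                              msd_slope = 0.0057, seed = NULL) {
  stopifnot(n_traj >= 1L, n_frames >= 2L, dt > 0)
  if (!is.finite(msd_slope) || msd_slope < 0)
    stop("msd_slope must be >= 0")
  with_seed(seed, {
    sd_ax <- sqrt(msd_slope * dt / 2)
    nstep <- (n_frames - 1L) * n_traj
    dx <- matrix(stats::rnorm(nstep, sd = sd_ax), n_frames - 1L, n_traj)
    dy <- matrix(stats::rnorm(nstep, sd = sd_ax), n_frames - 1L, n_traj)
    tracks_from_increments(dx, dy, dt, "brownian")
  })
}

# fBm increment autocovariance gamma(k) for unit-variance steps, Hurst H.
fbm_acov <- function(k, H) {
  (abs(k + 1)^(2 * H) + abs(k - 1)^(2 * H) - 2 * abs(k)^(2 * H)) / 2
}

# Sample n_series fractional-Gaussian-noise series of length n with Hurst H
# and unit marginal step variance. Davies-Harte circulant embedding; exact
# Cholesky fallback when the embedding is not positive semi-definite.
rfgn <- function(n, n_series, H) {
  acov <- fbm_acov(0:n, H)
  circ <- c(acov, rev(acov[2:n]))          # length 2n
  lambda <- Re(stats::fft(circ))
  if (min(lambda) >= -1e-8 * max(lambda)) {
    lambda <- pmax(lambda, 0)
    m <- 2L * n
    # complex Gaussian spectral synthesis; two independent real series per
    # FFT, use the real part only (columns are independent draws).
    z <- matrix(stats::rnorm(m * n_series), m, n_series) +
      1i * matrix(stats::rnorm(m * n_series), m, n_series)
    w <- sqrt(lambda / (2 * m)) * z
    out <- Re(stats::mvfft(w))[seq_len(n), , drop = FALSE]
    # Re(fft) of the symmetrized spectrum has the target covariance
    out * sqrt(2)
  } else {
    # exact covariance factorization (small n only)
    S <- stats::toeplitz(acov[seq_len(n)])
    L <- tryCatch(t(chol(S)), error = function(e)
      stop("fractional Gaussian noise covariance is not positive definite; ",
           "cannot synthesize exactly (n = ", n, ", H = ", H, ")"))
    L %*% matrix(stats::rnorm(n * n_series), n, n_series)
  }
}

#' Simulate subdiffusive trajectories as fractional Brownian motion
#'
#' Each axis is exact fractional Brownian motion with Hurst exponent
#' `H = alpha / 2`, scaled so the expected 2D MSD is `gamma * tau^alpha`.
#' Increments are synthesized with exact covariance (circulant embedding,
#' with a Cholesky fallback); the per-axis step variance is
#' `(gamma / 2) * dt^alpha` and the increment autocovariance follows the
#' fBm closed form.
#'
#' @param n_traj Number of trajectories.
#' @param n_frames Frames per trajectory.
#' @param dt Frame interval (s).
#' @param alpha Anomalous diffusion exponent, in (0, 2); `alpha < 1` is
#'   subdiffusion, `alpha = 1` recovers Brownian motion.
#' @param gamma Generalized diffusion prefactor (um^2 / s^alpha), > 0.
#' @param seed Integer seed.
#' @return A [trackset()].
#' @export
simulate_fbm <- function(n_traj, n_frames = 121L, dt = 0.5, alpha = 0.69,
                         gamma = 0.0057, seed = NULL) {
  stopifnot(n_traj >= 1L, n_frames >= 2L, dt > 0)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 2)
    stop("alpha must lie strictly inside (0, 2)")
  if (!is.finite(gamma) || gamma <= 0)
    stop("gamma must be > 0")
  with_seed(seed, {
    H <- alpha / 2
    sd_step <- sqrt((gamma / 2) * dt^alpha)
    n <- n_frames - 1L
    dx <- rfgn(n, n_traj, H) * sd_step
    dy <- rfgn(n, n_traj, H) * sd_step
    tracks_from_increments(dx, dy, dt, "fbm")
  })
}

#' Simulate confined trajectories (Ornstein-Uhlenbeck)
#'
#' Models constrained diffusion (e.g. chromatin tethering) as an exactly
#' discretized Ornstein-Uhlenbeck process per axis: mean-reversion rate
#' `1/tau_c`, stationary variance `D * tau_c`, started from the stationary
#' distribution. The expected 2D MSD is `4 * D * tau_c * (1 - exp(-tau/tau_c))`,
#' rising with initial slope `4 * D` and saturating at the plateau
#' `4 * D * tau_c`.
#'
#' @param n_traj Number of trajectories.
#' @param n_frames Frames per trajectory.
#' @param dt Frame interval (s).
#' @param D Per-axis diffusion coefficient (um^2/s), >= 0.
#' @param tau_c Confinement (relaxation) time in seconds, > 0.
#' @param seed Integer seed.
#' @return A [trackset()].
#' @export
simulate_confined <- function(n_traj, n_frames = 121L, dt = 0.5, D = 0.005,
                              tau_c = 5, seed = NULL) {
  stopifnot(n_traj >= 1L, n_frames >= 2L, dt > 0)
  if (!is.finite(D) || D < 0) stop("D must be >= 0")
  if (!is.finite(tau_c) || tau_c <= 0) stop("tau_c must be > 0")
  with_seed(seed, {
    phi <- exp(-dt / tau_c)
    svar <- D * tau_c                      # stationary variance per axis
    innov_sd <- sqrt(svar * (1 - phi^2))
    sim_axis <- function() {
      m <- matrix(0, n_frames, n_traj)
      m[1L, ] <- stats::rnorm(n_traj, sd = sqrt(svar))
      for (k in 2:n_frames)
        m[k, ] <- phi * m[k - 1L, ] + stats::rnorm(n_traj, sd = innov_sd)
      m
    }
    x <- sim_axis(); y <- sim_axis()
    times <- (seq_len(n_frames) - 1L) * dt
    trs <- lapply(seq_len(n_traj), function(i)
      trajectory(i, times, x[, i], y[, i]))
    trackset(trs, frame_interval = dt, condition_label = "confined")
  })
}

#' Add static localization noise to trajectories
#'
#' Adds i.i.d. Gaussian offsets (sd `sigma_loc` per axis, per frame) to every
#' position, emulating the finite-photon localization error of centroid
#' tracking. The expected MSD of the result equals the input MSD plus the
#' constant `4 * sigma_loc^2` at every lag >= 1.
#'
#' @param tracks A [trackset()].
#' @param sigma_loc Localization error sd per axis, in um (>= 0).
#' @param seed Integer seed.
#' @return A new `trackset` with perturbed positions.
#' @export
add_localization_noise <- function(tracks, sigma_loc, seed = NULL) {
  stopifnot(inherits(tracks, "trackset"))
  if (!is.finite(sigma_loc) || sigma_loc < 0)
    stop("sigma_loc must be >= 0")
  if (sigma_loc == 0) return(tracks)
  with_seed(seed, {
    trs <- lapply(tracks$trajectories, function(tr) {
      n <- nrow(tr)
      trajectory(attr(tr, "id"), tr$t_s,
                 tr$x_um + stats::rnorm(n, sd = sigma_loc),
                 tr$y_um + stats::rnorm(n, sd = sigma_loc))
    })
    trackset(trs, frame_interval = tracks$frame_interval,
             pixel_size = tracks$pixel_size,
             condition_label = tracks$condition_label)
  })
}

#' Simulate paired two-locus trajectories with common nuclear drift
#'
#' Emulates two chromosomal loci tracked in the same nucleus: each locus
#' diffuses independently (Brownian, MSD slopes `msd_slope_a`, `msd_slope_b`)
#' about anchors `mean_separation` apart, and an identical per-frame rigid
#' translation (i.i.d. Gaussian, sd `common_drift_sd` per axis) is applied to
#' both, emulating whole-nucleus motion. The inter-locus distance is exactly
#' invariant to the common term.
#'
#' @param n_pairs Number of locus pairs.
#' @param n_frames Frames per trajectory; default 101 matches a 150 s
#'   acquisition at 1.5 s intervals.
#' @param dt Frame interval (s); default 1.5.
#' @param msd_slope_a,msd_slope_b 2D MSD slopes of the two loci (um^2/s).
#' @param mean_separation Anchor separation in um, > 0.
#' @param common_drift_sd Per-axis sd of the shared per-frame translation (um).
#' @param seed Integer seed.
#' @return A list with `trackset` elements `a` and `b`; trajectories with the
#'   same id form a pair on a common time grid.
#' @export
simulate_two_locus <- function(n_pairs, n_frames = 101L, dt = 1.5,
                               msd_slope_a = 0.0057, msd_slope_b = 0.0057,
                               mean_separation = 2, common_drift_sd = 0.05,
                               seed = NULL) {
  stopifnot(n_pairs >= 1L, n_frames >= 2L, dt > 0)
  if (!is.finite(mean_separation) || mean_separation <= 0)
    stop("mean_separation must be > 0")
  if (msd_slope_a < 0 || msd_slope_b < 0) stop("msd slopes must be >= 0")
  if (common_drift_sd < 0) stop("common_drift_sd must be >= 0")
  with_seed(seed, {
    times <- (seq_len(n_frames) - 1L) * dt
    mk_paths <- function(slope) {
      sd_ax <- sqrt(slope * dt / 2)
      dx <- matrix(stats::rnorm((n_frames - 1L) * n_pairs, sd = sd_ax),
                   n_frames - 1L, n_pairs)
      dy <- matrix(stats::rnorm((n_frames - 1L) * n_pairs, sd = sd_ax),
                   n_frames - 1L, n_pairs)
      list(x = rbind(0, apply(dx, 2L, cumsum)),
           y = rbind(0, apply(dy, 2L, cumsum)))
    }
    pa <- mk_paths(msd_slope_a)
    pb <- mk_paths(msd_slope_b)
    drift_x <- matrix(stats::rnorm(n_frames * n_pairs, sd = common_drift_sd),
                      n_frames, n_pairs)
    drift_y <- matrix(stats::rnorm(n_frames * n_pairs, sd = common_drift_sd),
                      n_frames, n_pairs)
    mk_set <- function(p, x_anchor, label) {
      trs <- lapply(seq_len(n_pairs), function(i)
        trajectory(i, times,
                   p$x[, i] + x_anchor + drift_x[, i],
                   p$y[, i] + drift_y[, i]))
      trackset(trs, frame_interval = dt, condition_label = label)
    }
    list(a = mk_set(pa, 0, "locus_a"),
         b = mk_set(pb, mean_separation, "locus_b"))
  })
}
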
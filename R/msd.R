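## Mean-square-displacement analysis.
##
## MSD(tau) = < (r(t + tau) - r(t))^2 >, averaged over all overlapping start
## times t within a trajectory (time average), then over trajectories
## (ensemble average). K is the free-intercept OLS slope of the ensemble MSD
## over lag indices 1-10; alpha is the log-log OLS slope over lags 1-40.

new_msd_curve <- function(lags, values, sem, n_per_lag) {
  stopifnot(all(diff(lags) > 0), all(values >= 0 | is.na(values)))
  structure(
    data.frame(lag_s = lags, msd_um2 = values, sem_um2 = sem, n = n_per_lag),
    class = c("msd_curve", "data.frame"))
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve: %d lags, tau = %g..%g s>\n",
              nrow(x), min(x$lag_s), max(x$lag_s)))
  invisible(x)
}

#' Time-averaged MSD of a single trajectory
#'
#' For each lag `m = 1..max_lag`, averages the squared 2D displacement over
#' all `N - m` overlapping start times.
#'
#' @param traj A [trajectory()].
#' @param max_lag Largest lag index; truncated to `N - 1` with a warning when
#'   it exceeds the trajectory length.
#' @return An `msd_curve` data frame with columns `lag_s`, `msd_um2`,
#'   `sem_um2` (NA for a single trajectory) and `n` (displacement pairs).
#' @export
compute_msd <- function(traj, max_lag = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj)
  if (is.null(max_lag)) max_lag <- n - 1L
  if (max_lag >= n) {
    warning(sprintf("max_lag %d >= trajectory length %d; truncated to %d",
                    max_lag, n, n - 1L))
    max_lag <- n - 1L
  }
  stopifnot(max_lag >= 1L)
  dt <- attr(traj, "dt")
  vals <- vapply(seq_len(max_lag), function(m) {
    dxm <- traj$x_um[(1L + m):n] - traj$x_um[1:(n - m)]
    dym <- traj$y_um[(1L + m):n] - traj$y_um[1:(n - m)]
    mean(dxm^2 + dym^2)
  }, numeric(1))
  new_msd_curve(seq_len(max_lag) * dt, vals, rep(NA_real_, max_lag),
                n - seq_len(max_lag))
}

#' Ensemble-averaged MSD of a trackset
#'
#' Computes the time-averaged MSD of every trajectory and takes the unweighted
#' mean across trajectories at each lag (each trajectory counts once,
#' regardless of length). The SEM at each lag is the sample standard deviation
#' across contributing trajectories divided by sqrt(n). Trajectories shorter
#' than a lag simply do not contribute at that lag.
#'
#' @param tracks A [trackset()].
#' @param max_lag Largest lag index; default: longest trajectory minus 1.
#' @return An `msd_curve`; `n` counts contributing trajectories per lag.
#' @export
ensemble_msd <- function(tracks, max_lag = NULL) {
  stopifnot(inherits(tracks, "trackset"))
  if (length(tracks) < 1L) stop("empty trackset")
  lens <- vapply(tracks$trajectories, nrow, integer(1))
  if (is.null(max_lag)) max_lag <- max(lens) - 1L
  max_lag <- min(max_lag, max(lens) - 1L)
  dt <- tracks$frame_interval
  acc <- matrix(NA_real_, length(tracks), max_lag)
  for (i in seq_along(tracks$trajectories)) {
    tr <- tracks$trajectories[[i]]
    m_i <- min(max_lag, nrow(tr) - 1L)
    acc[i, seq_len(m_i)] <- compute_msd(tr, m_i)$msd_um2
  }
  n_per_lag <- colSums(!is.na(acc))
  vals <- colMeans(acc, na.rm = TRUE)
  sdv <- apply(acc, 2L, stats::sd, na.rm = TRUE)
  sem <- ifelse(n_per_lag >= 2L, sdv / sqrt(n_per_lag), NA_real_)
  keep <- n_per_lag >= 1L
  new_msd_curve((seq_len(max_lag) * dt)[keep], vals[keep], sem[keep],
                n_per_lag[keep])
}

new_diffusion_fit <- function(K = NA_real_, K_intercept = NA_real_,
                              K_r2 = NA_real_, K_window = NA,
                              alpha = NA_real_, alpha_prefactor = NA_real_,
                              alpha_r2 = NA_real_, alpha_window = NA) {
  structure(list(K = K, K_intercept = K_intercept, K_r2 = K_r2,
                 K_window = K_window, alpha = alpha,
                 alpha_prefactor = alpha_prefactor, alpha_r2 = alpha_r2,
                 alpha_window = alpha_window),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat("<diffusion_fit>\n")
  if (!is.na(x$K))
    cat(sprintf("  K     = %.4g um^2/s (intercept %.4g um^2, r2 %.4f)\n",
                x$K, x$K_intercept, x$K_r2))
  if (!is.na(x$alpha))
    cat(sprintf("  alpha = %.3f (prefactor %.4g um^2/s^alpha, r2 %.4f)\n",
                x$alpha, x$alpha_prefactor, x$alpha_r2))
  invisible(x)
}

#' Effective diffusion coefficient K from an MSD curve
#'
#' K is the ordinary-least-squares slope of MSD versus lag time over lag
#' indices 1-10 inclusive (tau = 0.5..5 s at 0.5 s framing). The intercept is
#' free by default, which decouples K from static localization error (whose
#' signature is a constant 4*sigma^2 offset); `through_origin = TRUE` forces
#' the fit through zero.
#'
#' @param msd An `msd_curve` with at least `max(window)` lags.
#' @param window Integer lag-index window, default `1:10`.
#' @param through_origin Constrain the intercept to zero.
#' @return A `diffusion_fit` with `K` (um^2/s), `K_intercept` (um^2) and fit
#'   r-squared.
#' @export
fit_K <- function(msd, window = 1:10, through_origin = FALSE) {
  stopifnot(inherits(msd, "msd_curve"))
  if (nrow(msd) < max(window))
    stop(sprintf("K fit needs %d lags but the curve has only %d",
                 max(window), nrow(msd)))
  tau <- msd$lag_s[window]
  y <- msd$msd_um2[window]
  if (through_origin) {
    fit <- stats::lm(y ~ tau + 0)
    K <- unname(stats::coef(fit)[1]); b <- 0
  } else {
    fit <- stats::lm(y ~ tau)
    K <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  }
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  new_diffusion_fit(K = K, K_intercept = b, K_r2 = r2,
                    K_window = range(window))
}

#' Anomalous diffusion exponent alpha from an MSD curve
#'
#' alpha is the slope of log(MSD) versus log(tau) by unweighted OLS over the
#' first `n_lags` lag indices (default 40, i.e. tau <= 20 s at 0.5 s framing);
#' the power-law prefactor is `exp(intercept)`.
#'
#' @param msd An `msd_curve` with at least `n_lags` lags, all positive within
#'   the window.
#' @param n_lags Number of leading lags to fit, default 40.
#' @return A `diffusion_fit` with `alpha`, `alpha_prefactor` and fit
#'   r-squared.
#' @export
fit_alpha <- function(msd, n_lags = 40L) {
  stopifnot(inherits(msd, "msd_curve"))
  if (nrow(msd) < n_lags)
    stop(sprintf("alpha fit needs %d lags but the curve has only %d",
                 n_lags, nrow(msd)))
  w <- seq_len(n_lags)
  y <- msd$msd_um2[w]
  if (any(y <= 0))
    stop("alpha fit window contains nonpositive MSD values; cannot take log")
  lx <- log(msd$lag_s[w]); ly <- log(y)
  fit <- stats::lm(ly ~ lx)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ly - mean(ly))^2)
  new_diffusion_fit(alpha = unname(stats::coef(fit)[2]),
                    alpha_prefactor = exp(unname(stats::coef(fit)[1])),
                    alpha_r2 = r2, alpha_window = n_lags)
}

#' Fit both K and alpha from one ensemble MSD curve
#'
#' @inheritParams fit_K
#' @inheritParams fit_alpha
#' @return A `diffusion_fit` with both the K and alpha fields populated.
#' @export
fit_diffusion <- function(msd, window = 1:10, n_lags = 40L,
                          through_origin = FALSE) {
  k <- fit_K(msd, window = window, through_origin = through_origin)
  a <- fit_alpha(msd, n_lags = n_lags)
  k$alpha <- a$alpha
  k$alpha_prefactor <- a$alpha_prefactor
  k$alpha_r2 <- a$alpha_r2
  k$alpha_window <- a$alpha_window
  k
}

#' Scalar inter-locus distance series of a two-locus pair
#'
#' The Euclidean distance between two loci at each common time point. Because
#' whole-nucleus translation moves both loci identically, the distance series
#' isolates intranuclear motion.
#'
#' @param traj_a,traj_b [trajectory()] objects; frames are matched by
#'   timestamp (within 1e-9 s) and unmatched frames dropped with a warning.
#' @return A `distance_series` data frame with columns `t_s` and `d_um`.
#' @export
two_locus_distance <- function(traj_a, traj_b) {
  stopifnot(inherits(traj_a, "trajectory"), inherits(traj_b, "trajectory"))
  ia <- round(traj_a$t_s / attr(traj_a, "dt"))
  ib <- round(traj_b$t_s / attr(traj_b, "dt"))
  common <- intersect(ia, ib)
  if (length(common) == 0L) stop("trajectories share no common frames")
  if (length(common) < max(length(ia), length(ib)))
    warning("frames present in only one trajectory were dropped")
  ka <- match(common, ia); kb <- match(common, ib)
  d <- sqrt((traj_a$x_um[ka] - traj_b$x_um[kb])^2 +
            (traj_a$y_um[ka] - traj_b$y_um[kb])^2)
  out <- data.frame(t_s = traj_a$t_s[ka], d_um = d)
  attr(out, "dt") <- attr(traj_a, "dt")
  class(out) <- c("distance_series", "data.frame")
  out
}

#' MSD of a scalar inter-locus distance series
#'
#' Mean over overlapping start times of `(d(t + tau) - d(t))^2`, the
#' interchromosomal MSD used to quantify intranuclear displacement free of
#' whole-nucleus translation.
#'
#' @param series A `distance_series` from [two_locus_distance()].
#' @param max_lag Largest lag index (as in [compute_msd()]).
#' @return An `msd_curve`.
#' @export
two_locus_msd <- function(series, max_lag = NULL) {
  stopifnot(inherits(series, "distance_series"))
  n <- nrow(series)
  if (is.null(max_lag)) max_lag <- n - 1L
  if (max_lag >= n) {
    warning(sprintf("max_lag %d >= series length %d; truncated", max_lag, n))
    max_lag <- n - 1L
  }
  dt <- attr(series, "dt")
  vals <- vapply(seq_len(max_lag), function(m)
    mean((series$d_um[(1L + m):n] - series$d_um[1:(n - m)])^2), numeric(1))
  new_msd_curve(seq_len(max_lag) * dt, vals, rep(NA_real_, max_lag),
                n - seq_len(max_lag))
}

#' Ensemble two-locus MSD over a paired trackset
#'
#' Averages the per-pair distance MSDs across pairs (unweighted, SEM across
#' pairs), mirroring [ensemble_msd()].
#'
#' @param pair A list with `trackset` elements `a` and `b` (ids matched), as
#'   returned by [simulate_two_locus()].
#' @param max_lag Largest lag index.
#' @return An `msd_curve`.
#' @export
ensemble_two_locus_msd <- function(pair, max_lag = NULL) {
  ids_a <- vapply(pair$a$trajectories, function(tr) attr(tr, "id"), integer(1))
  ids_b <- vapply(pair$b$trajectories, function(tr) attr(tr, "id"), integer(1))
  common <- intersect(ids_a, ids_b)
  if (length(common) == 0L) stop("no matched pair ids")
  dt <- pair$a$frame_interval
  curves <- lapply(common, function(id) {
    s <- two_locus_distance(pair$a$trajectories[[match(id, ids_a)]],
                            pair$b$trajectories[[match(id, ids_b)]])
    two_locus_msd(s, max_lag)
  })
  m <- max(vapply(curves, nrow, integer(1)))
  acc <- matrix(NA_real_, length(curves), m)
  for (i in seq_along(curves))
    acc[i, seq_len(nrow(curves[[i]]))] <- curves[[i]]$msd_um2
  n_per_lag <- colSums(!is.na(acc))
  sem <- ifelse(n_per_lag >= 2L,
                apply(acc, 2L, stats::sd, na.rm = TRUE) / sqrt(n_per_lag),
                NA_real_)
  new_msd_curve(seq_len(m) * dt, colMeans(acc, na.rm = TRUE), sem, n_per_lag)
}

#' Write / read an MSD curve as CSV
#'
#' Schema: `lag_s,msd_um2,sem_um2,n`.
#' @param msd An `msd_curve`.
#' @param path CSV path.
#' @return `path` (write) or an `msd_curve` (read).
#' @export
write_msd <- function(msd, path) {
  utils::write.csv(as.data.frame(msd), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_msd
#' @export
read_msd <- function(path) {
  df <- utils::read.csv(path)
  new_msd_curve(df$lag_s, df$msd_um2, df$sem_um2, df$n)
}

#' Log-log MSD overlay plot
#'
#' Plots one or more MSD curves on log-log axes with a dashed slope-one guide
#' line (the signature of pure Brownian motion).
#'
#' @param curves Named list of `msd_curve` objects.
#' @param path Optional PNG path; when given the plot is written there.
#' @param main Plot title.
#' @return `invisible(NULL)`.
#' @export
plot_msd_loglog <- function(curves, path = NULL, main = "ensemble MSD") {
  if (inherits(curves, "msd_curve")) curves <- list(MSD = curves)
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 600)
    on.exit(grDevices::dev.off())
  }
  xr <- range(unlist(lapply(curves, function(cu) cu$lag_s)))
  yr <- range(unlist(lapply(curves, function(cu) cu$msd_um2[cu$msd_um2 > 0])))
  graphics::plot(NA, xlim = xr, ylim = yr, log = "xy",
                 xlab = expression(tau ~ "(s)"),
                 ylab = expression(MSD ~ (mu * m^2)), main = main)
  cols <- grDevices::hcl.colors(max(2L, length(curves)), "Dark 2")
  for (i in seq_along(curves))
    graphics::lines(curves[[i]]$lag_s, curves[[i]]$msd_um2, col = cols[i],
                    lwd = 2)
  # slope-one guide through the geometric centre
  gx <- exp(mean(log(xr))); gy <- exp(mean(log(yr)))
  graphics::abline(a = log10(gy) - log10(gx), b = 1, untf = FALSE,
                   col = "gray", lty = 2)
  if (length(curves) > 1L)
    graphics::legend("topleft", legend = names(curves), col =
                     cols[seq_along(curves)], lwd = 2, bty = "n")
  invisible(NULL)
}
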
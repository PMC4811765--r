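## Synthetic AFM force curves and Coulter-counter volume populations.

#' Simulate an AFM parallel-plate compression force curve
#'
#' Emulates repeated micro-compression of a single spheroplast with a wedged
#' tipless cantilever: per cycle, the cantilever approaches at `rate` through
#' a free-travel segment (zero force), contacts the cell and loads linearly
#' with slope `k_cell` until `f_max`, holds for `hold_s`, then retracts.
#' Samples are taken at 40 Hz; Gaussian force noise of sd `noise_sd` is added
#' to every sample.
#'
#' @param k_cell Cell stiffness in nN/um, >= 0.
#' @param n_cycles Number of compression cycles; default 8 (one initial plus
#'   seven repeats).
#' @param f_max Target force in nN, > 0; default 10.
#' @param rate Cantilever speed in um/s; default 1.
#' @param noise_sd Force noise sd in nN, >= 0.
#' @param free_travel Zero-force approach distance in um before contact.
#' @param hold_s Hold duration at `f_max` in seconds; default 10.
#' @param sample_hz Sampling rate; default 40.
#' @param seed Integer seed.
#' @return A `force_curve`: data frame `cycle,phase,t_s,height_um,force_nN`
#'   with phases `approach`, `hold`, `retract`; heights decrease during
#'   approach.
#' @export
simulate_force_curve <- function(k_cell, n_cycles = 8L, f_max = 10,
                                 rate = 1, noise_sd = 0, free_travel = 2,
                                 hold_s = 10, sample_hz = 40, seed = NULL) {
  if (!is.finite(k_cell) || k_cell < 0) stop("k_cell must be >= 0")
  if (!is.finite(f_max) || f_max <= 0) stop("f_max must be > 0")
  stopifnot(n_cycles >= 1L, rate > 0, noise_sd >= 0, sample_hz > 0)
  dt <- 1 / sample_hz
  contact_h <- 0                        # height at first contact
  indent <- if (k_cell > 0) f_max / k_cell else free_travel
  top <- contact_h + free_travel
  bottom <- contact_h - indent
  with_seed(seed, {
    rows <- vector("list", n_cycles)
    t0 <- 0
    for (cy in seq_len(n_cycles)) {
      # approach: height falls from top to bottom at `rate`
      n_app <- max(2L, ceiling((top - bottom) / rate / dt))
      h_app <- seq(top, bottom, length.out = n_app)
      f_app <- ifelse(h_app < contact_h, k_cell * (contact_h - h_app), 0)
      t_app <- t0 + seq_len(n_app) * dt
      # hold at bottom
      n_hold <- max(1L, round(hold_s / dt))
      t_hold <- t_app[n_app] + seq_len(n_hold) * dt
      f_hold <- rep(if (k_cell > 0) f_max else 0, n_hold)
      # retract back to top
      n_ret <- n_app
      h_ret <- seq(bottom, top, length.out = n_ret)
      f_ret <- ifelse(h_ret < contact_h, k_cell * (contact_h - h_ret), 0)
      t_ret <- t_hold[n_hold] + seq_len(n_ret) * dt
      rows[[cy]] <- data.frame(
        cycle = cy,
        phase = c(rep("approach", n_app), rep("hold", n_hold),
                  rep("retract", n_ret)),
        t_s = c(t_app, t_hold, t_ret),
        height_um = c(h_app, rep(bottom, n_hold), h_ret),
        force_nN = c(f_app, f_hold, f_ret))
      t0 <- t_ret[n_ret]
    }
    out <- do.call(rbind, rows)
    if (noise_sd > 0)
      out$force_nN <- out$force_nN + stats::rnorm(nrow(out), sd = noise_sd)
    class(out) <- c("force_curve", "data.frame")
    out
  })
}

#' Write / read a force curve as TSV
#'
#' Schema: `cycle,phase,t_s,height_um,force_nN` (tab-separated).
#' @param curve A `force_curve`.
#' @param path TSV path.
#' @return `path` (write) or a `force_curve` (read).
#' @export
write_force_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_force_curve
#' @export
read_force_curve <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("cycle", "phase", "t_s", "height_um", "force_nN")
  if (!all(need %in% names(df)))
    stop("force-curve TSV must have columns cycle,phase,t_s,height_um,force_nN")
  class(df) <- c("force_curve", "data.frame")
  df
}

#' Simulate a log-normal cell-volume population
#'
#' Draws cell volumes from a log-normal distribution parameterized by its
#' median and standard deviation: `mu = log(median_fL)` and `sigma^2` solved
#' from the log-normal variance identity
#' `sd^2 = (exp(sigma^2) - 1) * exp(2*mu + sigma^2)`.
#'
#' @param n Number of cells; Coulter-counter runs in the emulated protocol
#'   count 50,000 yeast (100,000 bacteria).
#' @param median_fL Population median volume in fL, > 0.
#' @param sd_fL Population standard deviation in fL, > 0.
#' @param seed Integer seed.
#' @return A `volume_population`: numeric vector of volumes (fL) with
#'   attribute `instrument_label`.
#' @export
simulate_volume_population <- function(n, median_fL = 101.6, sd_fL = 54.6,
                                       seed = NULL) {
  stopifnot(n >= 1L)
  if (!is.finite(median_fL) || median_fL <= 0) stop("median_fL must be > 0")
  if (!is.finite(sd_fL) || sd_fL <= 0) stop("sd_fL must be > 0")
  mu <- log(median_fL)
  # w = exp(sigma^2) solves w^2 - w = (sd/median)^2
  disc <- 1 + 4 * (sd_fL / median_fL)^2
  w <- (1 + sqrt(disc)) / 2
  if (!is.finite(w) || w <= 1)
    stop("no real sigma solves the requested median/sd pair")
  sigma <- sqrt(log(w))
  with_seed(seed, {
    v <- stats::rlnorm(n, meanlog = mu, sdlog = sigma)
    structure(v, instrument_label = "synthetic multisizer",
              class = "volume_population")
  })
}

#' @export
print.volume_population <- function(x, ...) {
  cat(sprintf("<volume_population: n = %d, median = %.1f fL (%s)>\n",
              length(x), stats::median(unclass(x)),
              attr(x, "instrument_label")))
  invisible(x)
}

#' Write / read a volume population as single-column CSV (`volume_fL`)
#'
#' @param pop A `volume_population` (or numeric vector of fL volumes).
#' @param path CSV path.
#' @return `path` (write) or a `volume_population` (read).
#' @export
write_volumes <- function(pop, path) {
  utils::write.csv(data.frame(volume_fL = as.numeric(pop)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_volumes
#' @export
read_volumes <- function(path) {
  df <- utils::read.csv(path)
  if (!"volume_fL" %in% names(df))
    stop("volume CSV must have a volume_fL column")
  if (any(df$volume_fL <= 0)) stop("all volumes must be > 0")
  structure(df$volume_fL, instrument_label = basename(path),
            class = "volume_population")
}
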
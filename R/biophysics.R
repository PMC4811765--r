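## Non-trajectory quantifications: accessible cytoplasmic volume budget,
## volume-distribution summaries, dry-mass crowding index, AFM stiffness,
## ratiometric pH calibration, ATP standardization.

#' Nuclear volumes (fL) before and after glucose starvation
#'
#' Named constants used as defaults by [accessible_volume()]: the non-starved
#' and starved nuclear volumes from three-dimensional reconstruction,
#' 4.60 fL and 4.12 fL.
#' @export
nuclear_volumes <- c(NS = 4.60, S = 4.12)

#' Accessible cytoplasmic volume budget
#'
#' The volume available to diffusing cytoplasmic macromolecules is the total
#' cell volume minus the vacuolar and nuclear volumes, evaluated separately
#' for the non-starved (NS) and starved (S) conditions:
#' \deqn{A_{NS} = C_{NS} - V_{NS} - N_{NS}, \quad A_S = C_S - V_S - N_S}
#' with \eqn{C_S = (1 - shrink) \cdot C_{NS}}, \eqn{V_{NS} = vr_{NS} \cdot
#' C_{NS}} and \eqn{V_S = vr_S \cdot C_S}. The headline quantity is the
#' fractional reduction `1 - A_S / A_NS`.
#'
#' @param C_NS Non-starved total cell volume in fL, > 0.
#' @param shrink Fractional cell-volume loss upon starvation, in \[0, 1);
#'   default 0.15.
#' @param v_ratio_NS,v_ratio_S Vacuole-to-cell volume fractions, in \[0, 1);
#'   defaults 0.25 and 0.40.
#' @param N_NS,N_S Nuclear volumes in fL; defaults [nuclear_volumes].
#' @return A `volume_budget` list: `C_NS,C_S,V_NS,V_S,N_NS,N_S,A_NS,A_S,
#'   reduction`.
#' @examples
#' accessible_volume(101.6)$reduction   # ~0.334
#' @export
accessible_volume <- function(C_NS = 101.6, shrink = 0.15,
                              v_ratio_NS = 0.25, v_ratio_S = 0.40,
                              N_NS = nuclear_volumes[["NS"]],
                              N_S = nuclear_volumes[["S"]]) {
  if (!is.finite(C_NS) || C_NS <= 0) stop("C_NS must be > 0")
  if (shrink < 0 || shrink >= 1) stop("shrink must lie in [0, 1)")
  if (v_ratio_NS < 0 || v_ratio_NS >= 1 || v_ratio_S < 0 || v_ratio_S >= 1)
    stop("vacuole ratios must lie in [0, 1)")
  if (N_NS <= 0 || N_S <= 0) stop("nuclear volumes must be > 0")
  C_S <- (1 - shrink) * C_NS
  V_NS <- v_ratio_NS * C_NS
  V_S <- v_ratio_S * C_S
  if (V_NS + N_NS >= C_NS || V_S + N_S >= C_S)
    stop("vacuole plus nucleus exceed the cell volume; inputs inconsistent")
  A_NS <- C_NS - V_NS - N_NS
  A_S <- C_S - V_S - N_S
  if (A_NS <= 0 || A_S <= 0)
    stop("accessible volume is nonpositive; inputs inconsistent")
  structure(list(C_NS = C_NS, C_S = C_S, V_NS = V_NS, V_S = V_S,
                 N_NS = N_NS, N_S = N_S, A_NS = A_NS, A_S = A_S,
                 reduction = 1 - A_S / A_NS),
            class = "volume_budget")
}

#' @export
print.volume_budget <- function(x, ...) {
  cat(sprintf(paste0("<volume_budget: A_NS = %.2f fL, A_S = %.2f fL, ",
                     "reduction = %.1f%%>\n"),
              x$A_NS, x$A_S, 100 * x$reduction))
  invisible(x)
}

#' Summary statistics of a cell-volume population
#'
#' Median and standard deviation are the plain sample statistics. The modal
#' volume follows the Coulter-counter convention for right-skewed size
#' distributions: a log-spaced histogram (bin count by the Freedman-Diaconis
#' rule on log-volumes) is converted to a density by dividing counts by the
#' per-bin width in fL, and the peak is refined to sub-bin precision by the
#' vertex of a local quadratic fit around the highest smoothed bin.
#'
#' @param pop A `volume_population` or positive numeric vector (fL), n >= 10.
#' @return List `median`, `modal_volume`, `sd`, `n`, `bin_width_log` (width of
#'   the log-volume bins the mode was read from).
#' @export
volume_summary <- function(pop) {
  v <- as.numeric(pop)
  if (length(v) < 10L) stop("need at least 10 volumes")
  if (any(v <= 0)) stop("volumes must be > 0")
  lv <- log(v)
  rng <- diff(range(lv))
  if (rng == 0)
    return(list(median = v[1], modal_volume = v[1], sd = 0,
                n = length(v), bin_width_log = 0))
  iqr <- stats::IQR(lv)
  bw <- if (iqr > 0) 2 * iqr / length(v)^(1 / 3) else rng / 30
  nbin <- max(1L, ceiling(rng / bw))
  breaks <- seq(min(lv), max(lv), length.out = nbin + 1L)
  h <- graphics::hist(lv, breaks = breaks, plot = FALSE)
  # log-spaced bins widen with volume; divide counts by the bin width in fL
  # so the maximum estimates the mode of the volume density, not of log-volume
  dens <- h$counts / diff(exp(breaks))
  # FD-width bins are tuned for the full histogram, not for the argmax, whose
  # raw position carries several bins of counting noise on flat peaks; locate
  # the peak on a lightly smoothed density, then refine to sub-bin precision
  # by the vertex of a local quadratic fit
  sm <- if (length(dens) >= 5L)
    stats::filter(dens, rep(1 / 5, 5), sides = 2) else dens
  i0 <- which.max(sm)
  win <- max(1L, i0 - 10L):min(length(dens), i0 + 10L)
  mode_log <- h$mids[i0]
  if (length(win) >= 5L) {
    co <- stats::coef(stats::lm(dens[win] ~ stats::poly(h$mids[win], 2,
                                                        raw = TRUE)))
    vertex <- -co[2] / (2 * co[3])
    if (is.finite(vertex) && co[3] < 0 && vertex >= min(h$mids[win]) &&
        vertex <= max(h$mids[win]))
      mode_log <- vertex
  }
  list(median = stats::median(v), modal_volume = exp(mode_log),
       sd = stats::sd(v), n = length(v),
       bin_width_log = diff(breaks[1:2]))
}

#' Fractional volume contraction between two populations
#'
#' `1 - stat(after) / stat(before)` with `stat` either the median or the
#' modal volume of [volume_summary()].
#'
#' @param pop_before,pop_after Volume populations (fL).
#' @param statistic `"median"` or `"mode"`.
#' @return Fractional contraction (positive when the population shrank).
#' @export
volume_contraction <- function(pop_before, pop_after,
                               statistic = c("median", "mode")) {
  statistic <- match.arg(statistic)
  sb <- volume_summary(pop_before); sa <- volume_summary(pop_after)
  if (statistic == "median") 1 - sa$median / sb$median
  else 1 - sa$modal_volume / sb$modal_volume
}

#' Dry-mass density (crowding index) and condition-pair changes
#'
#' Density is dry mass per accessible volume (pg/fL). When a second condition
#' is supplied, percent changes are reported separately for the densities and
#' for the masses, since a volume loss at constant mass is precisely what
#' raises crowding.
#'
#' @param dry_mass_per_cell Dry mass in pg/cell, > 0.
#' @param accessible_vol Accessible volume in fL, > 0.
#' @param dry_mass_2,accessible_vol_2 Optional second condition.
#' @return List with `density` (and, given a pair, `density_2`,
#'   `density_change_pct`, `mass_change_pct`).
#' @export
crowding_index <- function(dry_mass_per_cell, accessible_vol,
                           dry_mass_2 = NULL, accessible_vol_2 = NULL) {
  if (dry_mass_per_cell <= 0 || accessible_vol <= 0)
    stop("mass and volume must be > 0")
  out <- list(density = dry_mass_per_cell / accessible_vol)
  if (!is.null(dry_mass_2)) {
    if (is.null(accessible_vol_2))
      stop("supply both dry_mass_2 and accessible_vol_2")
    if (dry_mass_2 <= 0 || accessible_vol_2 <= 0)
      stop("mass and volume must be > 0")
    out$density_2 <- dry_mass_2 / accessible_vol_2
    out$density_change_pct <- 100 * (out$density_2 / out$density - 1)
    out$mass_change_pct <- 100 * (dry_mass_2 / dry_mass_per_cell - 1)
  }
  out
}

#' Spheroplast stiffness from AFM compression cycles
#'
#' For each cycle, fits force versus cantilever height by ordinary least
#' squares over the approach ("downward") samples with force in
#' `[f_lo, f_hi]` (inclusive; defaults 3-7 nN) and takes the magnitude of the
#' slope as that cycle's stiffness (nN/um). Cycles with fewer than
#' `min_samples` in-window samples are skipped with a warning; the result is
#' the arithmetic mean over usable cycles.
#'
#' @param curve A `force_curve` (columns `cycle,phase,t_s,height_um,force_nN`).
#' @param f_lo,f_hi Force window in nN.
#' @param min_samples Minimum in-window samples per usable cycle; default 5.
#' @return A `stiffness_result`: `per_cycle_slopes`, `mean_stiffness`,
#'   `n_cycles_used`.
#' @export
afm_stiffness <- function(curve, f_lo = 3, f_hi = 7, min_samples = 5L) {
  stopifnot(inherits(curve, "data.frame"))
  if (!(f_hi > f_lo)) stop("need f_hi > f_lo")
  slopes <- c()
  for (cy in sort(unique(curve$cycle))) {
    seg <- curve[curve$cycle == cy & curve$phase == "approach", ]
    seg <- seg[seg$force_nN >= f_lo & seg$force_nN <= f_hi, ]
    if (nrow(seg) < min_samples) {
      warning(sprintf("cycle %s: only %d samples in the %g-%g nN window; skipped",
                      cy, nrow(seg), f_lo, f_hi))
      next
    }
    co <- stats::coef(stats::lm(force_nN ~ height_um, data = seg))
    slopes <- c(slopes, abs(unname(co[2])))
  }
  if (length(slopes) == 0L)
    stop("no usable cycles: no approach segment spans the force window")
  structure(list(per_cycle_slopes = slopes,
                 mean_stiffness = mean(slopes),
                 n_cycles_used = length(slopes)),
            class = "stiffness_result")
}

#' @export
print.stiffness_result <- function(x, ...) {
  cat(sprintf("<stiffness_result: %.2f nN/um over %d cycles>\n",
              x$mean_stiffness, x$n_cycles_used))
  invisible(x)
}

#' Fit a ratiometric pH calibration curve
#'
#' Builds a shape-preserving monotone piecewise-cubic (Hyman-filtered spline)
#' interpolant between buffer pH and emission ratio, in both directions. Node
#' ratios must be strictly monotone in pH; the calibration buffers span
#' pH 5.0-8.0 in the emulated protocol.
#'
#' @param ph Buffer pH values, >= 4 points, strictly increasing.
#' @param ratio Measured emission ratios, strictly monotone in pH.
#' @return A `ph_calibration` with forward (`pH -> ratio`) and inverse
#'   evaluators and the node table.
#' @export
fit_ph_calibration <- function(ph, ratio) {
  if (length(ph) < 4L) stop("need at least 4 calibration points")
  if (length(ratio) != length(ph)) stop("ph and ratio lengths differ")
  o <- order(ph)
  ph <- ph[o]; ratio <- ratio[o]
  if (any(diff(ph) <= 0)) stop("pH nodes must be distinct")
  dr <- diff(ratio)
  if (!(all(dr > 0) || all(dr < 0))) {
    bad <- which(sign(dr) != sign(dr[1]))
    stop("calibration ratios are not strictly monotone in pH; offending ",
         "segment(s) after pH ", paste(ph[bad], collapse = ", "))
  }
  fwd <- stats::splinefun(ph, ratio, method = "hyman")
  inv <- if (dr[1] > 0) stats::splinefun(ratio, ph, method = "hyman")
         else stats::splinefun(rev(ratio), rev(ph), method = "hyman")
  structure(list(nodes = data.frame(pH = ph, ratio = ratio),
                 forward = fwd, inverse = inv,
                 ratio_range = range(ratio)),
            class = "ph_calibration")
}

#' @export
print.ph_calibration <- function(x, ...) {
  cat(sprintf("<ph_calibration: %d nodes, pH %.1f-%.1f, ratio %.3g-%.3g>\n",
              nrow(x$nodes), min(x$nodes$pH), max(x$nodes$pH),
              x$ratio_range[1], x$ratio_range[2]))
  invisible(x)
}

#' Invert an emission ratio to intracellular pH
#'
#' @param curve A `ph_calibration`.
#' @param ratio Emission ratio(s) within the calibrated range; values outside
#'   it raise an error stating the valid range (no extrapolation).
#' @return Estimated pH value(s).
#' @export
invert_ph <- function(curve, ratio) {
  stopifnot(inherits(curve, "ph_calibration"))
  rr <- curve$ratio_range
  if (any(ratio < rr[1] - 1e-12 | ratio > rr[2] + 1e-12))
    stop(sprintf("ratio outside the calibrated range [%g, %g]", rr[1], rr[2]))
  curve$inverse(pmin(pmax(ratio, rr[1]), rr[2]))
}

#' Standardize luciferase ATP measurements
#'
#' Fits the standards by linear OLS (`luminescence ~ concentration`), converts
#' sample luminescence to concentration via the fitted line (floored at zero
#' with a flag), divides by the sample OD600, and normalizes to the
#' pre-treatment value so the pre-treatment time point is 1 by construction.
#'
#' @param samples Data frame `time,luminescence,OD600`.
#' @param standards Data frame `conc,luminescence`, >= 3 rows, luminescence
#'   increasing in concentration.
#' @param pre_treatment List or vector with `luminescence` and `OD600` of the
#'   pre-treatment control.
#' @return An `atp_result`: standards fit (`slope`, `intercept`, `r2`) and a
#'   per-timepoint data frame `time,conc_uM,normalized,floored`.
#' @export
atp_standardize <- function(samples, standards, pre_treatment) {
  need <- c("time", "luminescence", "OD600")
  if (!all(need %in% names(samples)))
    stop("samples must have columns time,luminescence,OD600")
  if (!all(c("conc", "luminescence") %in% names(standards)))
    stop("standards must have columns conc,luminescence")
  if (nrow(standards) < 3L) stop("need at least 3 standards")
  o <- order(standards$conc)
  if (any(diff(standards$luminescence[o]) <= 0))
    stop("standards luminescence must increase with concentration")
  fit <- stats::lm(luminescence ~ conc, data = standards)
  slope <- unname(stats::coef(fit)[2]); intercept <- unname(stats::coef(fit)[1])
  if (abs(slope) < .Machine$double.eps)
    stop("degenerate standards: zero slope")
  lum <- standards$luminescence
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((lum - mean(lum))^2)
  pre <- as.list(pre_treatment)
  conv <- function(lum) (lum - intercept) / slope
  pre_conc <- conv(pre$luminescence)
  if (pre_conc <= 0) stop("pre-treatment luminescence is at or below blank")
  pre_norm <- pre_conc / pre$OD600
  conc_raw <- conv(samples$luminescence)
  floored <- conc_raw < 0
  conc <- pmax(conc_raw, 0)
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 timepoints = data.frame(
                   time = samples$time, conc_uM = conc,
                   normalized = (conc / samples$OD600) / pre_norm,
                   floored = floored)),
            class = "atp_result")
}

#' @export
print.atp_result <- function(x, ...) {
  cat(sprintf("<atp_result: standards slope %.4g counts/uM (r2 %.4f), %d timepoints>\n",
              x$slope, x$r2, nrow(x$timepoints)))
  invisible(x)
}
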
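# Volume budget, volume summaries, crowding index, AFM stiffness, pH
# calibration and ATP standardization.

test_that("accessible volume obeys the budget identities and printed inputs", {
  vb <- accessible_volume(101.6, shrink = 0.15, v_ratio_NS = 0.25,
                          v_ratio_S = 0.40, N_NS = 4.60, N_S = 4.12)
  # conservation to machine precision
  expect_equal(vb$A_NS + vb$V_NS + vb$N_NS, vb$C_NS, tolerance = 1e-15)
  expect_equal(vb$A_S + vb$V_S + vb$N_S, vb$C_S, tolerance = 1e-15)
  # closed-form evaluation of the printed inputs: ~33.4% reduction
  expect_equal(vb$A_NS, 101.6 - 25.4 - 4.60, tolerance = 1e-12)
  expect_equal(vb$reduction, 1 - 47.696 / 71.6, tolerance = 1e-9)
  expect_gte(100 * vb$reduction, 30)  # at least the rounded headline claim
  # no-change inputs -> zero reduction
  same <- accessible_volume(100, shrink = 0, v_ratio_NS = 0.2,
                            v_ratio_S = 0.2, N_NS = 4, N_S = 4)
  expect_equal(same$reduction, 0, tolerance = 1e-15)
  # large-cell limit with the standard ratios: 1 - 0.51/0.75
  lim <- accessible_volume(1e9, shrink = 0.15, v_ratio_NS = 0.25,
                           v_ratio_S = 0.40, N_NS = 4.6, N_S = 4.12)
  expect_equal(lim$reduction, 1 - 0.85 * 0.60 / 0.75, tolerance = 1e-6)
  expect_error(accessible_volume(10, v_ratio_NS = 0.9, N_NS = 4, N_S = 4),
               "inconsistent|exceed")
})

test_that("reduction grows with shrink and with the starved vacuole ratio", {
  grid_s <- seq(0, 0.3, by = 0.05)
  red_s <- sapply(grid_s, function(s)
    accessible_volume(101.6, shrink = s)$reduction)
  expect_true(all(diff(red_s) > 0))
  grid_v <- seq(0.25, 0.6, by = 0.05)
  red_v <- sapply(grid_v, function(v)
    accessible_volume(101.6, v_ratio_S = v)$reduction)
  expect_true(all(diff(red_v) > 0))
})

test_that("volume summaries and contraction match their definitions", {
  allsame <- structure(rep(50, 100), class = "volume_population")
  vs <- volume_summary(allsame)
  expect_equal(vs$median, 50)
  expect_equal(vs$modal_volume, 50, tolerance = 1e-9)
  expect_equal(vs$sd, 0)
  expect_error(volume_summary(rep(50, 5)), "at least 10")
  # identical populations -> zero contraction
  vp <- simulate_volume_population(2000, 100, 40, seed = 1)
  expect_equal(volume_contraction(vp, vp), 0, tolerance = 1e-15)
  # modal contraction recovers the generated mode ratio (~9.5%)
  b <- simulate_volume_population(100000, 100, 40, seed = 2)
  a <- simulate_volume_population(100000, 90.5, 36.2, seed = 3)
  got <- volume_contraction(b, a, statistic = "mode")
  expect_lt(abs(got - 0.095), 0.04)
  # median contraction across seeds: recovery within 1% at n = 50,000
  for (s in 4:6) {
    p <- simulate_volume_population(50000, 101.6, 54.6, seed = s)
    expect_lt(abs(volume_summary(p)$median - 101.6) / 101.6, 0.01)
  }
})

test_that("crowding index arithmetic matches the printed mass/volume numbers", {
  # equal masses, accessible volume falls by a third -> density +50%
  ci <- crowding_index(10, 60, 10, 40)
  expect_equal(ci$density_change_pct, 50, tolerance = 1e-12)
  expect_equal(ci$mass_change_pct, 0, tolerance = 1e-12)
  # 11.5 -> 8.9 pg/cell is a 22.6% mass reduction (rounds to 23%)
  cm <- crowding_index(11.5, 71.6, 8.9, 71.6)
  expect_equal(round(-cm$mass_change_pct), 23)
  expect_equal(-cm$mass_change_pct, 100 * (1 - 8.9 / 11.5), tolerance = 1e-12)
  # densities from the dry-mass + accessible-volume pairing
  cd <- crowding_index(11.5, 71.6, 11.9, 47.696)
  expect_equal(cd$density, 11.5 / 71.6, tolerance = 1e-12)
  expect_equal(cd$density_2, 11.9 / 47.696, tolerance = 1e-12)
  expect_error(crowding_index(-1, 10), "> 0")
})

test_that("AFM stiffness: exact on noiseless curves, unbiased under noise", {
  fc <- simulate_force_curve(20, n_cycles = 8, noise_sd = 0, seed = 1)
  sr <- afm_stiffness(fc)
  expect_equal(sr$n_cycles_used, 8)
  expect_equal(sr$per_cycle_slopes, rep(20, 8), tolerance = 1e-9)
  expect_equal(sr$mean_stiffness, mean(sr$per_cycle_slopes))
  # curve that never reaches the window -> error
  weak <- simulate_force_curve(20, n_cycles = 2, f_max = 2, noise_sd = 0)
  expect_error(suppressWarnings(afm_stiffness(weak)), "no usable cycles")
  # invariance: sample order within a cycle and a constant force offset with
  # a compensating window shift leave the slope unchanged
  perm <- fc[sample(nrow(fc)), ]
  expect_equal(afm_stiffness(perm)$mean_stiffness, 20, tolerance = 1e-9)
  shifted <- fc
  shifted$force_nN <- shifted$force_nN + 1
  expect_equal(afm_stiffness(shifted, f_lo = 4, f_hi = 8)$mean_stiffness, 20,
               tolerance = 1e-9)
  # 200 replicate noisy curves at k = 18: mean recovery within 2%
  means <- vapply(1:200, function(s)
    afm_stiffness(simulate_force_curve(18, n_cycles = 8, noise_sd = 0.1,
                                       seed = s))$mean_stiffness,
    numeric(1))
  expect_lt(abs(mean(means) - 18) / 18, 0.02)
})

test_that("force curves round-trip through TSV", {
  fc <- simulate_force_curve(15, n_cycles = 2, noise_sd = 0.05, seed = 9)
  p <- tempfile(fileext = ".tsv")
  write_force_curve(fc, p)
  back <- read_force_curve(p)
  expect_equal(afm_stiffness(back)$mean_stiffness,
               afm_stiffness(fc)$mean_stiffness, tolerance = 1e-6)
})

test_that("pH calibration interpolates nodes exactly and inverts monotonely", {
  ph <- seq(5, 8, by = 0.5)
  sig <- function(p) 0.3 + 1.6 / (1 + exp(-(p - 6.5) / 0.6))
  cal <- fit_ph_calibration(ph, sig(ph))
  # interpolation identity at nodes
  expect_equal(invert_ph(cal, sig(ph)), ph, tolerance = 1e-9)
  # inversion at inter-node ratios within 0.05 pH of dense numeric inversion
  dense_p <- seq(5, 8, by = 1e-4)
  for (r in sig(c(5.3, 6.1, 6.8, 7.6))) {
    truth <- dense_p[which.min(abs(sig(dense_p) - r))]
    expect_lt(abs(invert_ph(cal, r) - truth), 0.05)
  }
  # strict monotonicity of the inverse over the whole range
  rr <- seq(min(cal$ratio_range), max(cal$ratio_range), length.out = 200)
  expect_true(all(diff(invert_ph(cal, rr)) > 0))
  # out-of-range ratio and non-monotone nodes are loud errors
  expect_error(invert_ph(cal, 10), "range")
  expect_error(fit_ph_calibration(c(5, 6, 7, 8), c(1, 2, 1.5, 3)),
               "monotone")
  # decreasing ratio calibration also works (linear 2-segment check)
  cal2 <- fit_ph_calibration(c(5, 6, 7, 8), c(2.0, 1.5, 1.0, 0.5))
  expect_equal(invert_ph(cal2, 1.25), 6.5, tolerance = 1e-9)
})

test_that("ATP standardization: linear standards, OD correction, flooring", {
  std <- data.frame(conc = c(0, 0.5, 1, 2), luminescence = 500 * c(0, 0.5, 1, 2) + 50)
  pre <- list(luminescence = 550, OD600 = 0.5)
  samples <- data.frame(time = c(0, 10, 30),
                        luminescence = c(550, 300, 40),
                        OD600 = c(0.5, 0.5, 0.5))
  res <- atp_standardize(samples, std, pre)
  expect_equal(res$slope, 500, tolerance = 1e-9)
  expect_equal(res$intercept, 50, tolerance = 1e-9)
  expect_equal(res$r2, 1, tolerance = 1e-12)
  # sample identical to pre-treatment -> normalized 1; blank -> conc 0
  expect_equal(res$timepoints$normalized[1], 1, tolerance = 1e-12)
  expect_equal(res$timepoints$conc_uM[1], 1, tolerance = 1e-9)
  expect_equal(res$timepoints$conc_uM[3], 0)
  expect_true(res$timepoints$floored[3])
  # OD correction: same luminescence at half the OD doubles the normalized value
  s2 <- data.frame(time = 0, luminescence = 550, OD600 = 0.25)
  expect_equal(atp_standardize(s2, std, pre)$timepoints$normalized, 2,
               tolerance = 1e-12)
  expect_error(atp_standardize(samples, std[1:2, ], pre), "3 standards")
  bad <- data.frame(conc = c(0, 1, 2), luminescence = c(100, 50, 200))
  expect_error(atp_standardize(samples, bad, pre), "increase")
})
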
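# Feature finding and linking: bandpass behaviour, sub-pixel localization
# accuracy against rendered ground truth, and optimality of the assignment.

test_that("bandpass filter zeroes constants, preserves peaks, contracts noise", {
  const <- matrix(7, 32, 32)
  expect_equal(bandpass_filter(const), matrix(0, 32, 32))
  expect_error(bandpass_filter(const, noise_scale = 5, feature_diameter = 3),
               "feature_diameter")
  # single Gaussian spot on a flat background: argmax unchanged
  st <- static_tracks(cbind(20 * 0.1067, 14 * 0.1067), 1)
  img <- render_image_stack(st, psf_sigma = 1.5, amplitude = 50,
                            background = 20, shape = c(32, 40))$stack$frames[1, , ]
  f <- bandpass_filter(img)
  expect_equal(which(f == max(f), arr.ind = TRUE)[1, ],
               which(img == max(img), arr.ind = TRUE)[1, ])
  # white noise: output variance strictly below input variance
  set.seed(5)
  noise <- matrix(rnorm(64 * 64), 64, 64)
  expect_lt(var(as.vector(bandpass_filter(noise))), var(as.vector(noise)))
})

test_that("a noiseless rendered spot is detected within 0.1 px of truth", {
  st <- static_tracks(cbind(20.3 * 0.1067, 41.7 * 0.1067), 1)
  rend <- render_image_stack(st, psf_sigma = 1.5, amplitude = 100,
                             background = 10, shape = c(64, 64))
  d <- detect_spots(rend$stack$frames[1, , ])
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$x_px - 20.3), 0.1)
  expect_lt(abs(d$y_px - 41.7), 0.1)
  expect_gt(d$mass, 0)
  expect_gte(d$rg2, 0)
  # blank image -> no detections, not an error
  expect_equal(nrow(detect_spots(matrix(0, 32, 32))), 0)
  expect_error(detect_spots(rend$stack$frames[1, , ], threshold = 0),
               "threshold")
})

test_that("rendered spot intensity and centroid match the Gaussian integral", {
  st <- static_tracks(cbind(20.3 * 0.1067, 41.7 * 0.1067), 1)
  rend <- render_image_stack(st, psf_sigma = 1.5, amplitude = 100,
                             background = 10, shape = c(64, 64))
  img <- rend$stack$frames[1, , ] - 10
  expect_lt(abs(sum(img) - 100 * 2 * pi * 1.5^2) / (100 * 2 * pi * 1.5^2),
            0.01)
  # intensity-weighted centroid of the whole frame within 0.05 px
  xc <- outer(rep(1, 64), 0:63); yc <- outer(0:63, rep(1, 64))
  expect_lt(abs(sum(img * xc) / sum(img) - 20.3), 0.05)
  expect_lt(abs(sum(img * yc) / sum(img) - 41.7), 0.05)
  # amplitude 0 -> constant background
  r0 <- render_image_stack(st, amplitude = 0, background = 3,
                           shape = c(16, 16))
  expect_equal(r0$stack$frames[1, , ], matrix(3, 16, 16))
  # off-frame spots flagged, not rendered
  far <- static_tracks(cbind(500 * 0.1067, 2 * 0.1067), 1)
  rf <- render_image_stack(far, shape = c(16, 16))
  expect_true(all(rf$truth$off_frame))
})

test_that("detection on 50 SNR-10 Poisson spots: recall >= 0.95, RMSE <= 0.2 px", {
  # jittered grid, >= 10 px separation, on a 200x200 frame
  set.seed(17)
  gx <- rep(seq(12, 180, by = 24), times = 8)[1:50]
  gy <- rep(seq(12, 180, by = 24), each = 8)[1:50]
  pos_px <- cbind(gx + runif(50, -3, 3), gy + runif(50, -3, 3))
  st <- static_tracks(pos_px * 0.1067, 1)
  rend <- render_image_stack(st, psf_sigma = 1.5, amplitude = 100,
                             background = 10, noise_model = "poisson",
                             shape = c(200, 200), seed = 18)
  d <- detect_spots(rend$stack$frames[1, , ])
  truth <- rend$truth[rend$truth$frame == 0, ]
  errs <- c(); hits <- 0
  for (i in seq_len(nrow(truth))) {
    de <- sqrt((d$x_px - truth$x_px[i])^2 + (d$y_px - truth$y_px[i])^2)
    if (length(de) && min(de) < 2) {
      hits <- hits + 1
      errs <- c(errs, min(de))
    }
  }
  expect_gte(hits / nrow(truth), 0.95)
  expect_lte(sqrt(mean(errs^2)), 0.2)
})

test_that("linking: single spot and well-separated spots give exact tracks", {
  # one detection per frame for 121 frames -> one track of length 121
  det <- data.frame(frame = 0:120, x_px = 20 + 0.1 * sin(0:120),
                    y_px = 30 + 0.1 * cos(0:120))
  ts <- link_trajectories(det, max_displacement = 5, min_track_length = 20)
  expect_equal(length(ts), 1)
  expect_equal(nrow(ts$trajectories[[1]]), 121)
  # two spots always >= 10 * max_displacement apart: two tracks, no swaps
  set.seed(23)
  n <- 60
  xa <- 10 + cumsum(rnorm(n, sd = 0.5)); ya <- 10 + cumsum(rnorm(n, sd = 0.5))
  xb <- 150 + cumsum(rnorm(n, sd = 0.5)); yb <- 150 + cumsum(rnorm(n, sd = 0.5))
  det2 <- data.frame(frame = rep(0:(n - 1), 2), x_px = c(xa, xb),
                     y_px = c(ya, yb))
  ts2 <- link_trajectories(det2, max_displacement = 5, min_track_length = 20,
                           pixel_size = 1, frame_interval = 1)
  expect_equal(length(ts2), 2)
  ends <- sapply(ts2$trajectories, function(tr) tr$x_um[1])
  # each track stays on its own side
  for (tr in ts2$trajectories) {
    expect_true(all(tr$x_um < 100) || all(tr$x_um > 100))
  }
})

test_that("assignment equals the brute-force optimum on crossing tracks", {
  set.seed(29)
  for (rep in 1:20) {
    np <- sample(2:4, 1); nc <- sample(2:4, 1)
    prev <- matrix(runif(2 * np, 0, 10), np)
    cur <- matrix(runif(2 * nc, 0, 10), nc)
    max_d2 <- runif(1, 4, 49)
    got <- sptcrowd:::assign_links(prev, cur, max_d2)
    want <- brute_assign(prev, cur, max_d2)
    # same link count and same total cost (tie-broken solutions may differ)
    cost <- function(a) sum(((prev[, 1] - cur[a, 1])^2 +
                             (prev[, 2] - cur[a, 2])^2)[!is.na(a)])
    expect_equal(sum(!is.na(got)), sum(!is.na(want)))
    expect_equal(cost(got), cost(want), tolerance = 1e-12)
  }
})

test_that("linking is permutation-invariant and monotone in max_displacement", {
  set.seed(31)
  n <- 40
  det <- do.call(rbind, lapply(0:(n - 1), function(f) {
    k <- 3
    data.frame(frame = f,
               x_px = c(10, 25, 40) + rnorm(k, sd = 0.8),
               y_px = c(10, 25, 40) + rnorm(k, sd = 0.8))
  }))
  base <- link_trajectories(det, 5, 10, pixel_size = 1, frame_interval = 1)
  perm <- det[sample(nrow(det)), ]
  again <- link_trajectories(perm, 5, 10, pixel_size = 1, frame_interval = 1)
  key <- function(ts) {
    df <- as.data.frame(ts)
    df <- df[order(df$t_s, df$x_um), c("t_s", "x_um", "y_um")]
    rownames(df) <- NULL
    df
  }
  expect_equal(key(again), key(base), tolerance = 1e-12)
  # link count never increases as max_displacement decreases
  n_links <- function(ts) if (is.null(ts)) 0 else
    sum(sapply(ts$trajectories, nrow) - 1)
  l_big <- n_links(link_trajectories(det, 6, 2, 1, 1))
  l_mid <- n_links(link_trajectories(det, 3, 2, 1, 1))
  l_small <- n_links(link_trajectories(det, 1, 2, 1, 1))
  expect_gte(l_big, l_mid)
  expect_gte(l_mid, l_small)
})

test_that("end-to-end: noiseless movies are recovered with correct identities", {
  # three well-separated slow walkers, 30 frames
  set.seed(37)
  n <- 30
  anchors <- cbind(c(12, 32, 52), c(12, 40, 20))
  x <- sapply(1:3, function(i) anchors[i, 1] + cumsum(rnorm(n, sd = 0.3)))
  y <- sapply(1:3, function(i) anchors[i, 2] + cumsum(rnorm(n, sd = 0.3)))
  truth_ts <- tracks_from_xy(x * 0.1067, y * 0.1067, dt = 0.5)
  rend <- render_image_stack(truth_ts, psf_sigma = 1.5, amplitude = 200,
                             background = 5, shape = c(64, 64))
  got <- track_stack(rend$stack, min_track_length = 20)
  expect_equal(length(got), 3)
  # match each recovered track to its ground-truth twin; per-frame error <= 0.1 px
  for (tr in got$trajectories) {
    expect_equal(nrow(tr), n)
    d0 <- sapply(1:3, function(i)
      mean(sqrt((tr$x_um / 0.1067 - x[, i])^2 + (tr$y_um / 0.1067 - y[, i])^2)))
    i <- which.min(d0)
    err_px <- sqrt((tr$x_um / 0.1067 - x[, i])^2 + (tr$y_um / 0.1067 - y[, i])^2)
    expect_lt(max(err_px), 0.1)
  }
})

test_that("image stacks round-trip through 16-bit TIFF", {
  st <- static_tracks(cbind(10 * 0.1067, 12 * 0.1067), 3)
  rend <- render_image_stack(st, amplitude = 500, background = 20,
                             shape = c(32, 32))
  p <- tempfile(fileext = ".tif")
  write_image_stack(rend$stack, p)
  back <- read_image_stack(p, frame_interval = 0.5)
  expect_equal(dim(back$frames), dim(rend$stack$frames))
  # 16-bit quantization: at most one count of error
  expect_lt(max(abs(back$frames - rend$stack$frames)), 1.01)
})
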
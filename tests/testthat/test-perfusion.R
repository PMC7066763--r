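# perfusion curve metrics and extraction

line_curve <- function(slope = 10, base = 50, nb = 8, n = 30) {
  t <- 0:(n - 1)
  v <- base + pmax(t - nb, 0) * slope
  si_time_curve(t, v, baseline_frames = nb)
}

test_that("foot detection: construction, degenerate baseline, no arrival", {
  ph <- make_perfusion_series(phantom_spec("perfusion_series", t0 = 12))
  fb <- detect_foot_and_baseline(ph$curves$seg_1)
  expect_lte(abs(fb$foot_time - 12), 1)          # within one frame of t0
  flat <- si_time_curve(0:29, rep(50, 30), baseline_frames = 8)
  expect_error(detect_foot_and_baseline(flat), "no contrast arrival")
  # zero-sd baseline: foot at the first sustained uptick
  lc <- line_curve()
  expect_identical(detect_foot_and_baseline(lc)$foot_index, 10L)
  expect_error(detect_foot_and_baseline(
    si_time_curve(0:29, c(rep(1, 4), 2:27), baseline_frames = 4)),
    "at least 5")
})

test_that("max_upslope: exact line, window contract, normalization", {
  lc <- line_curve(slope = 10)
  for (w in c(2, 3, 5))
    expect_equal(as.numeric(max_upslope(lc, window = w)), 10)
  expect_error(max_upslope(lc, window = 1), "window")
  # window longer than the foot-to-peak rise
  short <- si_time_curve(0:9, c(rep(10, 6), 20, 30, 25, 24),
                         baseline_frames = 5)
  expect_error(max_upslope(short, window = 8), "window longer")
  # normalized upslope is flagged and scale-invariant
  ph <- make_perfusion_series(phantom_spec("perfusion_series"))
  raw <- max_upslope(ph$curves$seg_1)
  nrm <- max_upslope(ph$curves$seg_1, normalize_to = ph$curves$blood)
  expect_false(attr(raw, "normalized")); expect_true(attr(nrm, "normalized"))
  scaled <- ph$curves$seg_1; scaled$values <- scaled$values * 3
  sblood <- ph$curves$blood; sblood$values <- sblood$values * 3
  expect_equal(as.numeric(max_upslope(scaled)), 3 * as.numeric(raw))
  expect_equal(as.numeric(max_upslope(scaled, normalize_to = sblood)),
               as.numeric(nrm))
})

test_that("hypoperfusion factor is recovered exactly without noise", {
  ph <- make_perfusion_series(phantom_spec("perfusion_series",
                                           hypo_segments = 5L,
                                           hypo_factor = 0.5))
  a <- max_upslope(ph$curves$seg_5, normalize_to = ph$curves$blood)
  b <- max_upslope(ph$curves$seg_1, normalize_to = ph$curves$blood)
  expect_equal(as.numeric(a) / as.numeric(b), 0.5)
})

test_that("time_to_peak: analytic mode, tie rule, truncation warning", {
  ph <- make_perfusion_series(phantom_spec("perfusion_series"))
  expect_lte(abs(as.numeric(time_to_peak(ph$curves$seg_1)) - ph$truth$ttp), 1)
  # plateau of equal maxima resolves to the first plateau frame
  pl <- si_time_curve(0:19, c(rep(10, 8), 20, 50, 90, 90, 90, 60, 40,
                              rep(30, 5)), baseline_frames = 8)
  expect_equal(as.numeric(time_to_peak(pl)),
               10 - detect_foot_and_baseline(pl)$foot_index + 1)
  # peak on the last frame carries a warning
  rise <- si_time_curve(0:14, c(rep(10, 8), 11:17), baseline_frames = 8)
  expect_match(attr(time_to_peak(rise), "warnings"), "truncated")
})

test_that("upslope_integral: triangle, gamma-variate oracle, baseline shift", {
  tri <- si_time_curve(0:24, c(rep(0, 9), seq(10, 100, by = 10),
                               rep(0, 6)), baseline_frames = 8)
  expect_equal(as.numeric(upslope_integral(tri)), 500)   # triangle area
  ph <- make_perfusion_series(phantom_spec("perfusion_series"))
  expect_equal(as.numeric(upslope_integral(ph$curves$seg_1)),
               ph$truth$upslope_integral, tolerance = 0.02)
  # all metrics invariant under adding a constant to the whole curve
  sh <- ph$curves$seg_1; sh$values <- sh$values + 37
  expect_equal(as.numeric(upslope_integral(sh)),
               as.numeric(upslope_integral(ph$curves$seg_1)))
  expect_equal(as.numeric(max_upslope(sh)),
               as.numeric(max_upslope(ph$curves$seg_1)))
  expect_equal(as.numeric(time_to_peak(sh)),
               as.numeric(time_to_peak(ph$curves$seg_1)))
})

test_that("perfusion_reserve_index ratios and contracts", {
  ph_s <- make_perfusion_series(phantom_spec("perfusion_series", peak = 200))
  ph_r <- make_perfusion_series(phantom_spec("perfusion_series", peak = 100))
  ms <- perfusion_metrics(ph_s$curves$seg_1, blood = ph_s$curves$blood)
  mr <- perfusion_metrics(ph_r$curves$seg_1, blood = ph_r$curves$blood)
  idx <- perfusion_reserve_index(ms, mr)
  expect_equal(idx$upslope_ratio, 2)
  expect_equal(perfusion_reserve_index(ms, ms)$upslope_ratio, 1)
  # zero rest upslope -> NA with warning
  mr0 <- mr; mr0$max_upslope <- 0
  z <- perfusion_reserve_index(ms, mr0)
  expect_true(is.na(z$upslope_ratio))
  expect_match(z$warnings, "zero")
  # normalization mismatch
  ms_raw <- perfusion_metrics(ph_s$curves$seg_1)
  expect_error(perfusion_reserve_index(ms, ms_raw), "mismatch")
})

test_that("extract_segment_curves: symmetry, layers, blood ROI fidelity", {
  grid <- 64; nfr <- 25; c0 <- 32
  xy <- pixel_xy(grid)
  r <- sqrt((xy$x - c0)^2 + (xy$y - c0)^2)
  inner <- matrix(r >= 10 & r < 15, grid, grid)
  blood_curve <- c(rep(40, 8), 40 + 20 * (1:17))
  vox <- array(rep(50, nfr * grid * grid), c(nfr, grid, grid))
  for (k in seq_len(nfr)) {
    fr <- matrix(50, grid, grid)
    fr[r < 8] <- blood_curve[k]
    vox[k, , ] <- fr
  }
  st <- image_stack(vox, c(1, 1), 8, frame_times = 0:(nfr - 1))
  m <- aha_model(c(c0, c0), c(c0, c0 - 12), c(c0 - 10.4, c0 + 6), "mid", 17)
  en <- circ(c0, c0, 10, "endo"); ep <- circ(c0, c0, 20, "epi")
  # uniform myocardium: all segment curves identical
  cur <- extract_segment_curves(st, en, ep, m, baseline_frames = 8,
                                blood_roi = circ(c0, c0, 6, "blood_pool"))
  for (s in 8:12)
    expect_equal(cur[[paste0("seg_", s)]]$values, cur$seg_7$values)
  # blood ROI reproduces the generator's input curve exactly (uniform pool)
  expect_equal(cur$blood$values, blood_curve)
  # enhancement confined to the inner half: endo layer rises, epi flat
  vox2 <- vox
  for (k in 9:nfr) {
    fr <- vox2[k, , ]
    fr[inner] <- 50 + 10 * (k - 8)
    vox2[k, , ] <- fr
  }
  st2 <- image_stack(vox2, c(1, 1), 8, frame_times = 0:(nfr - 1))
  cur2 <- extract_segment_curves(st2, en, ep, m, layers = "endo_epi",
                                 baseline_frames = 8)
  rise_endo <- max(cur2$seg_7_endo$values) - cur2$seg_7_endo$values[1]
  rise_epi <- max(cur2$seg_7_epi$values) - cur2$seg_7_epi$values[1]
  expect_gt(rise_endo, 100)
  expect_lt(rise_epi, 0.1 * rise_endo)
})
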
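# phase-contrast flow integration, derived indices, VENC handling, QC

# frames with one uniform-velocity phase over an ROI of exactly 5 pixels
# of 1 cm^2 each (pixel spacing 10 mm)
uniform_frames <- function(v_cm_s, venc = 200) {
  vel <- array(0, c(1, 4, 6))
  vel[1, 1, 1:5] <- v_cm_s
  velocity_frame_set(vel, venc = venc, frame_duration = 1,
                     pixel_spacing_mm = c(10, 10),
                     roi = rect(0, 0, 50, 10))
}

test_that("integrate_flow: rectangle integral and printed formulas", {
  r <- integrate_flow(uniform_frames(100))
  expect_equal(r$net_ml, 500)                 # 100 cm/s x 5 cm^2 x 1 s
  expect_equal(r$regurgitant_fraction_pct, 0)
  r2 <- integrate_flow(two_phase_frames(80, 20))
  expect_equal(r2$antegrade_ml, 80)
  expect_equal(r2$retrograde_ml, 20)
  expect_equal(r2$net_ml, 60)
  expect_equal(r2$regurgitant_fraction_pct, 25)
})

test_that("flow linearity, sign reversal and conservation identity", {
  f <- make_flow_field(phantom_spec("flow_field", reverse_frac = 0.3,
                                    seed = 2))
  r <- integrate_flow(f$frames)
  # reversing all velocities swaps antegrade and retrograde exactly
  neg <- f$frames; neg$velocity <- -neg$velocity
  rn <- integrate_flow(neg)
  expect_equal(rn$antegrade_ml, r$retrograde_ml)
  expect_equal(rn$retrograde_ml, r$antegrade_ml)
  # conservation: sum of flow_rate x dt = net at machine precision
  expect_equal(sum(r$flow_rate_ml_s) * f$frames$frame_duration, r$net_ml,
               tolerance = 1e-12)
  # linear in velocity
  dbl <- f$frames; dbl$velocity <- 2 * dbl$velocity
  expect_equal(integrate_flow(dbl)$net_ml, 2 * r$net_ml, tolerance = 1e-9)
})

test_that("parabolic phantom: net within 1% of the closed-form disc integral", {
  f <- make_flow_field(phantom_spec("flow_field"))
  r <- integrate_flow(f$frames)
  expect_equal(r$net_ml, f$truth$net_ml, tolerance = 0.01)
  f2 <- make_flow_field(phantom_spec("flow_field", reverse_frac = 0.25))
  r2 <- integrate_flow(f2$frames)
  expect_equal(r2$regurgitant_fraction_pct, f2$truth$rf_pct,
               tolerance = 0.01)
})

test_that("cardiac output/index, lung split, Qp/Qs arithmetic", {
  co <- cardiac_output_index(60, 70, 2.0)
  expect_equal(co$co, 4.2); expect_equal(co$ci, 2.1)
  expect_equal(cardiac_output_index(0, 70)$co, 0)
  expect_error(cardiac_output_index(60, 0), "positive")
  sp <- lung_flow_split(2, 1)
  expect_equal(sp$right_pct, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(lung_flow_split(3, 3)$right_pct, 50)
  z <- lung_flow_split(5, 0)
  expect_equal(z$right_pct, 100); expect_match(z$warnings, "no flow")
  expect_error(lung_flow_split(0, 0), "positive")
  expect_equal(qp_qs(6, 4), 1.5)
  expect_equal(qp_qs(4.2, 4.2), 1)
  expect_error(qp_qs(5, 0), "systemic")
})

test_that("valve regurgitation arithmetic and clipping", {
  a <- av_regurgitation("A_direct", semilunar_forward_ml = 80,
                        diastolic_av_inflow_ml = 100)
  expect_equal(a$regurgitant_ml, 20)
  b <- av_regurgitation("B_volumetric", semilunar_forward_ml = 90,
                        ventricular_sv_ml = 90)
  expect_equal(b$regurgitant_ml, 0)
  clip <- av_regurgitation("A_direct", semilunar_forward_ml = 100,
                           diastolic_av_inflow_ml = 90)
  expect_equal(clip$regurgitant_ml, 0)
  expect_match(clip$warnings, "clipped")
  expect_error(av_regurgitation("A_direct", semilunar_forward_ml = 80),
               "diastolic_av_inflow_ml")
  ao <- aortic_regurgitation_alternative(100, 80)
  expect_equal(ao$regurgitant_ml, 20)
  expect_match(ao$note, "bronchial")
  expect_match(aortic_regurgitation_alternative(70, 80)$warnings, "error")
})

test_that("recenter_venc: wrap recovery, identity, involution", {
  # 175 cm/s acquired at VENC 150 is stored wrapped at -125; moving the
  # window to (-100, 200) recovers it exactly
  vel <- array(0, c(1, 3, 3)); vel[1, 2, 2] <- -125
  fr <- velocity_frame_set(vel, venc = 150, frame_duration = 1,
                           pixel_spacing_mm = c(10, 10),
                           roi = rect(0, 0, 30, 30), aliased = TRUE)
  rec <- recenter_venc(fr, c(-100, 200))
  expect_equal(rec$velocity[1, 2, 2], 175)
  # in-window pixels are untouched
  expect_equal(rec$velocity[1, 1, 1], 0)
  # involution: shifting back to the symmetric window restores the input
  back <- recenter_venc(rec, c(-150, 150))
  expect_equal(back$velocity, fr$velocity)
  expect_error(recenter_venc(fr, c(-100, 100)), "width")
  # phantom round-trip: construct -> alias -> recenter -> integrate
  ph <- make_flow_field(phantom_spec("flow_field", v_max = 175, venc = 150,
                                     alias = TRUE))
  fixed <- recenter_venc(ph$frames, c(-100, 200))
  r <- integrate_flow(fixed)
  expect_equal(r$net_ml, ph$truth$net_ml, tolerance = 0.01)
  expect_equal(as.numeric(peak_velocity(fixed)), 175, tolerance = 0.03)
})

test_that("peak_velocity conventions and outlier robustness", {
  ph <- make_flow_field(phantom_spec("flow_field"))
  single <- peak_velocity(ph$frames, "single_pixel")
  expect_equal(as.numeric(single), 100, tolerance = 0.03)
  neigh <- peak_velocity(ph$frames, "k_neighborhood")
  expect_lte(as.numeric(neigh), as.numeric(single))
  expect_match(attr(neigh, "convention"), "k_neighborhood")
  # a single hot pixel inflates single_pixel but not the neighborhood mean
  hot <- ph$frames
  k_peak <- which.max(apply(hot$velocity, 1, max))
  fr <- hot$velocity[k_peak, , ]
  fr[16, 16] <- fr[16, 16] + 50       # near the vessel center
  hot$velocity[k_peak, , ] <- fr
  s2 <- as.numeric(peak_velocity(hot, "single_pixel"))
  n2 <- as.numeric(peak_velocity(hot, "k_neighborhood"))
  expect_gt(s2 - as.numeric(single), 30)
  expect_lt(n2 - as.numeric(neigh), 15)
})

test_that("flow_qc thresholds fire exactly at the declared boundaries", {
  expect_match(flow_qc(vessel_diameter_px = 6), "8-16")
  expect_length(flow_qc(vessel_diameter_px = 12, frames_per_cycle = 20,
                        mpa_ml = 100, rpa_ml = 55, lpa_ml = 45), 0)
  expect_match(flow_qc(frames_per_cycle = 10), "11-16")
  expect_length(flow_qc(frames_per_cycle = 11), 0)
  expect_length(flow_qc(mpa_ml = 100, rpa_ml = 55, lpa_ml = 40), 0)  # 5%
  expect_match(flow_qc(mpa_ml = 100, rpa_ml = 55, lpa_ml = 39), "branch")
})

test_that("velocity_frame_set contracts and phase-offset option", {
  vel <- array(0, c(2, 3, 3)); vel[1, , ] <- 250
  expect_error(velocity_frame_set(vel, venc = 200, frame_duration = 1,
                                  roi = rect(0, 0, 3, 3)), "alias")
  vel2 <- array(10, c(2, 4, 4))
  fr <- velocity_frame_set(vel2, venc = 200, frame_duration = 0.04,
                           pixel_spacing_mm = c(10, 10),
                           roi = rect(0, 0, 40, 40))
  expect_true(fr$roi_copied)
  expect_match(integrate_flow(fr)$qc, "copied", all = FALSE)
  corr <- subtract_phase_offset(fr, rect(0, 0, 40, 40))
  expect_equal(corr$phase_offset_cm_s, 10)
  expect_equal(max(abs(corr$velocity)), 0)
})
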
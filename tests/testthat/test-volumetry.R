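# Simpson volumetry, mass, area-length, global function, LV/RV consistency

cylinder_stack <- function(n_slices = 10, r = 20, thickness = 8, gap = 2,
                           phases = 1) {
  contours <- list()
  for (ph in seq_len(phases)) for (i in seq_len(n_slices))
    contours[[length(contours) + 1L]] <-
      list(slice = i, phase = ph, label = "endo",
           contour = circ(30, 30, r, "endo"))
  contour_stack(contours, list(pixel_spacing = c(1, 1),
                               slice_thickness = thickness, slice_gap = gap))
}

test_that("simpson_volume: cylinder closed form, inclusion flags, additivity", {
  st <- cylinder_stack()
  v <- simpson_volume(st, 1, "endo")
  expect_equal(v, 10 * pi * 400 * 10 / 1000, tolerance = 1e-3)  # 125.66 ml
  # dropping one slice removes exactly area x (thickness + gap)
  st2 <- cylinder_stack()
  st2$include_slice <- data.frame(slice = 4, phase = 1, include = FALSE)
  a4 <- polygon_area(st2$contours[[4]]$contour)
  expect_equal(v - simpson_volume(st2, 1, "endo"), a4 * 10 / 1000)
  # linear in (thickness + gap)
  st3 <- cylinder_stack(thickness = 4, gap = 1)
  expect_equal(simpson_volume(st3, 1, "endo"), v / 2)
  expect_error(simpson_volume(st, 2, "endo"), "no included slices")
})

test_that("papillary bookkeeping: volume and mass move by the papillary volume", {
  mk <- function(mode) {
    contours <- list()
    for (i in 1:6) {
      contours[[length(contours) + 1L]] <-
        list(slice = i, phase = 1, label = "endo",
             contour = circ(30, 30, 15, "endo"))
      contours[[length(contours) + 1L]] <-
        list(slice = i, phase = 1, label = "epi",
             contour = circ(30, 30, 22, "epi"))
      contours[[length(contours) + 1L]] <-
        list(slice = i, phase = 1, label = "papillary",
             contour = square_ctr(30, 30, 4, "papillary"))
    }
    contour_stack(contours, list(pixel_spacing = c(1, 1),
                                 slice_thickness = 8, slice_gap = 2),
                  papillary_mode = mode)
  }
  blood <- mk("in_blood_pool"); mass <- mk("in_mass")
  pap_ml <- 16 * 10 * 6 / 1000              # 4x4 square x dz x slices
  expect_equal(simpson_volume(blood, 1, "endo") -
                 simpson_volume(mass, 1, "endo"), pap_ml)
  expect_equal(lv_mass(mass, 1) - lv_mass(blood, 1), 1.05 * pap_ml)
})

test_that("lv_mass: density constant, epi-only slices, error guards", {
  # shell of exactly 1 ml via concentric squares: (6^2 - 4^2) x 10 x 5 slices
  contours <- list()
  for (i in 1:5) {
    contours[[length(contours) + 1L]] <-
      list(slice = i, phase = 1, label = "endo",
           contour = square_ctr(20, 20, 4, "endo"))
    contours[[length(contours) + 1L]] <-
      list(slice = i, phase = 1, label = "epi",
           contour = square_ctr(20, 20, 6, "epi"))
  }
  st <- contour_stack(contours, list(pixel_spacing = c(1, 1),
                                     slice_thickness = 8, slice_gap = 2))
  expect_equal(lv_mass(st, 1), 1.05)
  # apical epi-only slice contributes area x dz x density with no endo term
  extra <- c(contours, list(list(slice = 6, phase = 1, label = "epi",
                                 contour = square_ctr(20, 20, 6, "epi"))))
  st2 <- contour_stack(extra, st$geometry)
  expect_equal(lv_mass(st2, 1) - lv_mass(st, 1), 36 * 10 / 1000 * 1.05)
})

test_that("ED/ES phase selection: monotone stack, tie rule, phantom truth", {
  # monotone shrinking cylinder over 10 phases
  contours <- list()
  for (ph in 1:10)
    contours[[length(contours) + 1L]] <-
      list(slice = 1, phase = ph, label = "endo",
           contour = circ(30, 30, 21 - ph, "endo"))
  st <- contour_stack(contours, list(pixel_spacing = c(1, 1),
                                     slice_thickness = 8, slice_gap = 2))
  sel <- select_ed_es_phases(st)
  expect_identical(sel$ed_phase, 1L)
  expect_identical(sel$es_phase, 10L)
  # tie at the maximum resolves to the earlier phase
  tie <- contour_stack(list(
    list(slice = 1, phase = 1, label = "endo", contour = circ(30, 30, 20, "endo")),
    list(slice = 1, phase = 2, label = "endo", contour = circ(30, 30, 20, "endo")),
    list(slice = 1, phase = 3, label = "endo", contour = circ(30, 30, 10, "endo"))),
    list(pixel_spacing = c(1, 1), slice_thickness = 8, slice_gap = 2))
  expect_identical(select_ed_es_phases(tie)$ed_phase, 1L)
  # phantom with constructed ED/ES indices
  ph <- make_lv_phantom(phantom_spec("lv_ellipsoid", n_phases = 6))
  sel2 <- select_ed_es_phases(ph$stack)
  expect_identical(sel2$ed_phase, ph$truth$ed_phase)
  expect_identical(sel2$es_phase, as.integer(ph$truth$es_phase))
})

test_that("area_length_volume: printed formulas and method tags", {
  v1 <- area_length_volume(1, 1)
  expect_equal(as.numeric(v1), 0.85)
  expect_identical(attr(v1, "method"), "area_length_single")
  v2 <- area_length_volume(30, 8, area2 = 25)
  expect_equal(as.numeric(v2), 0.85 * 750 / 8)   # 79.6875 ml
  expect_identical(attr(v2, "method"), "area_length_biplane")
  expect_error(area_length_volume(-1, 1), "positive")
  # single-plane on a perfect prolate spheroid: within 0.5% of 4/3 pi a b^2
  a <- 4.5; b <- 2.6                              # cm
  est <- area_length_volume(pi * a * b, 2 * a)
  expect_equal(as.numeric(est), 4 / 3 * pi * a * b^2, tolerance = 5e-3)
})

test_that("derive_global_function arithmetic, indexing and contracts", {
  s <- subject(height = 180, weight = 80, heart_rate = 70)
  r <- derive_global_function(150, 60, s)
  expect_equal(r$sv, 90); expect_equal(r$ef, 60)
  expect_equal(r$co, 6.3)
  expect_equal(r$indexed$edv_i, 150 / r$bsa$value)
  expect_null(r$indexed$ef)                        # EF never indexed
  r2 <- derive_global_function(150, 60)
  expect_null(r2$co); expect_null(r2$indexed)
  expect_error(derive_global_function(0, 0), "EDV")
  expect_error(derive_global_function(100, 120), "EDV >= ESV")
})

test_that("EF is invariant under uniform contour scaling", {
  for (sc in c(0.5, 1, 1.7)) {
    ph <- make_lv_phantom(phantom_spec("lv_ellipsoid", a = 40 * sc,
                                       b = 25 * sc, wall = 10 * sc))
    expect_equal(lv_analysis(ph$stack)$ef, lv_analysis(
      make_lv_phantom(phantom_spec("lv_ellipsoid"))$stack)$ef,
      tolerance = 1e-6)
  }
})

test_that("RV volumes recover the crescent phantom and match LV SV", {
  rv <- make_rv_phantom(phantom_spec("rv_crescent"))
  r <- rv_volumes(rv$stack)
  expect_equal(r$edv, rv$truth$edv_ml, tolerance = 0.02)
  expect_equal(r$ef, rv$truth$ef_pct, tolerance = 0.01)
  expect_identical(r$method, "rv_simpson")
})

test_that("lv_rv_consistency thresholds", {
  mk <- function(sv) list(sv = sv)
  expect_identical(lv_rv_consistency(mk(90), mk(90))$verdict, "consistent")
  chk <- lv_rv_consistency(mk(90), mk(70))
  expect_identical(chk$verdict, "flag")
  expect_equal(chk$rel_diff_pct, 100 * 20 / 90, tolerance = 1e-9)
  expect_identical(lv_rv_consistency(mk(90), mk(70), tol_pct = 25)$verdict,
                   "consistent")
})

test_that("basal slice inclusion heuristic on constructed masks", {
  blood <- matrix(FALSE, 40, 40); blood[15:25, 15:25] <- TRUE
  full_ring <- matrix(FALSE, 40, 40); full_ring[13:27, 13:27] <- TRUE
  full_ring[15:25, 15:25] <- FALSE
  r1 <- basal_slice_inclusion(blood, full_ring)
  expect_true(r1$include)
  expect_equal(r1$fraction_surrounded, 1)
  # myocardium only along one edge: well under half the boundary
  partial <- matrix(FALSE, 40, 40); partial[13:14, 13:27] <- TRUE
  r2 <- basal_slice_inclusion(blood, partial)
  expect_false(r2$include)
  expect_lt(r2$fraction_surrounded, 0.5)
})
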
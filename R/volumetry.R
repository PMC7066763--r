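# Short-axis Simpson (summation-of-discs) volumetry, LV mass, area-length
# rapid methods, global function indices and the LV/RV stroke-volume
# consistency check.  Every slice contributes area x (thickness + gap),
# including the last slice: a literal reading of the standard mass formula,
# stated once here so reference ranges can be matched to the convention.

MYOCARDIUM_DENSITY_G_PER_ML <- 1.05

#' Select end-diastolic and end-systolic phases
#'
#' One global phase each, applied to all slice locations: end-diastole is
#' the phase with the largest summed endocardial slice volume, end-systole
#' the smallest.  Ties go to the earlier phase (determinism).
#'
#' @param stack a [contour_stack()].
#' @param label contour label to planimeter ("endo" for LV, "rv_endo" for RV).
#' @return list(ed_phase, es_phase, volumes_ml per phase).
#' @export
select_ed_es_phases <- function(stack, label = "endo") {
  phases <- stack_phases(stack)
  vols <- vapply(phases, function(ph) {
    v <- tryCatch(simpson_volume(stack, phase = ph, label = label),
                  error = function(e) NA_real_)
    v
  }, 1.0)
  if (all(is.na(vols))) stop("no phase has any included contours")
  ed <- phases[which.max(vols)]   # which.max/min return the first maximum
  es <- phases[which.min(vols)]
  list(ed_phase = ed, es_phase = es,
       volumes_ml = stats::setNames(vols, phases))
}

#' Simpson summation-of-discs volume
#'
#' Sum over included slices of planimetered area times (slice thickness +
#' interslice gap), converted to ml.  Under `papillary_mode = "in_mass"`
#' papillary polygon areas on a slice are subtracted from the endocardial
#' (blood) area; under `"in_blood_pool"` (default) they stay with the
#' cavity.
#'
#' @param stack a [contour_stack()].
#' @param phase 1-based phase index.
#' @param label contour label to integrate ("endo", "epi", "rv_endo").
#' @return volume in ml.
#' @export
simpson_volume <- function(stack, phase, label = "endo") {
  g <- stack$geometry
  dz <- g$slice_thickness + g$slice_gap
  total_mm3 <- 0
  any_slice <- FALSE
  for (sl in stack_slices(stack)) {
    if (!slice_included(stack, sl, phase)) next
    cnt <- stack_get(stack, sl, phase, label)
    if (is.null(cnt)) next
    a <- polygon_area(cnt)
    if (label == "endo" && stack$papillary_mode == "in_mass") {
      paps <- stack_get_all(stack, sl, phase, "papillary")
      for (pp in paps) a <- a - polygon_area(pp)
      if (a < 0) stop(sprintf("slice %d: papillary area exceeds cavity", sl))
    }
    total_mm3 <- total_mm3 + a * dz
    any_slice <- TRUE
  }
  if (!any_slice) stop(sprintf("no included slices carry label '%s' at phase %d",
                               label, phase))
  total_mm3 / 1000
}

#' Left-ventricular mass
#'
#' (Total epicardial volume - total endocardial volume) x 1.05 g/ml, the
#' specific density of myocardium.  Slices carrying an epicardial contour
#' without an endocardial one (basal crescent, apical cap) contribute
#' epicardial area only.  Under `papillary_mode = "in_mass"` papillary
#' areas move from blood pool to myocardium, increasing mass.
#'
#' @param stack a [contour_stack()].
#' @param phase 1-based phase index (mass is conventionally reported at
#'   end-diastole).
#' @return mass in g.
#' @export
lv_mass <- function(stack, phase) {
  g <- stack$geometry
  dz <- g$slice_thickness + g$slice_gap
  v_epi <- 0; v_endo <- 0
  any_slice <- FALSE
  for (sl in stack_slices(stack)) {
    if (!slice_included(stack, sl, phase)) next
    ep <- stack_get(stack, sl, phase, "epi")
    if (is.null(ep)) next
    v_epi <- v_epi + polygon_area(ep) * dz
    en <- stack_get(stack, sl, phase, "endo")
    if (!is.null(en)) {
      a <- polygon_area(en)
      if (stack$papillary_mode == "in_mass")
        for (pp in stack_get_all(stack, sl, phase, "papillary"))
          a <- a - polygon_area(pp)
      v_endo <- v_endo + a * dz
    }
    any_slice <- TRUE
  }
  if (!any_slice) stop("no included slices carry an epicardial contour")
  if (v_epi < v_endo) stop("epicardial volume below endocardial volume")
  (v_epi - v_endo) / 1000 * MYOCARDIUM_DENSITY_G_PER_ML
}

#' Area-length rapid volume estimate
#'
#' Single long-axis: V = 0.85 A^2 / L.  Biplane (4-chamber and 2-chamber
#' areas): V = 0.85 A1 A2 / L.  Areas in cm^2, length (mitral-annulus
#' midpoint to apex) in cm, result in ml.  The method name is attached so
#' reports can state the analysis technique.
#'
#' @param area1 planimetered LV area, cm^2.
#' @param length LV long-axis length, cm.
#' @param area2 optional second-plane area, cm^2 (biplane when given).
#' @return volume in ml with attribute `method`.
#' @export
area_length_volume <- function(area1, length, area2 = NULL) {
  if (area1 <= 0 || length <= 0 || (!is.null(area2) && area2 <= 0))
    stop("areas and length must be positive")
  if (is.null(area2)) {
    v <- 0.85 * area1^2 / length
    attr(v, "method") <- "area_length_single"
  } else {
    v <- 0.85 * area1 * area2 / length
    attr(v, "method") <- "area_length_biplane"
  }
  v
}

#' Derive global ventricular function
#'
#' Fills stroke volume (EDV - ESV), ejection fraction (100 SV/EDV),
#' cardiac output (SV x HR / 1000) and BSA-indexed variants of everything
#' except EF (a ratio, never indexed).
#'
#' @param edv,esv end-diastolic and end-systolic volumes, ml.
#' @param subj optional [subject()] supplying heart rate and BSA inputs.
#' @param mass_ed optional LV mass, g.
#' @param method analysis-technique tag echoed in the result.
#' @param papillary_mode convention tag echoed in the result.
#' @param phases optional c(ed_phase, es_phase).
#' @return object of class `ventricular_result`.
#' @export
derive_global_function <- function(edv, esv, subj = NULL, mass_ed = NULL,
                                   method = "short_axis_simpson",
                                   papillary_mode = "in_blood_pool",
                                   phases = NULL) {
  if (edv <= 0) stop("EDV must be positive")
  if (esv < 0 || esv > edv) stop("need EDV >= ESV >= 0")
  sv <- edv - esv
  ef <- 100 * sv / edv
  co <- NULL; indexed <- NULL; bsa <- NULL
  if (!is.null(subj)) {
    if (!is.null(subj$heart_rate)) co <- sv * subj$heart_rate / 1000
    if (!is.null(subj$height) && !is.null(subj$weight)) {
      b <- body_surface_area(subj)
      bsa <- list(value = as.numeric(b), formula = attr(b, "formula"))
      indexed <- list(edv_i = edv / bsa$value, esv_i = esv / bsa$value,
                      sv_i = sv / bsa$value)
      if (!is.null(co)) indexed$ci <- co / bsa$value
      if (!is.null(mass_ed)) indexed$mass_i <- mass_ed / bsa$value
    }
  }
  structure(list(edv = edv, esv = esv, sv = sv, ef = ef, co = co,
                 mass_ed = mass_ed, indexed = indexed, bsa = bsa,
                 method = method, papillary_mode = papillary_mode,
                 phases = phases),
            class = "ventricular_result")
}

#' @export
print.ventricular_result <- function(x, ...) {
  cat(sprintf("<ventricular_result> %s (papillary: %s)\n",
              x$method, x$papillary_mode))
  cat(sprintf("  EDV %.1f ml | ESV %.1f ml | SV %.1f ml | EF %.1f %%\n",
              x$edv, x$esv, x$sv, x$ef))
  if (!is.null(x$co)) cat(sprintf("  CO %.2f L/min\n", x$co))
  if (!is.null(x$mass_ed)) cat(sprintf("  mass %.1f g\n", x$mass_ed))
  invisible(x)
}

#' Full LV analysis of a contour stack
#'
#' Convenience wrapper: ED/ES phase selection, Simpson volumes, mass at ED,
#' global function.
#'
#' @param stack a [contour_stack()].
#' @param subj optional [subject()].
#' @return a `ventricular_result`.
#' @export
lv_analysis <- function(stack, subj = NULL) {
  ph <- select_ed_es_phases(stack, "endo")
  edv <- simpson_volume(stack, ph$ed_phase, "endo")
  esv <- simpson_volume(stack, ph$es_phase, "endo")
  mass <- tryCatch(lv_mass(stack, ph$ed_phase), error = function(e) NULL)
  derive_global_function(edv, esv, subj, mass_ed = mass,
                         papillary_mode = stack$papillary_mode,
                         phases = c(ph$ed_phase, ph$es_phase))
}

#' Right-ventricular volumes
#'
#' Same Simpson summation on RV endocardial contours; trabeculae and
#' papillary muscles are included in the volume (no subtraction) and no
#' mass is computed by default.
#'
#' @param stack a [contour_stack()] carrying `rv_endo` contours.
#' @param subj optional [subject()].
#' @param orientation "short_axis" or "axial", recorded in the result.
#' @return a `ventricular_result` with method `rv_simpson`.
#' @export
rv_volumes <- function(stack, subj = NULL, orientation = "short_axis") {
  ph <- select_ed_es_phases(stack, "rv_endo")
  edv <- simpson_volume(stack, ph$ed_phase, "rv_endo")
  esv <- simpson_volume(stack, ph$es_phase, "rv_endo")
  res <- derive_global_function(edv, esv, subj, method = "rv_simpson",
                                papillary_mode = "in_blood_pool",
                                phases = c(ph$ed_phase, ph$es_phase))
  res$orientation <- orientation
  res
}

#' LV/RV stroke-volume consistency check
#'
#' Absent shunts or valvular regurgitation the two stroke volumes should be
#' nearly equal; the relative difference 100 |SV_lv - SV_rv| / SV_lv is
#' compared against a tolerance (default 10%, a declared choice; published
#' guidance says only "nearly equal").
#'
#' @param lv,rv `ventricular_result` objects (or lists with `$sv`).
#' @param tol_pct tolerance in percent.
#' @return list(verdict = "consistent"|"flag", rel_diff_pct, tol_pct).
#' @export
lv_rv_consistency <- function(lv, rv, tol_pct = 10) {
  if (is.null(lv$sv) || is.null(rv$sv)) stop("both stroke volumes required")
  rel <- 100 * abs(lv$sv - rv$sv) / lv$sv
  list(verdict = if (rel <= tol_pct) "consistent" else "flag",
       rel_diff_pct = rel, tol_pct = tol_pct)
}

#' Basal-slice inclusion heuristic
#'
#' Helper implementing the "at least 50% of the blood volume surrounded by
#' myocardium" convention on binary masks: the fraction of blood-pool
#' boundary pixels whose outward 4-neighborhood touches myocardium.
#' Basal-slice handling has no single agreed convention, so this feeds the
#' explicit `include_slice` flags rather than being wired into the
#' integrals.
#'
#' @param blood_mask,myo_mask logical matrices on the same grid.
#' @param min_fraction inclusion cutoff (default 0.5).
#' @return list(include, fraction_surrounded).
#' @export
basal_slice_inclusion <- function(blood_mask, myo_mask, min_fraction = 0.5) {
  if (!any(blood_mask)) return(list(include = FALSE, fraction_surrounded = 0))
  nr <- nrow(blood_mask); nc <- ncol(blood_mask)
  pad <- function(m, dr, dc) {   # m shifted by (dr, dc), FALSE off-grid
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    out[rs + dr, cs + dc] <- m[rs, cs]
    out
  }
  nb_out <- (pad(!blood_mask, 1, 0) | pad(!blood_mask, -1, 0) |
               pad(!blood_mask, 0, 1) | pad(!blood_mask, 0, -1))
  boundary <- blood_mask & nb_out
  if (!any(boundary)) return(list(include = TRUE, fraction_surrounded = 1))
  nb_myo <- (pad(myo_mask, 1, 0) | pad(myo_mask, -1, 0) |
               pad(myo_mask, 0, 1) | pad(myo_mask, 0, -1))
  frac <- sum(boundary & nb_myo) / sum(boundary)
  list(include = frac >= min_fraction, fraction_surrounded = frac)
}
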
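# Late gadolinium enhancement quantification: n-SD and FWHM thresholding,
# manual corrections (no-reflow inclusion, artifact/blood-pool exclusion),
# scar mass and fraction, and per-AHA-segment transmural extent.

#' n-SD scar threshold
#'
#' Threshold = remote mean + n x remote SD, with the remote reference taken
#' from a manually selected normal (dark) myocardial region.  The default
#' n = 5 is the recommended starting point for infarction.  The returned
#' mask is the automatic result before manual corrections.
#'
#' @param image numeric matrix (one LGE frame).
#' @param myo_mask logical myocardial mask.
#' @param remote_roi [contour()] (mm coordinates) or logical mask of the
#'   remote reference region; must lie within the myocardium.
#' @param n_sd threshold multiplier (default 5).
#' @param pixel_spacing mm per pixel c(row, col), used when `remote_roi`
#'   is a contour.
#' @return object of class `scar_result` (mask, threshold, method "n_sd",
#'   remote stats, warnings).
#' @export
nsd_threshold <- function(image, myo_mask, remote_roi, n_sd = 5,
                          pixel_spacing = c(1, 1)) {
  rm_mask <- if (is.logical(remote_roi)) remote_roi else
    contour_to_mask(remote_roi, dim(image), pixel_spacing)
  rm_mask <- rm_mask & myo_mask
  if (!any(rm_mask)) stop("remote ROI contains no myocardial pixels")
  vals <- image[rm_mask]
  m <- mean(vals); s <- stats::sd(vals)
  if (!is.finite(s) || s <= 0)
    stop("remote ROI has zero intensity variation; cannot form a threshold")
  warnings <- character()
  if (m + n_sd * s >= max(image[myo_mask]))
    warnings <- c(warnings,
                  "remote ROI may overlap enhancement: threshold reaches the myocardial maximum")
  thr <- m + n_sd * s
  mask <- myo_mask & (image > thr)
  structure(list(scar_mask = mask, threshold = thr, method = "n_sd",
                 n_sd = n_sd, remote_mean = m, remote_sd = s,
                 no_reflow_included = FALSE, warnings = warnings),
            class = "scar_result")
}

#' Full-width-at-half-maximum scar threshold
#'
#' Threshold = half of the maximal signal within the operator-selected
#' bright-scar ROI (not the global myocardial maximum); scar = myocardial
#' pixels at or above the threshold.
#'
#' @inheritParams nsd_threshold
#' @param scar_max_roi [contour()] or logical mask containing the region of
#'   maximum enhancement.
#' @return a `scar_result` with method "fwhm".
#' @export
fwhm_threshold <- function(image, myo_mask, scar_max_roi,
                           pixel_spacing = c(1, 1)) {
  sm <- if (is.logical(scar_max_roi)) scar_max_roi else
    contour_to_mask(scar_max_roi, dim(image), pixel_spacing)
  sm <- sm & myo_mask
  if (!any(sm)) stop("scar-maximum ROI contains no myocardial pixels")
  thr <- 0.5 * max(image[sm])
  mask <- myo_mask & (image >= thr)
  structure(list(scar_mask = mask, threshold = thr, method = "fwhm",
                 no_reflow_included = FALSE, warnings = character()),
            class = "scar_result")
}

#' Apply manual corrections to a scar mask
#'
#' Union with "add" masks (typically hypointense no-reflow cores, which
#' count as infarct in acute MI) and removal of "remove" masks (artifact,
#' blood-pool spillover), always clipped to the myocardium.
#'
#' @param scar a `scar_result` or logical mask.
#' @param myo_mask logical myocardial mask (clip target).
#' @param add list of logical masks to include (no-reflow).
#' @param remove list of logical masks to exclude.
#' @return corrected `scar_result` (or mask, matching the input type) with
#'   `no_reflow_included = TRUE` when `add` is nonempty.
#' @export
apply_manual_corrections <- function(scar, myo_mask, add = list(),
                                     remove = list()) {
  mask <- if (inherits(scar, "scar_result")) scar$scar_mask else scar
  for (m in add) mask <- mask | m
  for (m in remove) mask <- mask & !m
  mask <- mask & myo_mask
  if (inherits(scar, "scar_result")) {
    scar$scar_mask <- mask
    scar$no_reflow_included <- scar$no_reflow_included || length(add) > 0
    scar
  } else mask
}

#' Scar mass and fraction of LV mass
#'
#' Total scar area x (slice thickness + interslice gap) x 1.05 g/ml, and
#' its percentage of total myocardial mass.
#'
#' @param scar a `scar_result` or logical mask.
#' @param geometry list with `pixel_spacing` (mm), `slice_thickness`,
#'   `slice_gap`.
#' @param lv_mass_g total LV mass in g.
#' @param myo_mask optional myocardial mask; scar pixels outside it are an
#'   upstream invariant violation and raise an error.
#' @return list(scar_mass_g, scar_fraction_pct) merged into the
#'   `scar_result` when one was given.
#' @export
scar_mass_and_fraction <- function(scar, geometry, lv_mass_g,
                                   myo_mask = NULL) {
  mask <- if (inherits(scar, "scar_result")) scar$scar_mask else scar
  if (lv_mass_g <= 0) stop("lv_mass_g must be positive")
  if (!is.null(myo_mask) && any(mask & !myo_mask))
    stop("scar mask extends outside the myocardium")
  px_area <- prod(geometry$pixel_spacing)
  dz <- geometry$slice_thickness + geometry$slice_gap
  mass <- sum(mask) * px_area * dz / 1000 * MYOCARDIUM_DENSITY_G_PER_ML
  frac <- 100 * mass / lv_mass_g
  out <- list(scar_mass_g = mass, scar_fraction_pct = frac)
  if (inherits(scar, "scar_result")) {
    scar[names(out)] <- out
    scar
  } else out
}

TRANSMURALITY_LEVELS <- c("0%", "1-25%", "26-50%", "51-75%", "76-100%")

transmurality_category <- function(pct) {
  cut(pct, breaks = c(-Inf, 0, 25, 50, 75, Inf),
      labels = TRANSMURALITY_LEVELS, right = TRUE)
}

#' Per-segment transmural extent of enhancement
#'
#' Radial chords are cast from the LV centroid at 1-degree steps; per
#' chord, transmurality = enhanced chord length / wall chord length
#' (sampled at quarter-pixel resolution).  The segment value is the mean
#' over the chords in its sector, reported in the five standard categories
#' 0%, 1-25%, 26-50%, 51-75%, 76-100% (intervals closed on the right, so a
#' depth of exactly 25% falls in "1-25%").
#'
#' @param scar a `scar_result` or logical mask.
#' @param myo_mask logical myocardial mask on the same grid.
#' @param model an [aha_model()]; the scene is treated as the slice given
#'   by `slice_index`.
#' @param slice_index 1-based index into `model$slice_tier` (default 1).
#' @param pixel_spacing mm per pixel (isotropic grids only need c(1, 1)).
#' @return named list: per-segment mean transmurality percent and category;
#'   segments without myocardial chords are reported NA with a warning.
#' @export
transmural_extent <- function(scar, myo_mask, model, slice_index = 1,
                              pixel_spacing = c(1, 1)) {
  mask <- if (inherits(scar, "scar_result")) scar$scar_mask else scar
  nr <- nrow(myo_mask); nc <- ncol(myo_mask)
  cx <- model$lv_centroid[1]; cy <- model$lv_centroid[2]
  r_max <- sqrt((nr * pixel_spacing[1])^2 + (nc * pixel_spacing[2])^2)
  step <- 0.25 * min(pixel_spacing)
  rs <- seq(step / 2, r_max, by = step)
  tier <- model$slice_tier[slice_index]
  seg_ids <- switch(tier, basal = 1:6, mid = 7:12, apical = 13:16,
                    stop("transmurality undefined for the apex tier"))
  acc <- stats::setNames(vector("list", length(seg_ids)), seg_ids)
  for (deg in seq(0.5, 359.5, by = 1)) {
    th <- deg * pi / 180
    px <- cx + rs * cos(th); py <- cy + rs * sin(th)
    ii <- ceiling(py / pixel_spacing[1]); jj <- ceiling(px / pixel_spacing[2])
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    idx <- cbind(ii[ok], jj[ok])
    in_myo <- myo_mask[idx]
    if (!any(in_myo)) next
    in_scar <- mask[idx] & in_myo
    tm <- 100 * sum(in_scar) / sum(in_myo)
    seg <- assign_aha_segment(c(cx + cos(th), cy + sin(th)), slice_index, model)
    key <- as.character(seg)
    acc[[key]] <- c(acc[[key]], tm)
  }
  out <- lapply(seq_along(seg_ids), function(k) {
    v <- acc[[as.character(seg_ids[k])]]
    if (is.null(v))
      return(list(segment = seg_ids[k], mean_pct = NA_real_,
                  category = NA_character_,
                  warning = "no myocardial chords in segment"))
    m <- mean(v)
    list(segment = seg_ids[k], mean_pct = m,
         category = as.character(transmurality_category(m)))
  })
  stats::setNames(out, paste0("segment_", seg_ids))
}
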
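# Parametric-map analysis: T1/T2 ROI values with Z-scores and normal
# ranges, extracellular volume fraction, T2* mono-exponential fitting with
# late-echo truncation, and T2-weighted edema signal-intensity ratios.

#' Reference range for a mapping parameter
#'
#' Site-specific normal data; the normal range is mean +/- 2 SD.
#'
#' @param mean,sd normal mean and SD (ms).
#' @param sequence,field_strength,contrast optional provenance strings
#'   quoted in reports.
#' @return list of class `map_reference` with a `range` element.
#' @export
map_reference <- function(mean, sd, sequence = NULL, field_strength = NULL,
                          contrast = NULL) {
  if (sd <= 0) stop("reference sd must be positive")
  structure(list(mean = mean, sd = sd, range = c(mean - 2 * sd, mean + 2 * sd),
                 sequence = sequence, field_strength = field_strength,
                 contrast = contrast),
            class = "map_reference")
}

#' ROI value on a parametric map
#'
#' ROI mean/SD (conservative septal ROI by convention), optionally after
#' excluding pixels flagged by an LGE-based focal-fibrosis mask; attaches
#' the Z-score and normal range when a reference is supplied.  Small ROIs
#' (< 20 pixels) are flagged.
#'
#' @param map_frame numeric matrix or 2D [image_stack()] (values in ms).
#' @param roi [contour()] or logical mask.
#' @param reference optional [map_reference()].
#' @param lge_exclusion_mask optional logical mask of pixels to exclude.
#' @param pixel_spacing mm per pixel when `roi` is a contour.
#' @return object of class `map_result`: value, sd, z, reference, roi
#'   stats, warnings.
#' @export
map_roi_value <- function(map_frame, roi, reference = NULL,
                          lge_exclusion_mask = NULL,
                          pixel_spacing = c(1, 1)) {
  rs <- roi_stats(map_frame, roi, pixel_spacing = pixel_spacing,
                  exclude = lge_exclusion_mask)
  z <- if (is.null(reference)) NULL else
    z_score(rs$mean, reference$mean, reference$sd)
  structure(list(value = rs$mean, sd = rs$sd, z = z, reference = reference,
                 roi = rs, warnings = rs$warnings),
            class = "map_result")
}

#' Extracellular volume fraction
#'
#' ECV = (dR1_myo / dR1_blood) x (100 - hematocrit%), with
#' dR1 = 1/T1_post - 1/T1_native from pre- and post-contrast T1 maps.
#' Hematocrit is entered as a fraction and converted internally.
#'
#' @param t1_myo_native,t1_myo_post,t1_blood_native,t1_blood_post T1 in ms
#'   (any common time unit works: the ratio is unit free).
#' @param hematocrit fraction in (0, 1).
#' @return object of class `ecv_result` with `ecv` in percent.
#' @export
compute_ecv <- function(t1_myo_native, t1_myo_post,
                        t1_blood_native, t1_blood_post, hematocrit) {
  vals <- c(t1_myo_native, t1_myo_post, t1_blood_native, t1_blood_post)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all four T1 values must be positive")
  if (!is.finite(hematocrit) || hematocrit <= 0 || hematocrit >= 1)
    stop("hematocrit must be a fraction in (0, 1)")
  if (t1_myo_post >= t1_myo_native)
    stop("post-contrast myocardial T1 must be below native T1")
  if (t1_blood_post >= t1_blood_native)
    stop("post-contrast blood T1 must be below native T1")
  dr1_myo <- 1 / t1_myo_post - 1 / t1_myo_native
  dr1_blood <- 1 / t1_blood_post - 1 / t1_blood_native
  if (dr1_blood == 0) stop("blood dR1 is zero: ECV undefined")
  ecv <- dr1_myo / dr1_blood * (100 - 100 * hematocrit)
  structure(list(ecv = ecv,
                 inputs = list(t1_myo_native = t1_myo_native,
                               t1_myo_post = t1_myo_post,
                               t1_blood_native = t1_blood_native,
                               t1_blood_post = t1_blood_post,
                               hematocrit = hematocrit)),
            class = "ecv_result")
}

# 1.5 T clinical cutoffs; 3 T flagging is not recommended and requires an
# explicit override
T2STAR_NORMAL_MS <- 40
T2STAR_OVERLOAD_MS <- 20
T2STAR_HIGH_RISK_MS <- 10

t2star_flags <- function(t2star) {
  if (t2star < T2STAR_HIGH_RISK_MS) c("iron_overload", "high_risk")
  else if (t2star < T2STAR_OVERLOAD_MS) "iron_overload"
  else "normal"
}

# log-linear initialisation + Gauss-Newton refinement of S0 exp(-TE/T2*)
fit_monoexp <- function(te, si) {
  pos <- si > 0
  init <- if (sum(pos) >= 2) {
    co <- stats::coef(stats::lm(log(si[pos]) ~ te[pos]))
    c(exp(co[1]), if (co[2] < 0) -1 / co[2] else max(te))
  } else c(max(si), max(te) / 2)
  init[2] <- min(max(init[2], 0.1), 10 * max(te))
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(si ~ s0 * exp(-te / t2s),
                 start = list(s0 = max(init[1], 1e-6), t2s = init[2]),
                 algorithm = "port",
                 lower = c(s0 = 1e-9, t2s = 1e-6),
                 control = stats::nls.control(maxiter = 500, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to the log-linear estimate
    pred <- init[1] * exp(-te / init[2])
    return(list(s0 = init[1], t2star = init[2],
                r2 = 1 - sum((si - pred)^2) / sum((si - mean(si))^2)))
  }
  co <- stats::coef(fit)
  pred <- co[["s0"]] * exp(-te / co[["t2s"]])
  list(s0 = co[["s0"]], t2star = co[["t2s"]],
       r2 = 1 - sum((si - pred)^2) / sum((si - mean(si))^2))
}

#' T2* mono-exponential fit with late-echo truncation
#'
#' Fits S(TE) = S0 exp(-TE/T2*) to the ROI decay curve (log-linear start,
#' nonlinear least squares).  With `truncation = "auto"` the latest echo is
#' iteratively dropped while at least 3 points remain and either (a) the
#' drop improves R^2 by more than `epsilon` or (b) the dropped sample lies
#' at or below the estimated noise floor -- the standard remedy for the
#' signal plateau that otherwise biases short T2* upward in iron overload.
#' Flags use the 1.5 T cutoffs: < 20 ms cardiac iron overload, < 10 ms
#' increased heart-failure risk; normal myocardium is about 40 ms.
#'
#' @param curve an [si_time_curve()] whose times are echo times in ms, or
#'   the output of [make_decay_series()].
#' @param noise_floor optional magnitude noise-floor estimate (SI units).
#' @param truncation "none" or "auto".
#' @param epsilon minimum R^2 improvement that justifies dropping an echo.
#' @param field_strength_t 1.5 by default; 3 T flagging is refused unless
#'   `allow_3t = TRUE` (and then carries a warning).
#' @param allow_3t explicit override for 3 T flagging.
#' @return object of class `t2star_fit`: s0, t2star, echoes_used,
#'   truncated_count, fit_r2, flags, reference_normal_ms, warnings.
#' @export
fit_t2star <- function(curve, noise_floor = NULL,
                       truncation = c("auto", "none"), epsilon = 1e-3,
                       field_strength_t = 1.5, allow_3t = FALSE) {
  truncation <- match.arg(truncation)
  if (is.list(curve) && !inherits(curve, "si_time_curve") &&
      !is.null(curve$curve)) curve <- curve$curve
  te <- curve$times; si <- curve$values
  if (length(te) < 4) stop("need at least 4 echoes")
  if (any(!is.finite(si))) stop("signal intensities must be finite")
  if (all(si <= 0)) stop("no positive signal to fit")
  n_total <- length(te)
  n <- n_total
  fit <- fit_monoexp(te[1:n], si[1:n])
  if (truncation == "auto") {
    repeat {
      if (n <= 3) break
      cand <- fit_monoexp(te[1:(n - 1)], si[1:(n - 1)])
      below_floor <- !is.null(noise_floor) && si[n] <= noise_floor
      if (cand$r2 - fit$r2 > epsilon || below_floor) {
        n <- n - 1L
        fit <- cand
      } else break
    }
  }
  if (n < 3) stop("fewer than 3 usable echoes after truncation")
  if (!is.finite(fit$t2star) || fit$t2star <= 0)
    stop("fit did not converge to a positive T2*")
  warnings <- character()
  flags <- if (field_strength_t >= 2.5 && !allow_3t) {
    warnings <- c(warnings,
                  "3 T iron-overload flagging is not recommended; set allow_3t = TRUE to force")
    character()
  } else {
    if (field_strength_t >= 2.5)
      warnings <- c(warnings, "3 T flagging forced by override: interpret with caution")
    t2star_flags(fit$t2star)
  }
  structure(list(s0 = fit$s0, t2star = fit$t2star,
                 echoes_used = te[1:n],
                 truncated_count = n_total - n,
                 fit_r2 = fit$r2, flags = flags,
                 reference_normal_ms = T2STAR_NORMAL_MS,
                 thresholds_ms = c(overload = T2STAR_OVERLOAD_MS,
                                   high_risk = T2STAR_HIGH_RISK_MS),
                 warnings = warnings),
            class = "t2star_fit")
}

#' @export
print.t2star_fit <- function(x, ...) {
  cat(sprintf("<t2star_fit> T2* = %.2f ms (S0 %.0f, R2 %.4f, %d echo(es) truncated)\n",
              x$t2star, x$s0, x$fit_r2, x$truncated_count))
  cat("  flags:", paste(x$flags, collapse = ", "),
      sprintf("| normal ~%g ms\n", x$reference_normal_ms))
  invisible(x)
}

#' T2-weighted edema signal-intensity ratio
#'
#' Myocardial ROI mean divided by skeletal-muscle ROI mean on dark-blood
#' T2-weighted images.  Edema-positive iff ratio >= `cutoff` (default 1.9,
#' the triple-inversion-recovery spin-echo value; a locally established
#' cutoff is preferable).  The optional parametric map marks pixels whose
#' pixelwise ratio to the skeletal-muscle mean is >= `map_cutoff`
#' (default 2) -- the two cutoffs are deliberately separate.
#'
#' @param image numeric matrix (T2-weighted frame).
#' @param myo_roi,skeletal_roi [contour()]s or logical masks.
#' @param cutoff ROI-ratio positivity cutoff.
#' @param map_cutoff pixel-map cutoff.
#' @param make_map also return the logical ratio >= map_cutoff map.
#' @param pixel_spacing mm per pixel for contour ROIs.
#' @return list(ratio, edema_positive, cutoff, myo, muscle, ratio_map).
#' @export
t2w_si_ratio <- function(image, myo_roi, skeletal_roi, cutoff = 1.9,
                         map_cutoff = 2, make_map = FALSE,
                         pixel_spacing = c(1, 1)) {
  myo <- roi_stats(image, myo_roi, pixel_spacing = pixel_spacing)
  mus <- roi_stats(image, skeletal_roi, pixel_spacing = pixel_spacing)
  if (mus$mean <= 0) stop("skeletal-muscle ROI mean must be positive")
  ratio <- myo$mean / mus$mean
  rmap <- NULL
  if (make_map) {
    myo_mask <- if (is.logical(myo_roi)) myo_roi else
      contour_to_mask(myo_roi, dim(image), pixel_spacing)
    rmap <- myo_mask & (image / mus$mean >= map_cutoff)
  }
  list(ratio = ratio, edema_positive = ratio >= cutoff, cutoff = cutoff,
       myo = myo, muscle = mus, ratio_map = rmap, map_cutoff = map_cutoff)
}
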
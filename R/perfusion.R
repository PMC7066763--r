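# Semi-quantitative first-pass perfusion: segmental SI/time curve
# extraction and the standard curve metrics (maximal upslope, time to peak,
# upslope integral) with stress/rest reserve ratios.  One sample per RR
# interval is assumed; curves with missing frames are rejected rather than
# interpolated.

#' Signal-intensity/time curve
#'
#' @param times sample times in seconds, strictly increasing (one per RR).
#' @param values signal intensities.
#' @param label segment id / "blood_pool" / layer tag.
#' @param baseline_frames number of declared pre-contrast frames.
#' @return object of class `si_time_curve`.
#' @export
si_time_curve <- function(times, values, label = "roi",
                          baseline_frames = 5L) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("times/values length mismatch")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (baseline_frames > 0 && length(times) < baseline_frames + 3)
    stop("curve must extend at least 3 frames past the baseline")
  structure(list(times = times, values = values, label = label,
                 baseline_frames = as.integer(baseline_frames)),
            class = "si_time_curve")
}

#' Extract per-segment SI/time curves from a dynamic series
#'
#' Pixels between the endocardial and epicardial contours are assigned to
#' AHA sectors (and optionally to endocardial/epicardial half-wall layers,
#' split at the mid-wall radius); each curve is the per-frame mean SI of
#' its pixel set.  A blood-pool curve is added when `blood_roi` is given
#' (the caller is responsible for excluding papillary muscles from it).
#'
#' @param series an [image_stack()] with 3D voxels (frame, row, col) and
#'   `frame_times`.
#' @param endo,epi [contour()]s on the reference frame (static or
#'   motion-corrected series assumed).
#' @param model an [aha_model()]; `slice_index` selects the tier.
#' @param layers "none" or "endo_epi".
#' @param blood_roi optional [contour()] for the LV blood pool.
#' @param slice_index 1-based index into `model$slice_tier`.
#' @param baseline_frames declared pre-contrast frame count.
#' @return named list of [si_time_curve()] (`seg_<id>`, `seg_<id>_endo`/
#'   `_epi` with layers, `blood`).
#' @export
extract_segment_curves <- function(series, endo, epi, model,
                                   layers = c("none", "endo_epi"),
                                   blood_roi = NULL, slice_index = 1,
                                   baseline_frames = 5L) {
  layers <- match.arg(layers)
  v <- series$voxels
  if (length(dim(v)) != 3) stop("series must be (frame, row, col)")
  nfr <- dim(v)[1]; nr <- dim(v)[2]; nc <- dim(v)[3]
  sp <- series$pixel_spacing
  times <- series$frame_times %||% (seq_len(nfr) - 1)
  ctr <- pixel_centers(nr, nc, sp)
  in_myo <- points_in_polygon(ctr$x, ctr$y, epi) &
    !points_in_polygon(ctr$x, ctr$y, endo)
  if (!any(in_myo)) stop("no myocardial pixels between the contours")
  idx <- which(in_myo)
  segs <- vapply(idx, function(k)
    assign_aha_segment(c(ctr$x[k], ctr$y[k]), slice_index, model), 1L)
  # half-wall split at the mid radius along each pixel's ray
  layer_tag <- rep("", length(idx))
  if (layers == "endo_epi") {
    cxy <- model$lv_centroid
    r_px <- sqrt((ctr$x[idx] - cxy[1])^2 + (ctr$y[idx] - cxy[2])^2)
    th <- atan2(ctr$y[idx] - cxy[2], ctr$x[idx] - cxy[1])
    r_mid <- vapply(seq_along(idx), function(k) {
      rr <- seq(0.25, max(r_px) + 2, by = 0.25)
      px <- cxy[1] + rr * cos(th[k]); py <- cxy[2] + rr * sin(th[k])
      ii <- ceiling(py / sp[1]); jj <- ceiling(px / sp[2])
      ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
      hit <- rr[ok][in_myo[(jj[ok] - 1) * nr + ii[ok]]]
      if (!length(hit)) r_px[k] else (min(hit) + max(hit)) / 2
    }, 1.0)
    layer_tag <- ifelse(r_px <= r_mid, "_endo", "_epi")
  }
  flat <- matrix(v, nfr, nr * nc)
  out <- list()
  for (s in sort(unique(segs))) for (lt in unique(layer_tag[segs == s])) {
    sel <- idx[segs == s & layer_tag == lt]
    if (!length(sel)) stop(sprintf("segment %d has zero pixels", s))
    out[[paste0("seg_", s, lt)]] <-
      si_time_curve(times, rowMeans(flat[, sel, drop = FALSE]),
                    label = paste0("seg_", s, lt),
                    baseline_frames = baseline_frames)
  }
  if (!is.null(blood_roi)) {
    bl <- which(points_in_polygon(ctr$x, ctr$y, blood_roi))
    if (!length(bl)) stop("blood ROI contains no pixels")
    out$blood <- si_time_curve(times, rowMeans(flat[, bl, drop = FALSE]),
                               label = "blood_pool",
                               baseline_frames = baseline_frames)
  }
  out
}

#' Baseline statistics and contrast-arrival foot
#'
#' Baseline = mean/SD of the declared pre-contrast frames; the foot is the
#' first frame exceeding baseline mean + 2 SD and sustained for two
#' consecutive frames (a declared detector; the clinical literature names
#' the metric but no arrival estimator).
#'
#' @param curve an [si_time_curve()] with >= 5 baseline frames.
#' @return list(baseline_mean, baseline_sd, foot_index, foot_time).
#' @export
detect_foot_and_baseline <- function(curve) {
  nb <- curve$baseline_frames
  if (nb < 5) stop("need at least 5 pre-contrast frames")
  base <- curve$values[seq_len(nb)]
  bm <- mean(base); bs <- stats::sd(base)
  thr <- bm + 2 * bs
  v <- curve$values
  n <- length(v)
  foot <- NA_integer_
  for (i in (nb + 1L):(n - 1L)) {
    if (v[i] > thr && v[i + 1L] > thr) { foot <- i; break }
  }
  if (is.na(foot)) stop("no contrast arrival: no frame exceeds baseline + 2 SD")
  list(baseline_mean = bm, baseline_sd = bs, foot_index = foot,
       foot_time = curve$times[foot])
}

peak_index <- function(curve, foot) {
  v <- curve$values
  foot - 1L + which.max(v[foot:length(v)])   # earliest maximum on ties
}

#' Maximal upslope of an SI/time curve
#'
#' Maximum over the foot-to-peak interval of the least-squares slope in a
#' sliding window (default 3 samples).  With `normalize_to` (the LV
#' blood-pool curve) the result is divided by the blood upslope computed
#' identically, giving the dimensionless normalized upslope; the flag is
#' recorded in the attribute `normalized`.
#'
#' @param curve an [si_time_curve()].
#' @param window sliding-window length in samples (>= 2).
#' @param normalize_to optional blood-pool [si_time_curve()].
#' @return slope in SI/s (or dimensionless), attributes `normalized`,
#'   `window`.
#' @export
max_upslope <- function(curve, window = 3L, normalize_to = NULL) {
  if (window < 2) stop("window must span at least 2 samples")
  fb <- detect_foot_and_baseline(curve)
  pk <- peak_index(curve, fb$foot_index)
  lo <- fb$foot_index
  if (pk <= fb$foot_index) stop("peak coincides with the foot")
  if (pk - lo + 1L < window) stop("window longer than the foot-to-peak rise")
  slopes <- vapply(lo:(pk - window + 1L), function(i) {
    tt <- curve$times[i:(i + window - 1L)]
    vv <- curve$values[i:(i + window - 1L)]
    sum((tt - mean(tt)) * (vv - mean(vv))) / sum((tt - mean(tt))^2)
  }, 1.0)
  out <- max(slopes)
  normalized <- FALSE
  if (!is.null(normalize_to)) {
    blood <- max_upslope(normalize_to, window = window)
    out <- out / as.numeric(blood)
    normalized <- TRUE
  }
  attr(out, "normalized") <- normalized
  attr(out, "window") <- as.integer(window)
  out
}

#' Time to peak signal intensity
#'
#' Time of the global maximum minus the contrast-arrival (foot) time; ties
#' resolve to the earliest maximum.  Referenced to contrast arrival, not
#' series start (recorded in the attribute `reference`).
#'
#' @param curve an [si_time_curve()].
#' @return seconds; attribute `warnings` flags a peak on the last frame.
#' @export
time_to_peak <- function(curve) {
  fb <- detect_foot_and_baseline(curve)
  pk <- peak_index(curve, fb$foot_index)
  if (pk == fb$foot_index && all(diff(curve$values[pk:length(curve$values)]) <= 0))
    stop("curve decreases monotonically after the foot")
  out <- curve$times[pk] - fb$foot_time
  attr(out, "reference") <- "contrast_arrival"
  if (pk == length(curve$values))
    attr(out, "warnings") <- "peak on the last frame: may be truncated"
  out
}

#' Upslope integral (area under the SI/time curve, foot to peak)
#'
#' Trapezoidal area of the baseline-subtracted curve between the foot and
#' the peak.
#'
#' @param curve an [si_time_curve()].
#' @return SI.s; a negative area is reported with a warning attribute.
#' @export
upslope_integral <- function(curve) {
  fb <- detect_foot_and_baseline(curve)
  pk <- peak_index(curve, fb$foot_index)
  if (fb$foot_index >= pk) stop("foot must precede the peak")
  # anchor at the frame before the first suprathreshold sample: the curve
  # leaves baseline between the two, and dropping that sliver biases the
  # trapezoidal area low by a systematic ~2%
  i <- max(1L, fb$foot_index - 1L):pk
  y <- curve$values[i] - fb$baseline_mean
  tt <- curve$times[i]
  area <- sum(diff(tt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  if (area < 0) attr(area, "warnings") <- "curve below baseline: negative area"
  area
}

#' Perfusion metrics for one curve
#'
#' Bundles maximal upslope (raw and optionally normalized), time to peak
#' and upslope integral.
#'
#' @param curve an [si_time_curve()].
#' @param blood optional blood-pool curve for normalization.
#' @param window upslope window.
#' @return object of class `perfusion_metrics`.
#' @export
perfusion_metrics <- function(curve, blood = NULL, window = 3L) {
  up <- max_upslope(curve, window = window)
  upn <- if (!is.null(blood))
    max_upslope(curve, window = window, normalize_to = blood) else NULL
  structure(list(label = curve$label,
                 max_upslope = as.numeric(up),
                 max_upslope_normalized =
                   if (is.null(upn)) NULL else as.numeric(upn),
                 time_to_peak = as.numeric(time_to_peak(curve)),
                 upslope_integral = as.numeric(upslope_integral(curve)),
                 window = window),
            class = "perfusion_metrics")
}

#' Myocardial perfusion reserve index (stress/rest ratios)
#'
#' Elementwise stress/rest ratio of matching metrics; both sides must have
#' been computed with the same normalization.  Division by zero yields NA
#' with a warning entry.
#'
#' @param stress,rest `perfusion_metrics` for the same segment.
#' @return list of ratios (`mpri` = normalized-upslope ratio when
#'   available, else raw-upslope ratio) plus warnings.
#' @export
perfusion_reserve_index <- function(stress, rest) {
  if (is.null(stress$max_upslope_normalized) !=
      is.null(rest$max_upslope_normalized))
    stop("normalization mismatch between stress and rest metrics")
  warnings <- character()
  ratio <- function(a, b, what) {
    if (is.null(a) || is.null(b)) return(NULL)
    if (b == 0) {
      warnings <<- c(warnings, sprintf("%s: rest value is zero", what))
      return(NA_real_)
    }
    a / b
  }
  out <- list(
    upslope_ratio = ratio(stress$max_upslope, rest$max_upslope, "upslope"),
    mpri = if (!is.null(stress$max_upslope_normalized))
      ratio(stress$max_upslope_normalized, rest$max_upslope_normalized,
            "normalized upslope")
    else ratio(stress$max_upslope, rest$max_upslope, "upslope"),
    integral_ratio = ratio(stress$upslope_integral, rest$upslope_integral,
                           "upslope integral"))
  out$warnings <- warnings
  out
}
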
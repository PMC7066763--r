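# Synthetic phantoms with closed-form analytic ground truth.  Every truth
# value here is computed from geometry or calculus, never by the code under
# test.  Identical spec (including seed) gives bit-identical output.

#' Phantom specification
#'
#' @param kind one of lv_ellipsoid, rv_crescent, decay_series,
#'   perfusion_series, flow_field, lge_scene, map_scene, t2w_scene.
#' @param seed integer RNG seed (phantoms are deterministic given the spec).
#' @param ... kind-specific parameters; see the `make_*` generators for the
#'   defaults, which are the canonical test conditions.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind, seed = 1L, ...) {
  kind <- match.arg(kind, c("lv_ellipsoid", "rv_crescent", "decay_series",
                            "perfusion_series", "flow_field", "lge_scene",
                            "map_scene", "t2w_scene"))
  params <- list(...)
  bad <- vapply(params, function(p)
    is.numeric(p) && length(p) == 1 && !is.na(p) && p < 0, FALSE)
  structure(list(kind = kind, seed = as.integer(seed), params = params),
            class = "phantom_spec")
}

# regular polygon approximating a circle; 128 vertices keeps the
# polygon-vs-circle area deficit ~0.04%, far below test tolerances
circle_contour <- function(cx, cy, r, label = "roi", n = 128L) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  contour(cbind(cx + r * cos(th), cy + r * sin(th)), label = label,
          check_simple = FALSE)
}

ellipse_contour <- function(cx, cy, rx, ry, label = "roi", n = 128L) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  contour(cbind(cx + rx * cos(th), cy + ry * sin(th)), label = label,
          check_simple = FALSE)
}

#' Beating prolate-spheroid LV phantom
#'
#' Endocardium is a prolate spheroid with long semi-axis `a` and short
#' semi-axes `b` (mm); the epicardial contour on every slice is the
#' endocardial circle dilated by a uniform in-plane wall thickness `wall`.
#' The stack shrinks linearly from end-diastole (phase 1) to end-systole
#' (last phase) so that the true ejection fraction is exactly `ef`.
#'
#' Closed-form truths: EDV = 4/3 pi a b^2; shell volume
#' pi^2 a b wall + 2 pi a wall^2 (in-plane dilation integrated along the
#' long axis); mass = shell volume x 1.05 g/ml.
#'
#' @param spec a [phantom_spec()] of kind `lv_ellipsoid`.  Parameters:
#'   `a` (default 40), `b` (25), `wall` (10) mm; `ef` (60, percent);
#'   `n_slices` (10), `n_phases` (2); `slice_thickness`/`slice_gap`
#'   default to an 80/20 split of the slice spacing.
#' @return list(stack = [contour_stack()], truth = list(edv_ml, esv_ml,
#'   ef_pct, mass_g, ed_phase, es_phase, ...)).
#' @export
make_lv_phantom <- function(spec) {
  p <- spec$params
  a <- p$a %||% 40; b <- p$b %||% 25; wall <- p$wall %||% 10
  ef <- p$ef %||% 60; n_slices <- p$n_slices %||% 10L
  n_phases <- p$n_phases %||% 2L
  if (n_slices < 5) stop("need at least 5 slices to cover the spheroid")
  if (a <= 0 || b <= 0 || wall <= 0) stop("semi-axes and wall must be positive")
  # slice spacing covers exactly [-a, a]; midpoint positions
  d <- 2 * a / n_slices
  thickness <- p$slice_thickness %||% (0.8 * d)
  gap <- d - thickness
  if (gap < 0) stop("slice thickness exceeds the spacing implied by coverage")
  z <- -a + (seq_len(n_slices) - 0.5) * d
  cx <- p$center %||% 60
  s_es <- (1 - ef / 100)^(1 / 3)    # uniform ES scale on the endo spheroid
  scales <- seq(1, s_es, length.out = n_phases)
  contours <- list()
  for (ph in seq_len(n_phases)) {
    s <- scales[ph]
    for (i in seq_len(n_slices)) {
      # endo radius at this slice for the scaled spheroid (axes s*a, s*b)
      u <- 1 - z[i]^2 / (s * a)^2
      r_en <- if (u > 0) s * b * sqrt(u) else 0
      u_ed <- 1 - z[i]^2 / a^2
      r_ed <- if (u_ed > 0) b * sqrt(u_ed) else 0
      if (r_en > 0.5)
        contours[[length(contours) + 1L]] <-
          list(slice = i, phase = ph, label = "endo",
               contour = circle_contour(cx, cx, r_en, "endo"))
      # epicardium fixed at its ED geometry (wall thickens in systole)
      if (r_ed > 0)
        contours[[length(contours) + 1L]] <-
          list(slice = i, phase = ph, label = "epi",
               contour = circle_contour(cx, cx, r_ed + wall, "epi"))
    }
  }
  geom <- list(pixel_spacing = c(1, 1), slice_thickness = thickness,
               slice_gap = gap)
  st <- contour_stack(contours, geom)
  edv <- 4 / 3 * pi * a * b^2 / 1000
  esv <- edv * (1 - ef / 100)
  shell_ml <- (pi^2 * a * b * wall + 2 * pi * a * wall^2) / 1000
  list(stack = st,
       truth = list(edv_ml = edv, esv_ml = esv, ef_pct = ef,
                    shell_ml = shell_ml, mass_g = shell_ml * 1.05,
                    ed_phase = 1L, es_phase = n_phases,
                    a = a, b = b, wall = wall, n_slices = n_slices))
}

# annular-sector ("crescent") cross-section polygon: outer arc forward,
# inner arc back; area = span/2 * (R^2 - r^2)
crescent_contour <- function(cx, cy, r_in, r_out, span_deg, label = "rv_endo",
                             n = 64L) {
  th <- seq(0, span_deg * pi / 180, length.out = n)
  pts <- rbind(cbind(cx + r_out * cos(th), cy + r_out * sin(th)),
               cbind(cx + r_in * cos(rev(th)), cy + r_in * sin(rev(th))))
  contour(pts, label = label, check_simple = FALSE)
}

#' Crescent right-ventricle phantom
#'
#' Cross-section is an annular sector (inner radius `r_in`, outer `r_out`,
#' angular span `span_deg`); the section is scaled along the long axis by
#' an ellipse factor sqrt(1 - z^2/L^2) and linearly contracted to
#' end-systole so EF is exact.  Truth volume: A0 * 4L/3 with
#' A0 = span/2 (r_out^2 - r_in^2).
#'
#' @param spec [phantom_spec()] of kind `rv_crescent`; parameters `r_in`
#'   (20), `r_out` (35) mm, `span_deg` (150), `L` (40) mm, `ef` (55),
#'   `n_slices` (10), `n_phases` (2).
#' @return list(stack, truth).
#' @export
make_rv_phantom <- function(spec) {
  p <- spec$params
  r_in <- p$r_in %||% 20; r_out <- p$r_out %||% 35
  span <- p$span_deg %||% 150; L <- p$L %||% 40
  ef <- p$ef %||% 55; n_slices <- p$n_slices %||% 10L
  n_phases <- p$n_phases %||% 2L
  if (n_slices < 5) stop("need at least 5 slices")
  d <- 2 * L / n_slices
  thickness <- 0.8 * d; gap <- d - thickness
  z <- -L + (seq_len(n_slices) - 0.5) * d
  s_es <- (1 - ef / 100)^(1 / 3)
  scales <- seq(1, s_es, length.out = n_phases)
  cx <- 60
  contours <- list()
  for (ph in seq_len(n_phases)) {
    s <- scales[ph]
    for (i in seq_len(n_slices)) {
      u <- 1 - z[i]^2 / (s * L)^2
      if (u <= 0) next
      f <- s * sqrt(u)     # in-plane scale of the section
      contours[[length(contours) + 1L]] <-
        list(slice = i, phase = ph, label = "rv_endo",
             contour = crescent_contour(cx, cx, f * r_in, f * r_out, span))
    }
  }
  geom <- list(pixel_spacing = c(1, 1), slice_thickness = thickness,
               slice_gap = gap)
  A0 <- (span * pi / 180) / 2 * (r_out^2 - r_in^2)
  edv <- A0 * 4 * L / 3 / 1000
  list(stack = contour_stack(contours, geom),
       truth = list(edv_ml = edv, esv_ml = edv * (1 - ef / 100),
                    ef_pct = ef, ed_phase = 1L, es_phase = n_phases))
}

#' Mono-exponential decay series (T2* phantom)
#'
#' S(TE) = S0 exp(-TE/T2*), optionally clipped from below at a noise floor
#' (magnitude-image plateau proxy) before additive gaussian noise.
#'
#' @param spec [phantom_spec()] of kind `decay_series`; parameters `s0`
#'   (1000), `t2star` (20 ms), `te` (default seq(2, 36, by 2) ms),
#'   `noise_sd` (0), `floor` (0).
#' @return list(curve = [si_time_curve()] over TE in ms,
#'   truth = list(s0, t2star, floor)).
#' @export
make_decay_series <- function(spec) {
  p <- spec$params
  s0 <- p$s0 %||% 1000; t2star <- p$t2star %||% 20
  te <- p$te %||% seq(2, 36, by = 2)
  noise_sd <- p$noise_sd %||% 0; floor_ <- p$floor %||% 0
  if (t2star <= 0) stop("T2* must be positive")
  if (any(diff(te) <= 0)) stop("TE list must be increasing")
  sig <- s0 * exp(-te / t2star)
  if (noise_sd > 0) {
    set.seed(spec$seed)
    sig <- sig + stats::rnorm(length(te), 0, noise_sd)
  }
  # magnitude-image noise-floor proxy: clip after noise so samples stay
  # nonnegative, mimicking the late-echo plateau of Rician magnitude data
  if (floor_ > 0) sig <- pmax(sig, floor_)
  list(curve = si_time_curve(te, sig, label = "t2star_roi",
                             baseline_frames = 0L),
       truth = list(s0 = s0, t2star = t2star, floor = floor_))
}

# gamma-variate bolus on a flat baseline
gamma_variate <- function(t, t0, A, alpha, beta) {
  u <- pmax(t - t0, 0)
  A * u^alpha * exp(-u / beta)
}

#' First-pass perfusion curve set (stress and/or rest)
#'
#' Per-segment signal-intensity/time curves: flat baseline plus a
#' gamma-variate bolus A (t-t0)^alpha exp(-(t-t0)/beta), one sample per RR
#' interval.  Hypoperfused segments get their amplitude scaled by
#' `hypo_factor`; the blood-pool curve leads the myocardium and has larger
#' amplitude.  Pixel noise is emulated by averaging `n_pixels` iid noisy
#' copies per segment, matching what sector-mean extraction from a dynamic
#' series produces.
#'
#' Analytic truths: time-to-peak after arrival = alpha beta; maximal
#' upslope is proportional to A, so the hypoperfused/normal normalized
#' upslope ratio is exactly `hypo_factor` in the noise-free limit.
#'
#' @param spec [phantom_spec()] of kind `perfusion_series`; parameters
#'   `n_segments` (16), `rr` (1 s), `n_frames` (50), `baseline_frames` (8),
#'   `t0` (10 s myocardium, blood leads by 3 s), `alpha` (2), `beta` (3 s),
#'   `peak` (100 SI myocardial peak), `baseline` (50 SI), `hypo_segments`
#'   (integer ids, default none), `hypo_factor` (0.5), `noise_sd`
#'   (per-pixel SI, 0), `n_pixels` (30).
#' @return list(curves = named list of [si_time_curve()] (`seg_1`...,
#'   `blood`), truth = list(...)).
#' @export
make_perfusion_series <- function(spec) {
  p <- spec$params
  n_seg <- p$n_segments %||% 16L
  rr <- p$rr %||% 1; n_frames <- p$n_frames %||% 50L
  baseline_frames <- p$baseline_frames %||% 8L
  t0 <- p$t0 %||% 10; alpha <- p$alpha %||% 2; beta <- p$beta %||% 3
  peak <- p$peak %||% 100; base <- p$baseline %||% 50
  hypo <- p$hypo_segments %||% integer()
  hfac <- p$hypo_factor %||% 0.5
  noise_sd <- p$noise_sd %||% 0
  n_pixels <- p$n_pixels %||% 30L
  t <- (seq_len(n_frames) - 1L) * rr
  if (t0 >= max(t)) stop("bolus arrival t0 beyond the series end")
  if (baseline_frames < 5) stop("need at least 5 baseline frames")
  # amplitude giving the requested peak: max of u^a e^{-u/b} at u = a b
  A <- peak / ((alpha * beta)^alpha * exp(-alpha))
  set.seed(spec$seed)
  curves <- list()
  mk <- function(t0i, Ai, label) {
    clean <- base + gamma_variate(t, t0i, Ai, alpha, beta)
    v <- if (noise_sd > 0) {
      noise <- matrix(stats::rnorm(length(t) * n_pixels, 0, noise_sd),
                      length(t), n_pixels)
      clean + rowMeans(noise)
    } else clean
    si_time_curve(t, v, label = label, baseline_frames = baseline_frames)
  }
  for (s in seq_len(n_seg)) {
    f <- if (s %in% hypo) hfac else 1
    curves[[paste0("seg_", s)]] <- mk(t0, A * f, paste0("seg_", s))
  }
  curves$blood <- mk(t0 - 3, A * 4, "blood_pool")
  list(curves = curves,
       truth = list(t0 = t0, alpha = alpha, beta = beta, A = A,
                    ttp = alpha * beta, hypo_segments = hypo,
                    hypo_factor = hfac,
                    upslope_integral =
                      A * beta^(alpha + 1) * gamma(alpha + 1) *
                      stats::pgamma(alpha, alpha + 1)))
}

#' Through-plane velocity field phantom
#'
#' Circular vessel of radius `R_px` pixels with a parabolic (Poiseuille)
#' profile v(r) = v_max (1 - r^2/R^2), modulated in time by a systolic
#' sin^2 forward lobe and an optional diastolic reverse lobe.  Velocities
#' beyond VENC are stored wrapped by 2 VENC when `alias = TRUE` (they must
#' be declared, mirroring what the scanner does).
#'
#' Truth integrals (closed form): spatial mean over the disc is v_max/2, so
#' net volume = 1/2 v_max A int w(t) dt with A the true disc area.
#'
#' @param spec [phantom_spec()] of kind `flow_field`; parameters `v_max`
#'   (100 cm/s), `R_px` (12), `grid` (32), `pixel_mm` (2), `n_phases` (30),
#'   `cycle_s` (1), `systole_frac` (0.4), `reverse_frac` (0, amplitude of
#'   the diastolic reverse lobe relative to v_max), `venc` (150 cm/s),
#'   `alias` (FALSE), `noise_sd` (0).
#' @return list(frames = [velocity_frame_set()], truth = list(antegrade_ml,
#'   retrograde_ml, net_ml, rf_pct, v_max, area_cm2)).
#' @export
make_flow_field <- function(spec) {
  p <- spec$params
  v_max <- p$v_max %||% 100; R_px <- p$R_px %||% 12
  grid <- p$grid %||% 32L; pixel_mm <- p$pixel_mm %||% 2
  n_phases <- p$n_phases %||% 30L; cycle <- p$cycle_s %||% 1
  sys_frac <- p$systole_frac %||% 0.4
  rev_frac <- p$reverse_frac %||% 0
  venc <- p$venc %||% 150
  alias <- isTRUE(p$alias); noise_sd <- p$noise_sd %||% 0
  if (R_px < 4) stop("vessel radius below 4 pixels fails QC by construction")
  if (v_max > venc && !alias)
    stop("v_max exceeds VENC: set alias = TRUE to declare wrapping")
  dt <- cycle / n_phases
  tt <- (seq_len(n_phases) - 0.5) * dt
  w <- ifelse(tt < sys_frac * cycle, sin(pi * tt / (sys_frac * cycle))^2, 0)
  n_sys <- sum(tt < sys_frac * cycle)
  wr <- ifelse(tt >= sys_frac * cycle,
               -rev_frac * sin(pi * (tt - sys_frac * cycle) /
                                 ((1 - sys_frac) * cycle))^2, 0)
  wav <- w + wr
  # pixel-center radial distances (mm) from the vessel center
  c0 <- grid / 2 * pixel_mm
  ctr <- pixel_centers(grid, grid, c(pixel_mm, pixel_mm))
  r2 <- (ctr$x - c0)^2 + (ctr$y - c0)^2
  R_mm <- R_px * pixel_mm
  prof <- pmax(1 - r2 / R_mm^2, 0)
  set.seed(spec$seed)
  vel <- array(0, c(n_phases, grid, grid))
  for (k in seq_len(n_phases)) {
    fr <- matrix(v_max * prof * wav[k], grid, grid)
    if (noise_sd > 0)
      fr <- fr + matrix(stats::rnorm(grid * grid, 0, noise_sd), grid, grid)
    if (alias) fr <- ((fr + venc) %% (2 * venc)) - venc
    vel[k, , ] <- fr
  }
  roi <- circle_contour(c0, c0, R_mm, "roi")
  frames <- velocity_frame_set(vel, venc = venc, frame_duration = dt,
                               pixel_spacing_mm = c(pixel_mm, pixel_mm),
                               roi = roi, aliased = alias)
  A_cm2 <- pi * R_mm^2 / 100
  fwd_int <- sum(w) * dt          # int of the forward lobe (midpoint exact
  rev_int <- -sum(wr) * dt        # enough at 30 phases for 1% tests)
  ante <- 0.5 * v_max * A_cm2 * fwd_int
  retro <- 0.5 * v_max * A_cm2 * rev_int
  list(frames = frames,
       truth = list(antegrade_ml = ante, retrograde_ml = retro,
                    net_ml = ante - retro,
                    rf_pct = if (ante > 0) 100 * retro / ante else NA_real_,
                    v_max = v_max, area_cm2 = A_cm2))
}

#' Late-gadolinium-enhancement scene phantom
#'
#' Annular myocardium (inner radius `r_endo`, outer `r_epi` pixels) with
#' gaussian remote intensities and a wedge-shaped scar of given angular
#' span and transmural depth fraction (measured from the endocardium).
#' The truth mask is recorded before noise.
#'
#' @param spec [phantom_spec()] of kind `lge_scene`; parameters `grid`
#'   (96), `r_endo` (18), `r_epi` (30) px, `remote_mean` (100),
#'   `remote_sd` (10), `scar_mean` (400), `scar_span_deg` (60, 0 for no
#'   scar), `scar_depth` (fraction of wall, 1 = transmural),
#'   `scar_start_deg` (0), `noise` (TRUE: gaussian remote_sd everywhere).
#' @return list(image, myo_mask, truth = list(scar_mask, depth_frac,
#'   span_deg, ...), geometry, model = [aha_model()] for the single slice).
#' @export
make_lge_scene <- function(spec) {
  p <- spec$params
  grid <- p$grid %||% 96L
  r_endo <- p$r_endo %||% 18; r_epi <- p$r_epi %||% 30
  remote_mean <- p$remote_mean %||% 100; remote_sd <- p$remote_sd %||% 10
  scar_mean <- p$scar_mean %||% 400
  span <- p$scar_span_deg %||% 60
  depth <- p$scar_depth %||% 0.5
  start <- p$scar_start_deg %||% 0
  noise <- p$noise %||% TRUE
  if (span > 0 && scar_mean <= remote_mean + remote_sd)
    stop("scar mean must exceed remote mean + 1 SD to form a usable scene")
  c0 <- grid / 2
  ctr <- pixel_centers(grid, grid, c(1, 1))
  dx <- ctr$x - c0; dy <- ctr$y - c0
  r <- sqrt(dx^2 + dy^2)
  myo <- matrix(r >= r_endo & r <= r_epi, grid, grid)
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  in_span <- if (span <= 0) rep(FALSE, length(ang)) else
    ((ang - start) %% 360) < span
  scar <- matrix(in_span & r >= r_endo & r <= r_endo + depth * (r_epi - r_endo),
                 grid, grid) & myo
  set.seed(spec$seed)
  img <- matrix(remote_mean, grid, grid)
  if (noise) img <- img + matrix(stats::rnorm(grid^2, 0, remote_sd), grid, grid)
  img[scar] <- scar_mean + if (noise)
    stats::rnorm(sum(scar), 0, remote_sd) else 0
  # anterior insertion placed at angle `start` so the scar wedge falls in
  # the first sector(s) of the sweep; inferior insertion 120 deg onward
  ins <- function(deg) c(c0 + (r_endo + 2) * cos(deg * pi / 180),
                         c0 + (r_endo + 2) * sin(deg * pi / 180))
  model <- aha_model(lv_centroid = c(c0, c0),
                     rv_insertion_anterior = ins(start),
                     rv_insertion_inferior = ins(start + 120),
                     slice_tier = "mid", n_segments = 17)
  list(image = img, myo_mask = myo,
       truth = list(scar_mask = scar, depth_frac = depth, span_deg = span,
                    start_deg = start, remote_mean = remote_mean,
                    remote_sd = remote_sd, scar_mean = scar_mean,
                    r_endo = r_endo, r_epi = r_epi),
       geometry = list(pixel_spacing = c(1, 1), slice_thickness = 8,
                       slice_gap = 2),
       model = model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dispatch a phantom spec to its generator
#' @param spec a [phantom_spec()].
#' @return the generator's output list.
#' @export
make_phantom <- function(spec) {
  switch(spec$kind,
         lv_ellipsoid = make_lv_phantom(spec),
         rv_crescent = make_rv_phantom(spec),
         decay_series = make_decay_series(spec),
         perfusion_series = make_perfusion_series(spec),
         flow_field = make_flow_field(spec),
         lge_scene = make_lge_scene(spec),
         stop(sprintf("no generator for kind '%s'", spec$kind)))
}
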
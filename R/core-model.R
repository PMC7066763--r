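# Core data model: image stacks, contours, AHA segmentation, ROI statistics,
# subject demographics.  Coordinate convention (fixed once, used everywhere):
# distances in millimeters, origin at the image corner, x along columns and
# y along rows, pixels are half-open unit boxes so the 1-based array element
# [i, j] covers [(j-1)*sx, j*sx) x [(i-1)*sy, i*sy) mm and has its center at
# ((j - 0.5)*sx, (i - 0.5)*sy).

#' Create an image stack
#'
#' Container for grayscale voxel data plus the geometry metadata every
#' quantitative computation needs: in-plane pixel spacing, slice thickness
#' and interslice gap.  The voxel array may be 2D (row, col), 3D
#' (slice/phase, row, col) or 4D (slice, phase, row, col); its
#' interpretation is up to the caller.
#'
#' @param voxels numeric array, 2--4 dimensions.
#' @param pixel_spacing length-2 numeric, mm per pixel as c(row, col).
#' @param slice_thickness slice thickness in mm.
#' @param slice_gap interslice gap in mm (0 for contiguous slices).
#' @param frame_times optional numeric vector of frame times in seconds,
#'   strictly increasing.
#' @param meta free-form list of acquisition tags (TE list, VENC, field
#'   strength, ...).
#' @return object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_spacing, slice_thickness = 1,
                        slice_gap = 0, frame_times = NULL, meta = list()) {
  if (!is.numeric(voxels) || is.null(dim(voxels)) || length(dim(voxels)) > 4)
    stop("voxels must be a numeric array with 2 to 4 dimensions")
  pixel_spacing <- rep_len(as.numeric(pixel_spacing), 2L)
  if (any(!is.finite(pixel_spacing)) || any(pixel_spacing <= 0))
    stop("pixel_spacing must be positive")
  if (!is.finite(slice_thickness) || slice_thickness <= 0)
    stop("slice_thickness must be positive")
  if (!is.finite(slice_gap) || slice_gap < 0)
    stop("slice_gap must be >= 0")
  if (!is.null(frame_times)) {
    frame_times <- as.numeric(frame_times)
    if (any(diff(frame_times) <= 0))
      stop("frame_times must be strictly increasing")
  }
  structure(list(voxels = voxels, pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness, slice_gap = slice_gap,
                 frame_times = frame_times, meta = meta),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat("<image_stack>", paste(dim(x$voxels), collapse = " x "),
      sprintf("| spacing %.3g x %.3g mm | thickness %.3g mm | gap %.3g mm\n",
              x$pixel_spacing[1], x$pixel_spacing[2],
              x$slice_thickness, x$slice_gap))
  invisible(x)
}

CONTOUR_LABELS <- c("endo", "epi", "roi", "blood_pool", "skeletal_muscle",
                    "remote", "scar_max", "papillary", "rv_endo")

#' Create a planar contour
#'
#' A closed polygon in image-plane millimeter coordinates.  Vertices are
#' stored in canonical counterclockwise orientation; the closing edge from
#' the last vertex back to the first is implicit.
#'
#' @param points two-column numeric matrix of (x, y) vertices in mm.
#' @param label contour role: endo, epi, roi, blood_pool, skeletal_muscle,
#'   remote, scar_max, papillary or rv_endo.
#' @param closed must be `TRUE`; open polylines are not valid analysis
#'   contours.
#' @param check_simple validate non-self-intersection (O(n^2); disable for
#'   very large programmatic contours known to be simple).
#' @return object of class `contour`.
#' @export
contour <- function(points, label = "roi", closed = TRUE,
                    check_simple = TRUE) {
  if (!closed) stop("open contours are not supported: closed must be TRUE")
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2)
    stop("points must be an n x 2 numeric matrix")
  if (any(!is.finite(points))) stop("contour vertices must be finite")
  # drop duplicated closing vertex if caller supplied one
  n <- nrow(points)
  if (n >= 2 && all(points[1, ] == points[n, ])) {
    points <- points[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3) stop("a contour needs at least 3 vertices")
  a <- signed_area(points)
  if (abs(a) < .Machine$double.eps * 100)
    stop("degenerate contour: zero area")
  if (a < 0) points <- points[n:1, , drop = FALSE]  # canonical CCW
  if (check_simple && n <= 512 && self_intersects(points))
    stop("contour is self-intersecting")
  label <- match.arg(label, CONTOUR_LABELS)
  structure(list(points = points, closed = TRUE, label = label),
            class = "contour")
}

# shoelace signed area (positive = counterclockwise in x-right/y-down? we
# treat orientation abstractly: sign is canonicalized away by contour())
signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# O(n^2) segment-pair crossing test; adjacent edges share an endpoint and
# are skipped.
self_intersects <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE]))
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]  # edge n touches edge 1
    a <- seg[i, ]
    d1 <- cross(a[1], a[2], a[3], a[4], seg[js, 1], seg[js, 2])
    d2 <- cross(a[1], a[2], a[3], a[4], seg[js, 3], seg[js, 4])
    d3 <- cross(seg[js, 1], seg[js, 2], seg[js, 3], seg[js, 4], a[1], a[2])
    d4 <- cross(seg[js, 1], seg[js, 2], seg[js, 3], seg[js, 4], a[3], a[4])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Planimetered polygon area
#'
#' Shoelace area of a closed contour, in mm^2.  Invariant under vertex
#' rotation and orientation reversal (orientation is canonicalized at
#' construction).
#'
#' @param x a [contour()] or an n x 2 vertex matrix.
#' @return area in mm^2 (positive).
#' @export
polygon_area <- function(x) {
  if (inherits(x, "contour")) return(abs(signed_area(x$points)))
  abs(signed_area(contour(x)$points))
}

#' Even-odd point-in-polygon test
#'
#' A pixel belongs to an ROI iff its center lies inside the polygon under
#' the even-odd (ray crossing) rule.  Vectorized over query points.
#'
#' @param px,py numeric vectors of query coordinates (mm).
#' @param poly a [contour()] or n x 2 vertex matrix.
#' @return logical vector.
#' @export
points_in_polygon <- function(px, py, poly) {
  p <- if (inherits(poly, "contour")) poly$points else as.matrix(poly)
  n <- nrow(p)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- p[i, 1]; yi <- p[i, 2]; xj <- p[j, 1]; yj <- p[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# pixel-center coordinates (mm) for an nrow x ncol image
pixel_centers <- function(nr, nc, pixel_spacing) {
  sx <- pixel_spacing[2]; sy <- pixel_spacing[1]
  list(x = rep((seq_len(nc) - 0.5) * sx, each = nr),
       y = rep((seq_len(nr) - 0.5) * sy, times = nc))
}

#' Rasterize a contour to a logical pixel mask
#'
#' @param poly a [contour()] or vertex matrix (mm coordinates).
#' @param dim_img c(nrow, ncol) of the target grid.
#' @param pixel_spacing mm per pixel c(row, col).
#' @return logical matrix; TRUE where the pixel center is inside.
#' @export
contour_to_mask <- function(poly, dim_img, pixel_spacing = c(1, 1)) {
  ctr <- pixel_centers(dim_img[1], dim_img[2], pixel_spacing)
  matrix(points_in_polygon(ctr$x, ctr$y, poly), dim_img[1], dim_img[2])
}

#' Create a contour stack
#'
#' Indexed collection of per-slice, per-phase contours plus the geometry
#' needed for Simpson summation.  Papillary-muscle convention is carried
#' here because downstream volume and mass bookkeeping depends on it.
#'
#' @param contours list of entries `list(slice=, phase=, label=, contour=)`
#'   with 1-based slice and phase indices.
#' @param geometry an [image_stack()] or a list with `pixel_spacing`,
#'   `slice_thickness`, `slice_gap`.
#' @param papillary_mode `"in_blood_pool"` (default; papillary/trabecular
#'   tissue counted with the cavity) or `"in_mass"` (moved to myocardium).
#'   Reference ranges are convention specific, so the mode is echoed in all
#'   results.
#' @param include_slice optional data.frame with columns slice, phase,
#'   include; slices default to included.
#' @return object of class `contour_stack`.
#' @export
contour_stack <- function(contours, geometry,
                          papillary_mode = c("in_blood_pool", "in_mass"),
                          include_slice = NULL) {
  papillary_mode <- match.arg(papillary_mode)
  if (!length(contours)) stop("contour stack needs at least one contour")
  for (e in contours) {
    if (!all(c("slice", "phase", "label", "contour") %in% names(e)))
      stop("each entry needs slice, phase, label, contour")
    if (!inherits(e$contour, "contour")) stop("entries must hold contour objects")
  }
  geom <- list(pixel_spacing = geometry$pixel_spacing,
               slice_thickness = geometry$slice_thickness,
               slice_gap = geometry$slice_gap)
  if (is.null(geom$slice_thickness) || geom$slice_thickness <= 0)
    stop("geometry must provide a positive slice_thickness")
  if (is.null(geom$slice_gap) || geom$slice_gap < 0)
    stop("geometry must provide slice_gap >= 0")
  st <- structure(list(contours = contours, geometry = geom,
                       papillary_mode = papillary_mode,
                       include_slice = include_slice),
                  class = "contour_stack")
  # epi must enclose endo wherever both exist
  for (sl in stack_slices(st)) for (ph in stack_phases(st)) {
    en <- stack_get(st, sl, ph, "endo"); ep <- stack_get(st, sl, ph, "epi")
    if (!is.null(en) && !is.null(ep) &&
        polygon_area(ep) < polygon_area(en))
      stop(sprintf("slice %d phase %d: epi area smaller than endo area", sl, ph))
  }
  st
}

stack_slices <- function(st)
  sort(unique(vapply(st$contours, function(e) as.integer(e$slice), 1L)))
stack_phases <- function(st)
  sort(unique(vapply(st$contours, function(e) as.integer(e$phase), 1L)))

# all contours for (slice, phase, label); usually 0 or 1, >1 for papillaries
stack_get_all <- function(st, slice, phase, label) {
  out <- list()
  for (e in st$contours)
    if (e$slice == slice && e$phase == phase && e$label == label)
      out[[length(out) + 1L]] <- e$contour
  out
}
stack_get <- function(st, slice, phase, label) {
  hits <- stack_get_all(st, slice, phase, label)
  if (!length(hits)) NULL else hits[[1L]]
}

slice_included <- function(st, slice, phase) {
  inc <- st$include_slice
  if (is.null(inc)) return(TRUE)
  hit <- inc$slice == slice & inc$phase == phase
  if (!any(hit)) TRUE else all(inc$include[hit])
}

#' Create an AHA segment model
#'
#' Geometry needed to assign myocardial points to the standardized 16- or
#' 17-segment left-ventricular model: the LV centroid, the anterior and
#' inferior right-ventricular insertion points, and the per-slice tier
#' (basal, mid, apical, apex).
#'
#' @param lv_centroid,rv_insertion_anterior,rv_insertion_inferior length-2
#'   (x, y) points in mm.
#' @param slice_tier character vector, one of "basal", "mid", "apical",
#'   "apex" per slice.
#' @param n_segments 16 or 17 (17 adds the apex-tier segment).
#' @return object of class `aha_model`.
#' @export
aha_model <- function(lv_centroid, rv_insertion_anterior,
                      rv_insertion_inferior, slice_tier, n_segments = 17) {
  if (!n_segments %in% c(16L, 17L)) stop("n_segments must be 16 or 17")
  slice_tier <- match.arg(slice_tier, c("basal", "mid", "apical", "apex"),
                          several.ok = TRUE)
  if (n_segments == 16L && any(slice_tier == "apex"))
    stop("apex tier requires the 17-segment model")
  if (all(lv_centroid == rv_insertion_anterior) ||
      all(lv_centroid == rv_insertion_inferior))
    stop("insertion points must differ from the centroid")
  structure(list(n_segments = as.integer(n_segments),
                 lv_centroid = as.numeric(lv_centroid),
                 rv_insertion_anterior = as.numeric(rv_insertion_anterior),
                 rv_insertion_inferior = as.numeric(rv_insertion_inferior),
                 slice_tier = slice_tier),
            class = "aha_model")
}

# sweep angle in degrees [0, 360): 0 at the anterior RV insertion,
# increasing in the rotational direction that reaches the inferior
# insertion through the septum (the shorter way round).
aha_sweep_angle <- function(x, y, model) {
  ang <- function(px, py) atan2(py - model$lv_centroid[2],
                                px - model$lv_centroid[1]) * 180 / pi
  a0 <- ang(model$rv_insertion_anterior[1], model$rv_insertion_anterior[2])
  ai <- ang(model$rv_insertion_inferior[1], model$rv_insertion_inferior[2])
  ccw_sep <- (ai - a0) %% 360
  sgn <- if (ccw_sep <= 180) 1 else -1
  (sgn * (ang(x, y) - a0)) %% 360
}

#' Assign a point to an AHA segment
#'
#' Segment ids follow the standard ordering within each tier: basal 1-6,
#' mid 7-12, apical 13-16, apex 17.  Sector boundaries start at the
#' anterior RV insertion point and sweep through the septum toward the
#' inferior insertion; basal/mid sectors span 60 degrees, apical sectors 90
#' degrees.
#'
#' @param point (x, y) in mm, inside the myocardial annulus.
#' @param slice_index 1-based slice index into `model$slice_tier`.
#' @param model an [aha_model()].
#' @return integer segment id in 1..17.
#' @export
assign_aha_segment <- function(point, slice_index, model) {
  tier <- model$slice_tier[slice_index]
  if (is.na(tier)) stop("slice_index outside the model's slice tiers")
  if (tier == "apex") {
    if (model$n_segments != 17L) stop("apex tier undefined for 16 segments")
    return(17L)
  }
  if (all(point[1:2] == model$lv_centroid))
    stop("angle undefined at the LV centroid")
  sweep <- aha_sweep_angle(point[1], point[2], model)
  switch(tier,
         basal  = 1L + as.integer(sweep %/% 60) %% 6L,
         mid    = 7L + as.integer(sweep %/% 60) %% 6L,
         apical = 13L + as.integer(sweep %/% 90) %% 4L)
}

#' Human-readable AHA segment names
#' @param id integer vector of segment ids 1..17.
#' @return character vector.
#' @export
aha_segment_name <- function(id) {
  nm <- c("basal anterior", "basal anteroseptal", "basal inferoseptal",
          "basal inferior", "basal inferolateral", "basal anterolateral",
          "mid anterior", "mid anteroseptal", "mid inferoseptal",
          "mid inferior", "mid inferolateral", "mid anterolateral",
          "apical anterior", "apical septal", "apical inferior",
          "apical lateral", "apex")
  nm[id]
}

#' ROI statistics over an image frame
#'
#' Mean and sample (n-1) standard deviation over the pixels whose centers
#' fall inside the polygon.  ROIs smaller than 20 pixels are flagged:
#' very small ROIs are unreliable on parametric maps.
#'
#' @param frame numeric matrix (one image frame) or [image_stack()] with 2D
#'   voxels.
#' @param roi a [contour()] in mm coordinates, or a logical mask matching
#'   the frame.
#' @param pixel_spacing mm per pixel c(row, col); taken from the stack when
#'   `frame` is an [image_stack()].
#' @param exclude optional logical mask of pixels to drop (e.g. focal
#'   fibrosis seen on LGE).
#' @return object of class `roi_stats`: list(mean, sd, n_pixels, warnings).
#' @export
roi_stats <- function(frame, roi, pixel_spacing = c(1, 1), exclude = NULL) {
  if (inherits(frame, "image_stack")) {
    pixel_spacing <- frame$pixel_spacing
    frame <- frame$voxels
  }
  if (length(dim(frame)) != 2) stop("frame must be a single 2D image")
  sel <- if (is.logical(roi)) roi else
    contour_to_mask(roi, dim(frame), pixel_spacing)
  if (!is.null(exclude)) sel <- sel & !exclude
  vals <- frame[sel]
  if (!length(vals)) stop("ROI contains no pixel centers")
  warnings <- character()
  if (length(vals) < 20)
    warnings <- c(warnings, sprintf("small ROI (%d < 20 pixels)", length(vals)))
  structure(list(mean = mean(vals),
                 sd = if (length(vals) > 1) stats::sd(vals) else 0,
                 n_pixels = length(vals), warnings = warnings),
            class = "roi_stats")
}

#' Z-score against a local normal reference
#'
#' Number of standard deviations by which a measured value differs from the
#' local normal mean.
#'
#' @param value measured value.
#' @param normal_mean,normal_sd local normal reference mean and SD
#'   (`normal_sd > 0`).
#' @return dimensionless Z-score.
#' @export
z_score <- function(value, normal_mean, normal_sd) {
  if (!is.finite(normal_sd) || normal_sd <= 0)
    stop("normal_sd must be > 0")
  (value - normal_mean) / normal_sd
}

#' Create a subject record
#'
#' @param height cm.
#' @param weight kg.
#' @param heart_rate bpm.
#' @param hematocrit fraction in (0, 1).
#' @param bsa_formula "mosteller" (default) or "dubois"; always echoed in
#'   derived results so indexed values are traceable.
#' @return object of class `subject`.
#' @export
subject <- function(height = NULL, weight = NULL, heart_rate = NULL,
                    hematocrit = NULL,
                    bsa_formula = c("mosteller", "dubois")) {
  bsa_formula <- match.arg(bsa_formula)
  for (f in c("height", "weight", "heart_rate")) {
    v <- get(f)
    if (!is.null(v) && (!is.finite(v) || v <= 0))
      stop(sprintf("%s must be positive", f))
  }
  if (!is.null(hematocrit) &&
      (!is.finite(hematocrit) || hematocrit <= 0 || hematocrit >= 1))
    stop("hematocrit must be a fraction in (0, 1)")
  structure(list(height = height, weight = weight, heart_rate = heart_rate,
                 hematocrit = hematocrit, bsa_formula = bsa_formula),
            class = "subject")
}

#' Body surface area
#'
#' Mosteller sqrt(h.w/3600) by default; DuBois-DuBois
#' 0.007184 h^0.725 w^0.425 selectable.  The formula used is attached as an
#' attribute so reports can echo it.
#'
#' @param subj a [subject()] with height (cm) and weight (kg).
#' @param formula override the subject's stored choice.
#' @return BSA in m^2 with attribute `formula`.
#' @export
body_surface_area <- function(subj, formula = NULL) {
  if (is.null(subj$height)) stop("missing field: height")
  if (is.null(subj$weight)) stop("missing field: weight")
  formula <- if (is.null(formula)) subj$bsa_formula else
    match.arg(formula, c("mosteller", "dubois"))
  bsa <- switch(formula,
                mosteller = sqrt(subj$height * subj$weight / 3600),
                dubois = 0.007184 * subj$height^0.725 * subj$weight^0.425)
  attr(bsa, "formula") <- formula
  bsa
}
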
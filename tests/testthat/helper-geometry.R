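# shared fixture builders (all fixtures are constructed in code)

circ <- function(cx, cy, r, label = "roi", n = 128L) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cmrquant::contour(cbind(cx + r * cos(th), cy + r * sin(th)),
                    label = label, check_simple = FALSE)
}

rect <- function(x0, y0, x1, y1, label = "roi") {
  cmrquant::contour(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)),
                    label = label)
}

square_ctr <- function(cx, cy, side, label = "roi")
  rect(cx - side / 2, cy - side / 2, cx + side / 2, cy + side / 2, label)

# annulus mask + matching wedge mask on an n x n unit-spaced grid
annulus_masks <- function(n, r_in, r_out) {
  c0 <- n / 2
  xy <- pixel_xy(n)
  r <- sqrt((xy$x - c0)^2 + (xy$y - c0)^2)
  matrix(r >= r_in & r <= r_out, n, n)
}

pixel_xy <- function(n) {
  list(x = rep(seq_len(n) - 0.5, each = n),
       y = rep(seq_len(n) - 0.5, times = n))
}

wedge_mask <- function(n, from_deg, to_deg) {
  c0 <- n / 2
  xy <- pixel_xy(n)
  ang <- (atan2(xy$y - c0, xy$x - c0) * 180 / pi) %% 360
  matrix(ang >= from_deg & ang < to_deg, n, n)
}

# independent brute-force AHA oracle: explicit angle table under the fixed
# convention (0 deg at the anterior insertion, sweeping through the septum
# toward the inferior insertion, sequential ids per tier)
aha_oracle <- function(point, tier, model) {
  ang <- function(p) atan2(p[2] - model$lv_centroid[2],
                           p[1] - model$lv_centroid[1]) * 180 / pi
  a0 <- ang(model$rv_insertion_anterior)
  ai <- ang(model$rv_insertion_inferior)
  ccw <- ((ai - a0) %% 360) <= 180
  sweep <- if (ccw) (ang(point) - a0) %% 360 else (a0 - ang(point)) %% 360
  if (tier == "apical") {
    edges <- seq(0, 360, by = 90)
    return(12L + findInterval(sweep, edges, rightmost.closed = TRUE))
  }
  edges <- seq(0, 360, by = 60)
  base <- if (tier == "basal") 0L else 6L
  base + findInterval(sweep, edges, rightmost.closed = TRUE)
}

# point at `deg` degrees of sweep from the anterior insertion (radius 20)
aha_sweep_point <- function(m, deg) {
  a0 <- atan2(m$rv_insertion_anterior[2] - m$lv_centroid[2],
              m$rv_insertion_anterior[1] - m$lv_centroid[1])
  ai <- atan2(m$rv_insertion_inferior[2] - m$lv_centroid[2],
              m$rv_insertion_inferior[1] - m$lv_centroid[1])
  sgn <- if (((ai - a0) * 180 / pi) %% 360 <= 180) 1 else -1
  th <- a0 + sgn * deg * pi / 180
  m$lv_centroid + 20 * c(cos(th), sin(th))
}

# remote-reference wedge on an LGE scene grid (away from the scar at 0-90)
lge_remote_mask <- function(grid, from = 150, to = 330) {
  c0 <- grid / 2
  xy <- pixel_xy(grid)
  ang <- (atan2(xy$y - c0, xy$x - c0) * 180 / pi) %% 360
  matrix(ang > from & ang < to, grid, grid)
}

# two-phase uniform flow frames: +fwd ml then -rev ml over 1 cm^2 pixels
two_phase_frames <- function(fwd = 80, rev = 20) {
  vel <- array(0, c(2, 4, 6))
  vel[1, 1, 1:5] <- fwd / 5
  vel[2, 1, 1:5] <- -rev / 5
  velocity_frame_set(vel, venc = 200, frame_duration = 1,
                     pixel_spacing_mm = c(10, 10),
                     roi = rect(0, 0, 50, 10))
}
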
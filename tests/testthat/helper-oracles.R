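# Independent oracles and fixture builders shared across the suite.

# All-pairs nearest-neighbour distances (micrometres), the brute-force
# reference for the grid-bucket implementation.
nnd_bruteforce <- function(points) {
  xy <- as.matrix(points[, c("x_mm", "y_mm")])
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  unname(apply(d, 1, min)) * 1000
}

# Closed-form regularity index of a 2D homogeneous Poisson process.
RI_POISSON <- 0.5 * sqrt(4 * pi / (4 - pi))

# Disc-shaped retina geometry without rendering an image: mask of radius
# radius_mm centred in a square frame, ONH at the centre pixel.
disc_geometry <- function(radius_mm, pixel_size_um) {
  half <- ceiling(radius_mm * 1000 / pixel_size_um)
  n <- 2L * half + 1L
  xs <- ((seq_len(n) - 1) - half) * pixel_size_um / 1000
  mask <- outer(xs^2, xs^2, "+") <= radius_mm^2
  retina_geometry(mask, pixel_size_um, c(half, half))
}

# Cells in the absolute (image) frame of disc_geometry, from retina-centred
# coordinates; no y flip (pure-geometry tests use orientation 90).
centre_cells <- function(points, geometry) {
  onh <- geometry$onh_xy_mm
  data.frame(x_mm = points$x_mm + onh[1], y_mm = points$y_mm + onh[2])
}

# Precision/recall of detections against ground-truth centres, matched by
# nearest neighbour within one soma radius.
match_truth <- function(cells, truth, retina, radius_mm = 6e-3) {
  n <- nrow(retina$image)
  ctr <- (n - 1) / 2
  if (nrow(cells) == 0) return(c(precision = NaN, recall = 0))
  cx <- (cells$x_px - ctr) * retina$pixel_size_um / 1000
  cy <- (ctr - cells$y_px) * retina$pixel_size_um / 1000
  d2 <- outer(cx, truth$x_mm, "-")^2 + outer(cy, truth$y_mm, "-")^2
  c(precision = mean(sqrt(apply(d2, 1, min)) < radius_mm),
    recall = mean(sqrt(apply(d2, 2, min)) < radius_mm))
}

# Noise-free two-phase decay profile in the (Plateau, spans) form.
two_phase_profile <- function(times, Y0, Plateau, PF,
                              t_fast = 1.7, t_slow = 16.3) {
  KF <- log(2) / t_fast
  KS <- log(2) / t_slow
  span <- Y0 - Plateau
  Plateau + span * (PF / 100) * exp(-KF * times) +
    span * (1 - PF / 100) * exp(-KS * times)
}
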
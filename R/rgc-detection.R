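#' Detection parameters
#'
#' Tunable parameters of the cell-detection chain. Defaults follow the
#' standard operator chain for labelled-soma counting in 8-bit whole-mount
#' images: background flattening, a grey-level threshold of 130,
#' distance-transform watershed splitting, then size (7-21 micrometre
#' equivalent-circle diameter) and circularity (> 0.7) gates.
#'
#' @param intensity_threshold 8-bit grey level; pixels at or above it (after
#'   background subtraction) are foreground.
#' @param min_diameter_um,max_diameter_um Accepted equivalent-circle diameter
#'   range of a particle, micrometres.
#' @param min_circularity Minimum `4*pi*area / perimeter^2`.
#' @param highpass_scale_um Side of the mean-filter kernel used to estimate
#'   the background that is subtracted before thresholding; about three times
#'   the largest soma diameter.
#' @param smooth_sigma_um Gaussian sigma of the mild soma-scale smoothing
#'   applied to the signal before the background is subtracted (the
#'   background-removal step is a band-pass). Suppresses pixel noise that
#'   would otherwise punch holes in thresholded somata; set to 0 to disable.
#' @param mask_threshold_high Upper grey level of the low-intensity band
#'   (`[0, mask_threshold_high]`) that defines the retinal-area mask.
#' @param watershed_tolerance Minimum depth (in distance-transform units) a
#'   watershed basin must have to remain a separate particle; suppresses
#'   shallow minima that would over-segment single somata.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(intensity_threshold = 130,
                             min_diameter_um = 7,
                             max_diameter_um = 21,
                             min_circularity = 0.7,
                             highpass_scale_um = 63,
                             smooth_sigma_um = 2,
                             mask_threshold_high = 5,
                             watershed_tolerance = 1) {
  stopifnot(intensity_threshold >= 0, intensity_threshold <= 255,
            mask_threshold_high >= 0, mask_threshold_high <= 255,
            min_diameter_um < max_diameter_um, min_diameter_um > 0,
            min_circularity >= 0, min_circularity <= 1,
            highpass_scale_um > 0, smooth_sigma_um >= 0,
            watershed_tolerance >= 0)
  structure(as.list(environment()), class = "detection_params")
}

#' Retina geometry: calibrated mask and optic-nerve-head centre
#'
#' @param mask Logical matrix (rows = y, cols = x) of retina pixels.
#' @param pixel_size_um Calibration, micrometres per pixel.
#' @param onh_xy_px Optic-nerve-head centre `(x, y)` in 0-based pixel
#'   coordinates (image origin top-left, y down).
#' @return Object of class `retina_geometry` with the mask, calibration,
#'   ONH centre in pixels and mm, and `retina_area_mm2` (mask pixel count
#'   times pixel area).
#' @export
retina_geometry <- function(mask, pixel_size_um, onh_xy_px) {
  stopifnot(is.matrix(mask), is.logical(mask), pixel_size_um > 0,
            length(onh_xy_px) == 2)
  onh_xy_px <- as.numeric(onh_xy_px)
  col <- round(onh_xy_px[1]) + 1L
  row <- round(onh_xy_px[2]) + 1L
  if (row < 1 || row > nrow(mask) || col < 1 || col > ncol(mask) ||
      !mask[row, col]) {
    warning("optic-nerve-head centre lies outside the retina mask")
  }
  structure(list(mask = mask,
                 pixel_size_um = pixel_size_um,
                 onh_xy_px = onh_xy_px,
                 onh_xy_mm = onh_xy_px * pixel_size_um / 1000,
                 retina_area_mm2 = sum(mask) * (pixel_size_um / 1000)^2),
            class = "retina_geometry")
}

#' @export
print.retina_geometry <- function(x, ...) {
  cat("Retina geometry:", nrow(x$mask), "x", ncol(x$mask), "px,",
      x$pixel_size_um, "um/px, area", round(x$retina_area_mm2, 2),
      "mm^2, ONH at (", x$onh_xy_px[1], ",", x$onh_xy_px[2], ") px\n")
  invisible(x)
}

#' Extract the retinal-area mask from a whole-mount image
#'
#' The flattened retina is the dark region of the image: pixels whose grey
#' level lies in the low band `[0, mask_threshold_high]` are selected, the
#' largest connected component is kept (dropping background speckle), and
#' holes (bright cell somata inside the retina) are filled.
#'
#' @param image Integer matrix (rows = y, cols = x), grey levels 0-255.
#' @param params A [detection_params()].
#' @return Logical matrix of retina pixels.
#' @export
make_retina_mask <- function(image, params = detection_params()) {
  stopifnot(is.matrix(image))
  low <- image <= params$mask_threshold_high
  if (!any(low)) stop("empty retina mask: no pixels at or below ",
                      params$mask_threshold_high, call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(t(low)))
  labm <- EBImage::imageData(lab)
  counts <- tabulate(labm[labm > 0])
  keep <- which.max(counts)
  mask <- EBImage::fillHull(EBImage::Image(labm == keep))
  t(EBImage::imageData(mask)) > 0
}

# O(n) box-mean filter via an integral image, replicate-padded at the
# borders; k must be odd. Used for both the soma-scale smoothing and the
# large-kernel background estimate (an FFT convolution is much slower at
# these kernel sizes).
box_mean <- function(m, k) {
  pad <- k %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  mp <- m[c(rep(1L, pad), seq_len(nr), rep(nr, pad)),
          c(rep(1L, pad), seq_len(nc), rep(nc, pad)), drop = FALSE]
  S <- apply(mp, 2, cumsum)
  S <- t(apply(S, 1, cumsum))
  S <- rbind(0, cbind(0, S))
  i1 <- seq_len(nr); j1 <- seq_len(nc)
  (S[i1 + k, j1 + k, drop = FALSE] - S[i1, j1 + k, drop = FALSE] -
     S[i1 + k, j1, drop = FALSE] + S[i1, j1, drop = FALSE]) / k^2
}

# Perimeter of each labelled particle as a Cauchy-corrected boundary-edge
# count: (pi/4) x (number of 4-neighbour pixel edges between the particle
# and anything else, image border included). The correction makes the
# estimator exact for smooth convex particles (Cauchy's projection formula),
# where a raw edge count overestimates the true boundary length by 4/pi.
label_perimeters <- function(lab) {
  nlab <- max(lab)
  if (nlab == 0) return(numeric(0))
  edges <- numeric(nlab)
  count_edges <- function(a, b) {
    diffs <- a != b
    e <- tabulate(a[diffs & a > 0], nbins = nlab) +
         tabulate(b[diffs & b > 0], nbins = nlab)
    e
  }
  nr <- nrow(lab); nc <- ncol(lab)
  edges <- edges + count_edges(lab[, -nc, drop = FALSE], lab[, -1, drop = FALSE])
  edges <- edges + count_edges(lab[-nr, , drop = FALSE], lab[-1, , drop = FALSE])
  border <- c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc])
  edges <- edges + tabulate(border[border > 0], nbins = nlab)
  (pi / 4) * edges
}

#' Detect labelled cells in an 8-bit whole-mount image
#'
#' Fixed pipeline: (1) background subtraction — a mean filter of side
#' `highpass_scale_um` estimates the slowly varying background, which is
#' subtracted and clipped at zero; (2) binarisation at
#' `intensity_threshold`; (3) watershed on the Euclidean distance transform
#' to split touching somata (shallow basins below `watershed_tolerance` are
#' merged); (4) particle gating by equivalent-circle diameter
#' (`[min_diameter_um, max_diameter_um]`), circularity
#' (`>= min_circularity`), and centroid inside the retina mask.
#'
#' @param image Integer matrix (rows = y, cols = x), grey levels 0-255.
#' @param geometry A [retina_geometry()] (supplies calibration and mask).
#' @param params A [detection_params()].
#' @return Data frame of detected cells in raster-scan order of their
#'   centroids, with columns `x_px`, `y_px` (0-based pixel coordinates),
#'   `x_mm`, `y_mm` (image-frame mm, origin top-left, y down), `area_um2`,
#'   `mean_intensity`, `circularity`, `equivalent_diameter_um`. Zero
#'   detections give a zero-row frame, not an error.
#' @export
detect_cells <- function(image, geometry, params = detection_params()) {
  stopifnot(is.matrix(image))
  if (!inherits(geometry, "retina_geometry")) {
    stop("geometry must be a retina_geometry (missing calibration?)",
         call. = FALSE)
  }
  px <- geometry$pixel_size_um
  if (!is.numeric(px) || is.na(px) || px <= 0) {
    stop("missing or invalid pixel-size calibration", call. = FALSE)
  }
  if (!all(dim(image) == dim(geometry$mask))) {
    stop("image and mask dimensions differ", call. = FALSE)
  }
  im <- t(image)                        # first dim = x, second = y
  k <- max(3L, round(params$highpass_scale_um / px))
  if (k %% 2 == 0) k <- k + 1L
  bg <- box_mean(im, k)
  ks <- round(params$smooth_sigma_um / px)
  fg <- if (ks > 0) box_mean(im, 2L * ks + 1L) else im
  hp <- pmax(fg - bg, 0)
  bin <- hp >= params$intensity_threshold
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      x_mm = numeric(0), y_mm = numeric(0),
                      area_um2 = numeric(0), mean_intensity = numeric(0),
                      circularity = numeric(0),
                      equivalent_diameter_um = numeric(0))
  if (!any(bin)) return(empty)
  bin <- EBImage::fillHull(EBImage::Image(bin * 1)) # somata have no holes
  dm <- EBImage::distmap(bin)
  lab <- EBImage::watershed(dm, tolerance = params$watershed_tolerance,
                            ext = 1)
  labm <- EBImage::imageData(lab)       # x by y integer labels
  nlab <- max(labm)
  if (nlab == 0) return(empty)
  area_px <- tabulate(labm[labm > 0], nbins = nlab)
  mom <- EBImage::computeFeatures.moment(lab)
  x_px <- mom[, "m.cx"] - 1             # 0-based image coordinates
  y_px <- mom[, "m.cy"] - 1
  perim_px <- label_perimeters(labm)
  circ <- pmin(1, 4 * pi * area_px / perim_px^2)
  inten <- as.numeric(tapply(t(image)[labm > 0], labm[labm > 0], mean))
  eqd_um <- 2 * sqrt(area_px / pi) * px
  ic <- round(x_px) + 1L; ir <- round(y_px) + 1L
  inside <- ir >= 1 & ir <= nrow(geometry$mask) &
            ic >= 1 & ic <= ncol(geometry$mask)
  inside[inside] <- geometry$mask[cbind(ir[inside], ic[inside])]
  keep <- eqd_um >= params$min_diameter_um &
          eqd_um <= params$max_diameter_um &
          circ >= params$min_circularity & inside
  cells <- data.frame(x_px = x_px, y_px = y_px,
                      x_mm = x_px * px / 1000, y_mm = y_px * px / 1000,
                      area_um2 = area_px * px^2,
                      mean_intensity = inten,
                      circularity = circ,
                      equivalent_diameter_um = eqd_um)[keep, , drop = FALSE]
  cells <- cells[order(cells$y_px, cells$x_px), , drop = FALSE]
  rownames(cells) <- NULL
  cells
}

#' Whole-retina count and density summary
#'
#' @param cells Data frame from [detect_cells()].
#' @param geometry A [retina_geometry()].
#' @return List with `total_cells`, `retina_area_mm2`,
#'   `density_per_mm2` (count / area).
#' @export
count_summary <- function(cells, geometry) {
  stopifnot(inherits(geometry, "retina_geometry"))
  if (!(geometry$retina_area_mm2 > 0)) {
    stop("retina area is zero", call. = FALSE)
  }
  list(total_cells = nrow(cells),
       retina_area_mm2 = geometry$retina_area_mm2,
       density_per_mm2 = nrow(cells) / geometry$retina_area_mm2)
}
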
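#' Concentric-ring and quadrant sector grid
#'
#' The retina is partitioned into `n_rings` concentric annuli of width
#' `ring_width_mm` centred on the optic nerve head, each subdivided into the
#' four anatomical quadrants (Superior, Inferior, Nasal, Temporal), giving
#' `4 * n_rings` non-overlapping sectors (60 by default). Ring 1 is centred
#' on the ONH, ring `n_rings` on the periphery; anything beyond the last
#' ring is "out of grid" and reported, never dropped.
#'
#' Quadrant boundaries are the two diagonals at 45 degrees to the superior
#' axis, so each quadrant is a 90-degree wedge centred on an anatomical
#' axis. `orientation_deg` is the angle of the superior pole measured
#' counter-clockwise from the +x axis of whatever coordinate frame the cells
#' live in: 90 for mathematical (y-up) coordinates, 270 for image-frame mm
#' coordinates (y down, superior at the top of the image). Which lateral
#' wedge is Nasal versus Temporal depends on the eye: for a left eye the
#' wedge counter-clockwise of Superior is Temporal; for a right eye it is
#' Nasal.
#'
#' @param onh_xy_mm Optic-nerve-head centre `(a, b)` in mm, same frame as
#'   the cell coordinates.
#' @param ring_width_mm Annulus width; the default 0.3 mm puts the outer
#'   ring boundary at 4.5 mm, matching a whole rat retina.
#' @param n_rings Number of rings.
#' @param orientation_deg Angle of the superior axis (see Details).
#' @param eye `"left"` or `"right"`; mirrors the Nasal/Temporal wedges.
#' @return Object of class `sector_grid`.
#' @export
sector_grid <- function(onh_xy_mm = c(0, 0), ring_width_mm = 0.3,
                        n_rings = 15, orientation_deg = 90,
                        eye = c("left", "right")) {
  eye <- match.arg(eye)
  stopifnot(ring_width_mm > 0, n_rings >= 1, length(onh_xy_mm) == 2)
  labels_ccw <- if (eye == "left") {
    c("Superior", "Temporal", "Inferior", "Nasal")
  } else {
    c("Superior", "Nasal", "Inferior", "Temporal")
  }
  structure(list(onh_xy_mm = as.numeric(onh_xy_mm),
                 ring_width_mm = ring_width_mm,
                 n_rings = as.integer(n_rings),
                 orientation_deg = orientation_deg,
                 eye = eye,
                 quadrant_labels = c("Superior", "Inferior", "Nasal",
                                     "Temporal"),
                 labels_ccw = labels_ccw),
            class = "sector_grid")
}

#' Euclidean distance of cells from the optic nerve head
#'
#' `d = sqrt((x - a)^2 + (y - b)^2)` for each cell centroid `(x, y)` and
#' ONH centre `(a, b)`.
#'
#' @param cell_xy Data frame with `x_mm`/`y_mm` (or `x`/`y`) columns, mm.
#' @param onh_xy `(a, b)` in the same units.
#' @return Numeric vector of distances.
#' @export
radial_distance <- function(cell_xy, onh_xy) {
  xy <- as_xy(cell_xy)
  sqrt((xy$x - onh_xy[1])^2 + (xy$y - onh_xy[2])^2)
}

# Quadrant wedge index (0 = Superior, then counter-clockwise) for offsets
# (dx, dy) from the ONH. Two interchangeable implementations; both put each
# boundary diagonal in the wedge that follows it counter-clockwise, and both
# assign the degenerate point d = 0 to Superior by convention.
quadrant_wedge <- function(dx, dy, orientation_deg,
                           method = c("polar", "cartesian")) {
  method <- match.arg(method)
  if (method == "polar") {
    theta <- atan2(dy, dx) * 180 / pi
    alpha <- (theta - orientation_deg + 45) %% 360
    w <- as.integer(floor(alpha / 90)) %% 4L
  } else {
    # rotate so the superior axis is +y, then sign tests against the two
    # diagonal boundary lines y' = x' and y' = -x'
    phi <- (90 - orientation_deg) * pi / 180
    xr <- dx * cos(phi) - dy * sin(phi)
    yr <- dx * sin(phi) + dy * cos(phi)
    s1 <- yr - xr
    s2 <- yr + xr
    w <- integer(length(dx))
    w[s1 >= 0 & s2 > 0] <- 0L   # superior (includes its CCW-entering boundary)
    w[s1 > 0 & s2 <= 0] <- 1L
    w[s1 <= 0 & s2 < 0] <- 2L   # inferior
    w[s1 < 0 & s2 >= 0] <- 3L
  }
  w[dx == 0 & dy == 0] <- 0L
  w
}

#' Assign cells to ring/quadrant sectors
#'
#' Ring `k` holds cells whose ONH distance `d` satisfies
#' `(k-1)*w <= d < k*w` (half-open, so boundary cells are counted exactly
#' once); cells beyond the last ring get ring `NA` ("out of grid").
#' Quadrants are 90-degree wedges about the superior axis; wedge boundaries
#' belong to the counter-clockwise-following wedge.
#'
#' @param x_mm,y_mm Cell coordinates (mm), same frame as the grid.
#' @param grid A [sector_grid()].
#' @param method `"polar"` (angle gating) or `"cartesian"` (sign tests
#'   against the diagonal boundary lines); the two give identical results.
#' @return Data frame with `ring` (integer or `NA`) and `quadrant`
#'   (character) per cell.
#' @export
assign_sector <- function(x_mm, y_mm, grid, method = c("polar", "cartesian")) {
  stopifnot(inherits(grid, "sector_grid"))
  method <- match.arg(method)
  dx <- x_mm - grid$onh_xy_mm[1]
  dy <- y_mm - grid$onh_xy_mm[2]
  d <- sqrt(dx^2 + dy^2)
  ring <- as.integer(floor(d / grid$ring_width_mm)) + 1L
  ring[ring > grid$n_rings] <- NA_integer_
  w <- quadrant_wedge(dx, dy, grid$orientation_deg, method)
  data.frame(ring = ring, quadrant = grid$labels_ccw[w + 1L])
}

#' Sector areas from the retinal mask
#'
#' Pixel-counts the intersection of the retina mask with every ring/quadrant
#' sector. Because every mask pixel is assigned to exactly one sector (or to
#' out-of-grid), sector areas plus the out-of-grid area equal the total mask
#' area exactly.
#'
#' @param geometry A [retina_geometry()].
#' @param grid A [sector_grid()] in image-frame mm coordinates (i.e. built
#'   with the ONH position from `geometry` and `orientation_deg = 270` for a
#'   superior-up image).
#' @return Data frame with `ring`, `quadrant`, `area_mm2`
#'   (`4 * n_rings` rows), with attributes `out_of_grid_mm2` and
#'   `total_mm2`.
#' @export
sector_areas <- function(geometry, grid) {
  stopifnot(inherits(geometry, "retina_geometry"),
            inherits(grid, "sector_grid"))
  mask <- geometry$mask
  px_mm <- geometry$pixel_size_um / 1000
  idx <- which(mask)
  nr <- nrow(mask)
  counts <- matrix(0, grid$n_rings, 4)
  out_px <- 0
  for (start in seq(1, length(idx), by = 2e6)) {
    ii <- idx[start:min(length(idx), start + 2e6 - 1)]
    row <- (ii - 1L) %% nr
    col <- (ii - 1L) %/% nr
    x_mm <- col * px_mm
    y_mm <- row * px_mm
    s <- assign_sector(x_mm, y_mm, grid)
    oog <- is.na(s$ring)
    out_px <- out_px + sum(oog)
    if (any(!oog)) {
      qi <- match(s$quadrant[!oog], grid$labels_ccw)
      tab <- table(factor(s$ring[!oog], levels = seq_len(grid$n_rings)),
                   factor(qi, levels = 1:4))
      counts <- counts + unclass(tab)
    }
  }
  out <- expand.grid(ring = seq_len(grid$n_rings),
                     quadrant = grid$labels_ccw,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$area_mm2 <- as.vector(counts) * px_mm^2
  attr(out, "out_of_grid_mm2") <- out_px * px_mm^2
  attr(out, "total_mm2") <- length(idx) * px_mm^2
  out
}

#' Per-sector counts, density, NND and regularity index
#'
#' Builds the per-sector summary table: cell count, mask area, density
#' (count / area), mean nearest-neighbour distance (NNDs computed globally
#' against the full retina cell set, then averaged over the cells falling in
#' the sector — they are not recomputed within the sector), and the
#' regularity index from the within-sector mean and SD of those global NNDs.
#' Sectors with fewer than 3 cells report an undefined (`NA`) RI.
#'
#' @param cells Data frame with `x_mm`, `y_mm` (image-frame mm).
#' @param geometry A [retina_geometry()].
#' @param grid A [sector_grid()].
#' @param nnd Optional vector of per-cell NNDs (micrometres) aligned with
#'   `cells`; computed with [nearest_neighbour_distances()] if omitted.
#' @return Data frame with one row per sector: `ring`, `quadrant`,
#'   `cell_count`, `area_mm2`, `density_per_mm2`, `mean_nnd_um`, `ri`;
#'   attributes `out_of_grid_cells` and `out_of_grid_mm2`.
#' @export
sector_table <- function(cells, geometry, grid, nnd = NULL) {
  stopifnot(inherits(grid, "sector_grid"))
  if (is.null(nnd) && nrow(cells) >= 2) {
    nnd <- nearest_neighbour_distances(cells)
  }
  if (!is.null(nnd) && length(nnd) != nrow(cells)) {
    stop("nnd must align with cells", call. = FALSE)
  }
  areas <- sector_areas(geometry, grid)
  s <- assign_sector(cells$x_mm, cells$y_mm, grid)
  key <- paste(s$ring, s$quadrant)
  akey <- paste(areas$ring, areas$quadrant)
  out <- areas
  out$cell_count <- as.integer(table(factor(key, levels = akey)))
  out$density_per_mm2 <- ifelse(out$area_mm2 > 0,
                                out$cell_count / out$area_mm2, 0)
  bad <- out$area_mm2 == 0 & out$cell_count > 0
  if (any(bad)) {
    stop(sprintf("sector ring %d %s has cells but zero mask area: geometry inconsistent",
                 out$ring[which(bad)[1]], out$quadrant[which(bad)[1]]),
         call. = FALSE)
  }
  out$mean_nnd_um <- NA_real_
  out$ri <- NA_real_
  if (!is.null(nnd)) {
    grp <- split(nnd, factor(key, levels = akey))
    out$mean_nnd_um <- vapply(grp, function(v)
      if (length(v) > 0) mean(v) else NA_real_, numeric(1))
    out$ri <- vapply(grp, function(v) {
      if (length(v) < 3) return(NA_real_)
      sdv <- sd(v)
      if (sdv == 0) NA_real_ else mean(v) / sdv
    }, numeric(1))
  }
  out <- out[, c("ring", "quadrant", "cell_count", "area_mm2",
                 "density_per_mm2", "mean_nnd_um", "ri")]
  attr(out, "out_of_grid_cells") <- sum(is.na(s$ring))
  attr(out, "out_of_grid_mm2") <- attr(areas, "out_of_grid_mm2")
  attr(out, "total_mm2") <- attr(areas, "total_mm2")
  out
}

#' Nearest-neighbour-distance colour map
#'
#' Scatter data and figure mapping each cell's NND to colour, with small
#' NNDs (dense regions) at the warm (red) end of the scale and large NNDs
#' (depleted regions) towards green/blue.
#'
#' @param cells Data frame with `x_mm`, `y_mm`.
#' @param nnd Per-cell NND vector (micrometres), aligned with `cells`.
#' @return List with `data` (data frame `x_mm`, `y_mm`, `nnd_um`) and
#'   `plot` (a ggplot).
#' @export
nnd_colormap_export <- function(cells, nnd) {
  if (length(nnd) != nrow(cells)) stop("nnd must align with cells",
                                       call. = FALSE)
  d <- data.frame(x_mm = cells$x_mm, y_mm = cells$y_mm, nnd_um = nnd)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                                       colour = .data$nnd_um)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_colour_gradientn(
      colours = c("red", "orange", "yellow", "green", "blue"),
      name = "NND (µm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
  list(data = d, plot = p)
}
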
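#' Specify a synthetic retinal ganglion cell mosaic
#'
#' A `mosaic_spec` describes the point process used to generate a ground-truth
#' RGC mosaic: a disc-shaped field (the flattened whole-mount), a target cell
#' density, an optional hard-core exclusion radius (soma-to-soma minimum
#' spacing, which produces the quasi-regular "mosaic" arrangement real RGC
#' populations show), and an optional linear centre-to-periphery density
#' gradient.
#'
#' With `exclusion_radius_um = 0` the mosaic is a homogeneous Poisson process,
#' whose regularity index converges to `0.5 * sqrt(4 * pi / (4 - pi))`
#' (about 1.913) — the classical "random arrangement" reference value near
#' 1.9. With a positive exclusion radius the points are a Matérn type-II
#' hard-core process, which raises the regularity index towards the 2.5-3
#' range typical of healthy RGC mosaics.
#'
#' @param field_radius_mm Radius of the disc-shaped retinal field in mm.
#' @param onh_xy_mm Optic-nerve-head centre in retina-centred mm coordinates
#'   (x right, y towards the superior pole).
#' @param target_density_per_mm2 Desired cell density within the disc.
#' @param exclusion_radius_um Minimum centre-to-centre spacing in micrometres;
#'   `0` gives a homogeneous Poisson process.
#' @param density_gradient Scalar in `[0, 1]`; local intensity falls linearly
#'   by this fraction from the field centre to the rim while preserving the
#'   overall target density.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return An object of class `mosaic_spec`.
#' @seealso [generate_mosaic()], [render_image()]
#' @export
mosaic_spec <- function(field_radius_mm = 4.1,
                        onh_xy_mm = c(0, 0),
                        target_density_per_mm2 = 1695,
                        exclusion_radius_um = 12,
                        density_gradient = 0,
                        seed = NULL) {
  stopifnot(field_radius_mm > 0, target_density_per_mm2 >= 0,
            exclusion_radius_um >= 0, length(onh_xy_mm) == 2,
            density_gradient >= 0, density_gradient <= 1)
  structure(list(field_radius_mm = field_radius_mm,
                 onh_xy_mm = as.numeric(onh_xy_mm),
                 target_density_per_mm2 = target_density_per_mm2,
                 exclusion_radius_um = exclusion_radius_um,
                 density_gradient = density_gradient,
                 seed = seed),
            class = "mosaic_spec")
}

#' @export
print.mosaic_spec <- function(x, ...) {
  cat("Mosaic spec: disc radius", x$field_radius_mm, "mm,",
      x$target_density_per_mm2, "cells/mm^2,",
      if (x$exclusion_radius_um > 0)
        paste0("hard core ", x$exclusion_radius_um, " um")
      else "Poisson (no hard core)",
      if (x$density_gradient > 0)
        paste0(", gradient ", x$density_gradient) else "", "\n")
  invisible(x)
}

# Uniform points in a disc of radius R (mm), via sqrt-radius sampling.
runif_disc <- function(n, radius) {
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  data.frame(x_mm = r * cos(th), y_mm = r * sin(th))
}

#' Generate a ground-truth cell mosaic
#'
#' Draws a point set from the process described by a [mosaic_spec()].
#' Hard-core mosaics use Matérn type-II dependent thinning with an exact
#' closed-form proposal-intensity correction so the *achieved* density matches
#' the target: for retention probability
#' `p = (1 - exp(-lambda_p * K)) / (lambda_p * K)` with `K = pi * r^2`, the
#' proposal intensity solving `lambda = lambda_p * p` is
#' `lambda_p = -log(1 - lambda * K) / K`, which exists only below the
#' theoretical hard-core maximum `1 / (pi * r^2)`.
#'
#' @param spec A [mosaic_spec()].
#' @return A data frame with columns `x_mm`, `y_mm` (retina-centred mm),
#'   carrying attributes `achieved_density_per_mm2`, `spec` and `seed`.
#' @export
#' @examples
#' pts <- generate_mosaic(mosaic_spec(field_radius_mm = 1,
#'   target_density_per_mm2 = 500, exclusion_radius_um = 0, seed = 1))
#' nrow(pts) / (pi * 1^2)  # close to 500
generate_mosaic <- function(spec) {
  stopifnot(inherits(spec, "mosaic_spec"))
  R <- spec$field_radius_mm
  g <- spec$density_gradient
  area <- pi * R^2
  # peak (centre) intensity giving the target disc-average density:
  # mean over the disc of (1 - g*d/R) is (1 - 2g/3)
  lam_max <- spec$target_density_per_mm2 / (1 - 2 * g / 3)
  pts <- with_seed(spec$seed, {
    if (lam_max == 0) {
      data.frame(x_mm = numeric(0), y_mm = numeric(0))
    } else if (spec$exclusion_radius_um > 0) {
      r_mm <- spec$exclusion_radius_um / 1000
      K <- pi * r_mm^2
      if (lam_max * K >= 1) {
        stop(sprintf(paste0("requested density %.1f/mm^2 exceeds the Matern II ",
                            "hard-core maximum 1/(pi*r^2) = %.1f/mm^2 for an ",
                            "exclusion radius of %g um"),
                     lam_max, 1 / K, spec$exclusion_radius_um), call. = FALSE)
      }
      lam_p <- -log(1 - lam_max * K) / K
      prop <- runif_disc(rpois(1, lam_p * area), R)
      if (nrow(prop) > 1) {
        marks <- runif(nrow(prop))
        prop <- prop[.matern_keep(prop$x_mm, prop$y_mm, marks, r_mm), ,
                     drop = FALSE]
      }
      prop
    } else {
      runif_disc(rpois(1, lam_max * area), R)
    }
  })
  if (g > 0 && nrow(pts) > 0) {
    pts <- with_seed(if (is.null(spec$seed)) NULL else spec$seed + 1L, {
      d <- sqrt(pts$x_mm^2 + pts$y_mm^2)
      pts[runif(nrow(pts)) < 1 - g * d / R, , drop = FALSE]
    })
  }
  rownames(pts) <- NULL
  attr(pts, "achieved_density_per_mm2") <- nrow(pts) / area
  attr(pts, "spec") <- spec
  attr(pts, "seed") <- spec$seed
  pts
}

#' Describe a regional cell-loss pattern
#'
#' `loss_pattern` parameterises simulated degeneration applied to a
#' ground-truth mosaic. Diffuse loss removes each in-region cell
#' independently (mimicking primary degeneration's spatially uniform
#' thinning); clustered loss deletes whole discs of cells around random foci
#' (the patchy dropout associated with secondary degeneration), which skews
#' the nearest-neighbour-distance distribution to the right.
#'
#' @param mode One of `"diffuse"`, `"clustered"`, `"none"`.
#' @param fraction_removed Target fraction of in-region cells removed, in
#'   `[0, 1]`.
#' @param region `NULL` for the whole retina, or a predicate
#'   `function(x_mm, y_mm)` returning a logical vector selecting in-region
#'   cells (see [sector_region()]).
#' @param cluster_radius_um Lesion disc radius, required for clustered mode.
#' @param seed Integer seed.
#' @return An object of class `loss_pattern`.
#' @export
loss_pattern <- function(mode = c("diffuse", "clustered", "none"),
                         fraction_removed = 0,
                         region = NULL,
                         cluster_radius_um = 150,
                         seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(fraction_removed >= 0, fraction_removed <= 1)
  if (mode == "clustered" && !(cluster_radius_um > 0)) {
    stop("clustered mode requires cluster_radius_um > 0", call. = FALSE)
  }
  if (!is.null(region) && !is.function(region)) {
    stop("region must be NULL or a function(x_mm, y_mm)", call. = FALSE)
  }
  structure(list(mode = mode, fraction_removed = fraction_removed,
                 region = region, cluster_radius_um = cluster_radius_um,
                 seed = seed),
            class = "loss_pattern")
}

#' Region predicate for a set of grid sectors
#'
#' Builds a `function(x_mm, y_mm)` selecting cells that fall in the given
#' rings and quadrants of a [sector_grid()], for use as the `region` of a
#' [loss_pattern()].
#'
#' @param grid A [sector_grid()].
#' @param rings Integer vector of ring indices (default: all rings).
#' @param quadrants Character vector of quadrant labels (default: all).
#' @return A predicate function.
#' @export
sector_region <- function(grid, rings = seq_len(grid$n_rings),
                          quadrants = grid$quadrant_labels) {
  force(grid); force(rings); force(quadrants)
  function(x_mm, y_mm) {
    s <- assign_sector(x_mm, y_mm, grid)
    !is.na(s$ring) & s$ring %in% rings & s$quadrant %in% quadrants
  }
}

#' Remove cells from a mosaic according to a loss pattern
#'
#' Diffuse mode removes each in-region point independently with probability
#' `fraction_removed`. Clustered mode nucleates lesion discs of radius
#' `cluster_radius_um` at randomly chosen surviving in-region cells, deleting
#' every in-region cell inside each disc, until the removed in-region
#' fraction first reaches or exceeds `fraction_removed`. Out-of-region points
#' are returned untouched.
#'
#' @param points Data frame with `x_mm`, `y_mm` columns.
#' @param pattern A [loss_pattern()].
#' @return The surviving points (same columns), with attribute
#'   `removed_fraction` (realised in-region fraction removed) and `seed`.
#' @export
apply_loss <- function(points, pattern) {
  stopifnot(inherits(pattern, "loss_pattern"))
  if (pattern$mode == "none" || pattern$fraction_removed == 0 ||
      nrow(points) == 0) {
    attr(points, "removed_fraction") <- 0
    return(points)
  }
  in_region <- if (is.null(pattern$region)) rep(TRUE, nrow(points)) else
    pattern$region(points$x_mm, points$y_mm)
  n_in <- sum(in_region)
  if (n_in == 0) {
    attr(points, "removed_fraction") <- 0
    return(points)
  }
  drop <- with_seed(pattern$seed, {
    if (pattern$mode == "diffuse") {
      in_region & runif(nrow(points)) < pattern$fraction_removed
    } else {
      r_mm <- pattern$cluster_radius_um / 1000
      dead <- rep(FALSE, nrow(points))
      idx_in <- which(in_region)
      while (sum(dead[idx_in]) < pattern$fraction_removed * n_in) {
        alive <- idx_in[!dead[idx_in]]
        if (length(alive) == 0) break
        focus <- if (length(alive) == 1) alive else sample(alive, 1)
        d2 <- (points$x_mm - points$x_mm[focus])^2 +
              (points$y_mm - points$y_mm[focus])^2
        dead <- dead | (in_region & d2 <= r_mm^2)
      }
      dead
    }
  })
  out <- points[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_fraction") <- sum(drop) / n_in
  attr(out, "seed") <- pattern$seed
  out
}

#' Render a mosaic to an 8-bit whole-mount image
#'
#' Emulates a maximum-projection image of a labelled whole-mount: each cell
#' becomes a radially symmetric soft-edged disc (a super-Gaussian profile
#' `exp(-(r^2 / (2 sigma^2))^3)`, i.e. a flat top with a ~2 micrometre skirt,
#' as filled stained nuclei appear) whose full width at half maximum equals
#' `soma_diameter_um`. Additive clipped Gaussian noise is applied inside the
#' retinal disc, and everything outside the disc is set to a flat level
#' *above* the retinal-mask threshold so that low-intensity mask extraction
#' (the retina is the dark region) behaves as on real images.
#'
#' @param points Data frame of cell centres (`x_mm`, `y_mm`, retina-centred,
#'   y towards superior).
#' @param pixel_size_um Calibration, micrometres per pixel.
#' @param soma_diameter_um Blob FWHM in micrometres.
#' @param peak_intensity Blob peak grey level (0-255); must exceed the
#'   downstream detection threshold to be detectable. The default 230 (near
#'   saturation, as for constant-exposure nuclear staining) makes the
#'   above-threshold cross-section of a default blob close to its nominal
#'   diameter under the default detection chain.
#' @param background_sd Standard deviation of the additive Gaussian noise
#'   (grey levels) inside the disc.
#' @param field_radius_mm Disc radius; defaults to the generating spec stored
#'   on `points`, if any.
#' @param onh_xy_mm Optic-nerve-head centre in the same coordinates.
#' @param outside_level Grey level outside the disc (must exceed the mask
#'   threshold used by [make_retina_mask()]).
#' @param seed Integer seed for the noise.
#' @return An object of class `synthetic_retina`: list with `points`,
#'   `image` (integer matrix, rows = y, cols = x, 0-255), `pixel_size_um`,
#'   and `geometry` (a [retina_geometry()]).
#' @export
render_image <- function(points, pixel_size_um = 1,
                         soma_diameter_um = 12,
                         peak_intensity = 230,
                         background_sd = 0,
                         field_radius_mm = NULL,
                         onh_xy_mm = NULL,
                         outside_level = 30,
                         seed = NULL) {
  spec <- attr(points, "spec")
  field_radius_mm <- field_radius_mm %||% spec$field_radius_mm
  onh_xy_mm <- onh_xy_mm %||% (spec$onh_xy_mm %||% c(0, 0))
  if (is.null(field_radius_mm)) stop("field_radius_mm required", call. = FALSE)
  stopifnot(pixel_size_um > 0, peak_intensity >= 0, peak_intensity <= 255)
  R_px <- field_radius_mm * 1000 / pixel_size_um
  half <- ceiling(R_px)
  n <- 2L * half + 1L          # square raster, centre pixel (half+1, half+1)
  ctr <- half + 1L
  if (nrow(points) > 0 &&
      any(abs(points$x_mm) > field_radius_mm |
          abs(points$y_mm) > field_radius_mm)) {
    stop("points outside the raster bounds", call. = FALSE)
  }
  img <- matrix(0, n, n)
  if (nrow(points) > 0) {
    # FWHM of exp(-(r^2/(2 s^2))^3) is 2*sqrt(2)*log(2)^(1/6)*s
    sigma <- (soma_diameter_um / pixel_size_um) / (2 * sqrt(2) * log(2)^(1 / 6))
    w <- ceiling(2.2 * sigma)
    off <- (-w):w
    # column (x) and row (y) of each cell; image y runs downwards
    cx <- ctr + points$x_mm * 1000 / pixel_size_um
    cy <- ctr - points$y_mm * 1000 / pixel_size_um
    for (i in seq_len(nrow(points))) {
      jc <- round(cx[i]); ir <- round(cy[i])
      cols <- jc + off; rows <- ir + off
      okc <- cols >= 1 & cols <= n; okr <- rows >= 1 & rows <= n
      dx2 <- (cols[okc] - cx[i])^2
      dy2 <- (rows[okr] - cy[i])^2
      blob <- peak_intensity *
        exp(-(outer(dy2, dx2, "+") / (2 * sigma^2))^3)
      img[rows[okr], cols[okc]] <- img[rows[okr], cols[okc]] + blob
    }
  }
  xs <- (seq_len(n) - ctr) * pixel_size_um / 1000
  inside <- outer(xs^2, xs^2, "+") <= field_radius_mm^2  # rows=y, cols=x
  if (background_sd > 0) {
    img <- img + with_seed(seed, matrix(rnorm(n * n, 0, background_sd), n, n))
  }
  img[!inside] <- outside_level
  img <- matrix(as.integer(pmin(255, pmax(0, round(img)))), n, n)
  onh_px <- c(x = ctr - 1 + onh_xy_mm[1] * 1000 / pixel_size_um,
              y = ctr - 1 - onh_xy_mm[2] * 1000 / pixel_size_um)
  geometry <- retina_geometry(inside, pixel_size_um, onh_px)
  structure(list(points = points, image = img,
                 pixel_size_um = pixel_size_um,
                 geometry = geometry, spec = spec, seed = seed),
            class = "synthetic_retina")
}

#' Simulate a complete synthetic retina
#'
#' Convenience wrapper: [generate_mosaic()], optionally [apply_loss()], then
#' [render_image()].
#'
#' @param spec A [mosaic_spec()].
#' @param loss Optional [loss_pattern()].
#' @param ... Passed to [render_image()].
#' @return A `synthetic_retina` object.
#' @export
simulate_retina <- function(spec, loss = NULL, ...) {
  pts <- generate_mosaic(spec)
  if (!is.null(loss)) pts <- apply_loss(pts, loss)
  render_image(pts, ...)
}

#' Write synthetic ground truth to disk
#'
#' Ground-truth centres go to CSV (`x_mm`, `y_mm`), the rendered image to
#' single-channel 8-bit TIFF, and the generating spec to a flat YAML config.
#'
#' @param retina A `synthetic_retina` object.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Invisibly, the paths written.
#' @export
write_synthetic_retina <- function(retina, dir, stem = "synthetic") {
  stopifnot(inherits(retina, "synthetic_retina"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(points = file.path(dir, paste0(stem, "_points.csv")),
             image = file.path(dir, paste0(stem, ".tif")),
             spec = file.path(dir, paste0(stem, "_spec.yaml")))
  write.csv(retina$points, paths["points"], row.names = FALSE)
  write_image_tiff(retina$image, paths["image"])
  sp <- retina$spec
  if (!is.null(sp)) {
    yaml::write_yaml(list(field_radius_mm = sp$field_radius_mm,
                          onh_x_mm = sp$onh_xy_mm[1], onh_y_mm = sp$onh_xy_mm[2],
                          target_density_per_mm2 = sp$target_density_per_mm2,
                          exclusion_radius_um = sp$exclusion_radius_um,
                          density_gradient = sp$density_gradient,
                          seed = sp$seed,
                          pixel_size_um = retina$pixel_size_um),
                     paths["spec"])
  }
  invisible(paths)
}
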
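test_that("radial distance is the Euclidean hypotenuse", {
  expect_identical(radial_distance(data.frame(x_mm = 3, y_mm = 4), c(0, 0)),
                   5)
  expect_identical(radial_distance(data.frame(x_mm = 1, y_mm = 2), c(1, 2)),
                   0)
  set.seed(51)
  xy <- data.frame(x_mm = runif(100, -5, 5), y_mm = runif(100, -5, 5))
  onh <- c(0.3, -0.7)
  expect_equal(radial_distance(xy, onh),
               sqrt((xy$x_mm - onh[1])^2 + (xy$y_mm - onh[2])^2))
})

test_that("ring gating is half-open on ring boundaries", {
  g <- sector_grid(ring_width_mm = 0.3, n_rings = 15)
  at <- function(x, y) assign_sector(x, y, g)$ring
  expect_identical(at(0, 0), 1L)
  expect_identical(at(0.45, 0), 2L)        # 0.3 <= 0.45 < 0.6
  expect_identical(at(0.3, 0), 2L)         # boundary joins the outer ring
  expect_identical(at(4.5, 0), NA_integer_)  # beyond ring 15: out of grid
  expect_identical(at(4.4999, 0), 15L)
})

test_that("polar and Cartesian quadrant gating give identical results", {
  set.seed(52)
  for (orientation in c(90, 270, 33)) {
    g <- sector_grid(onh_xy_mm = c(0.2, -0.1), orientation_deg = orientation)
    x <- runif(10000, -4, 4); y <- runif(10000, -4, 4)
    pol <- assign_sector(x, y, g, method = "polar")
    car <- assign_sector(x, y, g, method = "cartesian")
    expect_identical(pol, car)
    # every cell lands in exactly one sector (or out of grid), never none
    expect_true(all(pol$quadrant %in% g$quadrant_labels))
  }
})

test_that("quadrant wedges sit on the anatomical axes", {
  g <- sector_grid(orientation_deg = 90, eye = "left")
  q <- function(x, y) assign_sector(x, y, g)$quadrant
  expect_identical(q(0, 1), "Superior")
  expect_identical(q(0, -1), "Inferior")
  expect_identical(q(1, 0), "Nasal")       # left eye: nasal on +x
  expect_identical(q(-1, 0), "Temporal")
  gr <- sector_grid(orientation_deg = 90, eye = "right")
  expect_identical(assign_sector(1, 0, gr)$quadrant, "Temporal")
  # boundary diagonal belongs to the counter-clockwise-following wedge
  expect_identical(q(1, 1), "Superior")
  expect_identical(q(-1, 1), "Temporal")
  expect_identical(q(-1, -1), "Inferior")
  expect_identical(q(1, -1), "Nasal")
})

test_that("sector assignment is rotation-equivariant", {
  set.seed(53)
  r <- sqrt(runif(5000)) * 4.6              # includes out-of-grid cells
  th <- runif(5000, 0, 2 * pi)
  x <- r * cos(th); y <- r * sin(th)
  g0 <- sector_grid(orientation_deg = 90)
  phi <- 33 * pi / 180
  g1 <- sector_grid(orientation_deg = 90 + 33)
  s0 <- assign_sector(x, y, g0)
  s1 <- assign_sector(x * cos(phi) - y * sin(phi),
                      x * sin(phi) + y * cos(phi), g1)
  expect_identical(table(s0$ring, s0$quadrant), table(s1$ring, s1$quadrant))
})

test_that("sector areas match the analytic annulus quadrants", {
  # full-disc mask of radius 15 rings x 0.3 mm, ONH at the centre
  geom <- disc_geometry(4.5, pixel_size_um = 5)
  grid <- sector_grid(onh_xy_mm = geom$onh_xy_mm, ring_width_mm = 0.3)
  areas <- sector_areas(geom, grid)
  expect_identical(nrow(areas), 60L)
  w <- 0.3
  analytic <- pi * ((areas$ring * w)^2 - ((areas$ring - 1) * w)^2) / 4
  expect_true(all(abs(areas$area_mm2 / analytic - 1) < 0.01))
  expect_true(all(areas$area_mm2 >= 0))
})

test_that("sector areas partition any mask exactly", {
  set.seed(54)
  mask <- matrix(runif(300 * 300) < 0.4, 300, 300)  # arbitrary ragged mask
  mask[150, 150] <- TRUE
  suppressWarnings(geom <- retina_geometry(mask, 40, c(149, 149)))
  grid <- sector_grid(onh_xy_mm = geom$onh_xy_mm, ring_width_mm = 0.5,
                      n_rings = 6)
  areas <- sector_areas(geom, grid)
  expect_equal(sum(areas$area_mm2) + attr(areas, "out_of_grid_mm2"),
               geom$retina_area_mm2, tolerance = 1e-12)
})

test_that("sector table aggregates counts, densities, NND and RI", {
  spec <- mosaic_spec(field_radius_mm = 1.5, target_density_per_mm2 = 1700,
                      exclusion_radius_um = 12, seed = 55)
  pts <- generate_mosaic(spec)
  geom <- disc_geometry(1.5, pixel_size_um = 5)
  grid <- sector_grid(onh_xy_mm = geom$onh_xy_mm, ring_width_mm = 0.5,
                      n_rings = 3)
  cells <- centre_cells(pts, geom)
  nnd <- nearest_neighbour_distances(pts)
  tab <- sector_table(cells, geom, grid, nnd)
  expect_identical(nrow(tab), 12L)
  expect_identical(sum(tab$cell_count) + attr(tab, "out_of_grid_cells"),
                   nrow(cells))
  # uniform mosaic: all sector densities near the target
  expect_true(all(abs(tab$density_per_mm2 / 1700 - 1) < 0.10))
  # density = count / area row-wise
  expect_equal(tab$density_per_mm2, tab$cell_count / tab$area_mm2)
  expect_true(all(tab$ri > 2 | is.na(tab$ri)))
})

test_that("sectors without cells report zero density and undefined RI", {
  geom <- disc_geometry(1, pixel_size_um = 10)
  grid <- sector_grid(onh_xy_mm = geom$onh_xy_mm, ring_width_mm = 0.3,
                      n_rings = 3)
  cells <- centre_cells(data.frame(x_mm = c(0.02, -0.03, 0.01),
                                   y_mm = c(0.01, 0.02, -0.04)), geom)
  tab <- sector_table(cells, geom, grid,
                      nnd = nearest_neighbour_distances(cells))
  empty <- tab[tab$ring > 1, ]
  expect_true(all(empty$cell_count == 0))
  expect_true(all(empty$density_per_mm2 == 0))
  expect_true(all(is.na(empty$mean_nnd_um)))
  expect_true(all(is.na(empty$ri)))
})

test_that("cells in a zero-area sector flag a geometry inconsistency", {
  geom <- disc_geometry(0.25, pixel_size_um = 10)   # mask ends at ring 1
  grid <- sector_grid(onh_xy_mm = geom$onh_xy_mm, ring_width_mm = 0.3,
                      n_rings = 3)
  cells <- centre_cells(data.frame(x_mm = 0.5, y_mm = 0), geom)  # ring 2
  expect_error(sector_table(cells, geom, grid, nnd = NULL),
               "zero mask area")
})

test_that("clustered loss confined to one quadrant depresses its density", {
  spec <- mosaic_spec(field_radius_mm = 1, target_density_per_mm2 = 1700,
                      exclusion_radius_um = 12, seed = 57)
  pts <- generate_mosaic(spec)
  grid0 <- sector_grid(ring_width_mm = 0.3, n_rings = 3)  # retina-centred
  lesioned <- apply_loss(pts, loss_pattern(
    "clustered", 0.5, region = sector_region(grid0, quadrants = "Superior"),
    cluster_radius_um = 120, seed = 58))
  geom <- disc_geometry(1, pixel_size_um = 5)
  grid <- sector_grid(onh_xy_mm = geom$onh_xy_mm, ring_width_mm = 0.3,
                      n_rings = 3)
  tab <- sector_table(centre_cells(lesioned, geom), geom, grid, nnd = NULL)
  sup <- tab[tab$quadrant == "Superior", ]
  inf <- tab[tab$quadrant == "Inferior", ]
  expect_true(all(sup$density_per_mm2[order(sup$ring)] <
                    inf$density_per_mm2[order(inf$ring)]))
})

test_that("NND colour-map export round-trips and orders colours by NND", {
  cells <- data.frame(x_mm = c(0, 1, 2), y_mm = c(0, 0.5, 1))
  nnd <- c(25, 5, 14)
  out <- nnd_colormap_export(cells, nnd)
  expect_identical(nrow(out$data), 3L)
  expect_s3_class(out$plot, "ggplot")
  expect_identical(out$data$nnd_um, nnd)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(out$data, path, row.names = FALSE)
  back <- utils::read.csv(path)
  expect_equal(back, out$data)
  expect_error(nnd_colormap_export(cells, 1:2), "align")
})
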
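test_that("Poisson mosaic density matches intensity x area", {
  spec <- mosaic_spec(field_radius_mm = 1, target_density_per_mm2 = 1700,
                      exclusion_radius_um = 0, seed = 1)
  pts <- generate_mosaic(spec)
  expected <- 1700 * pi * 1^2
  expect_lt(abs(nrow(pts) - expected), 4 * sqrt(expected))
  expect_lt(abs(attr(pts, "achieved_density_per_mm2") / 1700 - 1), 0.05)
  expect_true(all(pts$x_mm^2 + pts$y_mm^2 <= 1))
})

test_that("zero density gives an empty point set", {
  pts <- generate_mosaic(mosaic_spec(target_density_per_mm2 = 0, seed = 1))
  expect_identical(nrow(pts), 0L)
})

test_that("generation is deterministic given the seed", {
  s <- mosaic_spec(field_radius_mm = 0.8, target_density_per_mm2 = 800,
                   exclusion_radius_um = 12, seed = 42)
  expect_identical(generate_mosaic(s), generate_mosaic(s))
  s2 <- s; s2$seed <- 43
  expect_false(nrow(generate_mosaic(s)) == nrow(generate_mosaic(s2)) &&
                 isTRUE(all.equal(generate_mosaic(s)$x_mm,
                                  generate_mosaic(s2)$x_mm)))
})

test_that("infeasible hard-core packing errors with the theoretical bound", {
  # 1/(pi * 0.012^2) ~ 2210 per mm^2 is the Matern II ceiling at 12 um
  spec <- mosaic_spec(target_density_per_mm2 = 3000,
                      exclusion_radius_um = 12, seed = 1)
  expect_error(generate_mosaic(spec), "hard-core maximum")
  expect_error(generate_mosaic(spec), "2210")
})

test_that("hard-core mosaic respects the exclusion radius and is regular", {
  spec <- mosaic_spec(field_radius_mm = 1, target_density_per_mm2 = 1700,
                      exclusion_radius_um = 12, seed = 7)
  pts <- generate_mosaic(spec)
  nnd <- nnd_bruteforce(pts)
  expect_gte(min(nnd), 12)
  expect_gt(mean(nnd) / sd(nnd), 2.5)   # well above the Poisson ~1.91
  expect_lt(abs(attr(pts, "achieved_density_per_mm2") / 1700 - 1), 0.05)
})

test_that("Poisson regularity index and mean NND match closed forms", {
  spec <- mosaic_spec(field_radius_mm = 2, target_density_per_mm2 = 1700,
                      exclusion_radius_um = 0, seed = 5)
  pts <- generate_mosaic(spec)
  nnd <- nearest_neighbour_distances(pts)
  expect_lt(abs(regularity_index(nnd) - RI_POISSON), 0.05)
  expect_lt(abs(mean(nnd) / (0.5 / sqrt(1700) * 1000) - 1), 0.02)
})

test_that("density gradient thins periphery but preserves overall density", {
  spec <- mosaic_spec(field_radius_mm = 2, target_density_per_mm2 = 1000,
                      exclusion_radius_um = 0, density_gradient = 0.8,
                      seed = 9)
  pts <- generate_mosaic(spec)
  expect_lt(abs(attr(pts, "achieved_density_per_mm2") / 1000 - 1), 0.05)
  d <- sqrt(pts$x_mm^2 + pts$y_mm^2)
  inner <- sum(d < 1) / (pi * 1)            # density in the inner disc
  outer_d <- sum(d >= 1) / (pi * (4 - 1))
  expect_gt(inner, 1.3 * outer_d)           # centre clearly denser
})

test_that("apply_loss trivial fractions behave exactly", {
  spec <- mosaic_spec(field_radius_mm = 1.5, target_density_per_mm2 = 1500,
                      exclusion_radius_um = 0, seed = 3)
  pts <- generate_mosaic(spec)
  none <- apply_loss(pts, loss_pattern("diffuse", 0, seed = 1))
  expect_equal(none$x_mm, pts$x_mm)
  all_gone <- apply_loss(pts, loss_pattern("diffuse", 1, seed = 1))
  expect_identical(nrow(all_gone), 0L)
})

test_that("diffuse loss removes a binomial fraction", {
  spec <- mosaic_spec(field_radius_mm = 1.4, target_density_per_mm2 = 1700,
                      exclusion_radius_um = 0, seed = 11)
  pts <- generate_mosaic(spec)          # ~10,500 points
  kept <- apply_loss(pts, loss_pattern("diffuse", 0.5, seed = 2))
  expect_lt(abs(nrow(kept) - 0.5 * nrow(pts)), 4 * sqrt(0.25 * nrow(pts)))
})

test_that("loss conserves out-of-region points exactly", {
  spec <- mosaic_spec(field_radius_mm = 1.2, target_density_per_mm2 = 1200,
                      exclusion_radius_um = 0, seed = 13)
  pts <- generate_mosaic(spec)
  right_half <- function(x_mm, y_mm) x_mm > 0
  for (mode in c("diffuse", "clustered")) {
    kept <- apply_loss(pts, loss_pattern(mode, 0.6, region = right_half,
                                         cluster_radius_um = 100, seed = 4))
    out_before <- pts[pts$x_mm <= 0, ]
    out_after <- kept[kept$x_mm <= 0, ]
    expect_identical(unname(as.matrix(out_after)),
                     unname(as.matrix(out_before)))
    in_after <- sum(kept$x_mm > 0)
    expect_lt(in_after, sum(pts$x_mm > 0))
  }
})

test_that("clustered loss reaches the requested fraction and is seeded", {
  spec <- mosaic_spec(field_radius_mm = 1, target_density_per_mm2 = 1700,
                      exclusion_radius_um = 12, seed = 17)
  pts <- generate_mosaic(spec)
  pat <- loss_pattern("clustered", 0.4, cluster_radius_um = 150, seed = 5)
  kept <- apply_loss(pts, pat)
  expect_gte(attr(kept, "removed_fraction"), 0.4)
  expect_identical(kept, apply_loss(pts, pat))
  expect_error(loss_pattern("clustered", 0.4, cluster_radius_um = 0),
               "cluster_radius_um")
})

test_that("rendering produces a single component per isolated cell", {
  one <- data.frame(x_mm = 0.02, y_mm = -0.01)
  ret <- render_image(one, pixel_size_um = 1, soma_diameter_um = 12,
                      peak_intensity = 200, background_sd = 0,
                      field_radius_mm = 0.1)
  expect_true(is.integer(ret$image))
  expect_true(all(ret$image >= 0 & ret$image <= 255))
  above <- EBImage::bwlabel(EBImage::Image(t(ret$image >= 130) * 1))
  expect_equal(max(above), 1)
  # no cells: nothing above threshold inside the disc
  ret0 <- render_image(one[0, ], pixel_size_um = 1, field_radius_mm = 0.1)
  expect_identical(sum(ret0$image[ret0$geometry$mask] >= 130), 0L)
})

test_that("rendering rejects points outside the raster", {
  bad <- data.frame(x_mm = 0.3, y_mm = 0)
  expect_error(render_image(bad, field_radius_mm = 0.1), "outside")
})

test_that("rendered noise is reproducible from its seed", {
  pts <- data.frame(x_mm = c(-0.02, 0.03), y_mm = c(0.01, -0.02))
  a <- render_image(pts, field_radius_mm = 0.1, background_sd = 10, seed = 8)
  b <- render_image(pts, field_radius_mm = 0.1, background_sd = 10, seed = 8)
  expect_identical(a$image, b$image)
  c <- render_image(pts, field_radius_mm = 0.1, background_sd = 10, seed = 9)
  expect_false(identical(a$image, c$image))
})

test_that("synthetic retina files round-trip to disk", {
  spec <- mosaic_spec(field_radius_mm = 0.2, target_density_per_mm2 = 500,
                      exclusion_radius_um = 0, seed = 21)
  ret <- simulate_retina(spec, pixel_size_um = 2)
  dir <- tempfile("synth")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  paths <- write_synthetic_retina(ret, dir)
  expect_true(all(file.exists(paths)))
  img <- read_image_tiff(paths["image"])
  expect_identical(img, ret$image)
  pts <- read.csv(paths["points"])
  expect_equal(pts$x_mm, ret$points$x_mm)
})
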
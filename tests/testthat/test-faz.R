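g320 <- scan_geometry(3, 3, 320, 320)
px_mm <- 3 / 320

# an enclosed FAZ phantom: dark disk surrounded by a solid vessel ring
ring_scene <- function(n = 320, r_faz = 30, ring = 6) {
  vessels <- disk_mask(n, c(n / 2, n / 2), r_faz + ring) &
    !disk_mask(n, c(n / 2, n / 2), r_faz)
  binary_image(vessels, scan_geometry(3, 3, n, n))
}

test_that("region growing recovers an enclosed dark disk exactly", {
  mask <- ring_scene()
  region <- grow_faz(mask)
  expect_equal(region, disk_mask(320, c(160, 160), 30), ignore_attr = TRUE)
})

test_that("an all-background mask grows to the whole image with a warning", {
  mask <- binary_image(matrix(FALSE, 32, 32), scan_geometry(3, 3, 32, 32))
  expect_warning(region <- grow_faz(mask), "unbounded")
  expect_true(all(region))
})

test_that("a 1-px breach in the enclosing ring leaks into the outer background", {
  mask <- ring_scene()
  px <- mask$pixels
  px[160, ] <- FALSE  # carve a channel through the ring
  leaky <- binary_image(px, g320)
  region <- grow_faz(leaky)
  # oracle: connected-component labelling of the background
  lab <- label_oracle(!px, 4)
  expect_equal(region, lab == lab[160, 160], ignore_attr = TRUE)
  expect_true(region[1, 1])  # reached the outer background
})

test_that("a seed on a vessel pixel relocates to the nearest background", {
  mask <- ring_scene(n = 320, r_faz = 10, ring = 200)  # centre open, thick ring
  expect_warning(region <- grow_faz(mask, seed = c(160, 148)), "moved")
  expect_true(any(region))
  all_vessel <- binary_image(matrix(TRUE, 32, 32), scan_geometry(3, 3, 32, 32))
  expect_error(suppressWarnings(grow_faz(all_vessel)),
               class = "octa_no_background")
})

test_that("region growing equals seed-component labelling on random masks", {
  set.seed(21)
  for (i in 1:50) {
    px <- matrix(runif(32 * 32) < 0.45, 32, 32)
    m <- binary_image(px, scan_geometry(3, 3, 32, 32))
    seeds <- which(!px, arr.ind = TRUE)
    if (nrow(seeds) == 0) next
    s <- seeds[sample.int(nrow(seeds), 1), ]
    region <- grow_faz(m, seed = s)
    lab <- label_oracle(!px, 4)
    expect_equal(region, lab == lab[s[1], s[2]], ignore_attr = TRUE)
  }
})

test_that("region growing agrees with EBImage connected components", {
  skip_if_not_installed("EBImage")
  set.seed(22)
  px <- matrix(runif(64 * 64) < 0.4, 64, 64)
  m <- binary_image(px, scan_geometry(3, 3, 64, 64))
  seeds <- which(!px, arr.ind = TRUE)
  s <- seeds[1, ]
  region <- grow_faz(m, seed = s)
  lab <- EBImage::bwlabel(matrix(as.numeric(!px), 64, 64))  # 4-connected
  expect_equal(region, lab == lab[s[1], s[2]], ignore_attr = TRUE)
})

test_that("area is pixel count times pixel area", {
  region <- matrix(FALSE, 320, 320)
  region[1:32, 1:32] <- TRUE  # 1024 px
  expect_equal(faz_area(region, g320), 0.09)
  one <- matrix(FALSE, 320, 320); one[7, 9] <- TRUE
  expect_equal(faz_area(one, g320), 8.7890625e-5)
  expect_error(faz_area(matrix(FALSE, 16, 16), scan_geometry(3, 3, 16, 16)),
               class = "octa_empty_region")
})

test_that("rasterized disk area approaches the analytic limit", {
  region <- disk_mask(320, c(160, 160), 50)
  expect_equal(faz_area(region, g320), pi * (50 * px_mm)^2, tolerance = 0.02)
})

test_that("area conservation: region plus complement equals the scan", {
  set.seed(23)
  region <- matrix(runif(320 * 320) < 0.3, 320, 320)
  expect_equal(faz_area(region, g320) + faz_area(!region, g320),
               g320$width_mm * g320$height_mm)
})

test_that("chain perimeter of an axis-aligned square is the hand-counted chain", {
  region <- matrix(FALSE, 320, 320)
  region[101:200, 101:200] <- TRUE  # side 100 px
  # closed boundary chain of a filled square of side n: 4 (n - 1) axial steps
  expect_equal(faz_perimeter(region, g320, method = "chain"), 396 * px_mm)
  # within 2 percent of the ideal 4 * side geometric perimeter
  expect_equal(faz_perimeter(region, g320, method = "chain"), 4 * 100 * px_mm,
               tolerance = 0.02)
})

test_that("degenerate and clipped contours behave as documented", {
  one <- matrix(FALSE, 320, 320); one[5, 5] <- TRUE
  expect_equal(faz_perimeter(one, g320), 0)
  # region touching the border is measured along the clipped contour
  region <- matrix(FALSE, 320, 320); region[1:50, 1:50] <- TRUE
  expect_warning(p <- faz_perimeter(region, g320, method = "chain"), "border")
  expect_equal(p, 4 * 49 * px_mm)
})

test_that("corrected perimeter of a rasterized disk is within 3% of 2 pi r", {
  region <- disk_mask(320, c(160, 160), 50)
  expect_equal(faz_perimeter(region, g320), 2 * pi * 50 * px_mm,
               tolerance = 0.03)
})

test_that("circularity is the isoperimetric quotient", {
  expect_equal(as.numeric(faz_circularity(pi, 2 * pi)), 1)
  expect_equal(as.numeric(faz_circularity(1, 4)), pi / 4)
  expect_error(faz_circularity(1, 0), class = "octa_zero_perimeter")
  # clipping keeps the raw value accessible
  c1 <- faz_circularity(1.05 * pi, 2 * pi)
  expect_equal(as.numeric(c1), 1)
  expect_gt(attr(c1, "raw"), 1)
})

test_that("end-to-end circularity of a rasterized disk is 1 within 0.05", {
  res <- faz_analyze(ring_scene(n = 320, r_faz = 50, ring = 6))
  expect_equal(res$circularity_raw, 1, tolerance = 0.05)
  expect_equal(res$circularity, 1, tolerance = 0.05)
})

test_that("isoperimetric bound holds across random synthetic FAZ shapes", {
  for (s in 1:20) {
    p <- scene_params(faz_irregularity = runif(1, 0, 0.3), noise_sigma = 0,
                      speckle_strength = 0, n_vessel_roots = 0, rng_seed = 300 + s)
    sc <- generate_scene(p)
    region <- sc$truth$faz_mask
    a <- faz_area(region, p$geometry)
    pm <- faz_perimeter(region, p$geometry)
    expect_lt(attr(faz_circularity(a, pm), "raw"), 1 + 0.05)
  }
})

test_that("circularity decreases as boundary irregularity increases", {
  mean_circ <- function(irr) {
    mean(vapply(1:20, function(s) {
      p <- scene_params(faz_irregularity = irr, noise_sigma = 0,
                        speckle_strength = 0, n_vessel_roots = 0,
                        rng_seed = 400 + s)
      sc <- generate_scene(p)
      region <- sc$truth$faz_mask
      attr(faz_circularity(faz_area(region, p$geometry),
                           faz_perimeter(region, p$geometry)), "raw")
    }, numeric(1)))
  }
  c0 <- mean_circ(0.05); c1 <- mean_circ(0.15); c2 <- mean_circ(0.3)
  expect_gt(c0, c1)
  expect_gt(c1, c2)
})
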
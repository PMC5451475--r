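g320 <- scan_geometry(3, 3, 320, 320)
px_mm <- 3 / 320
px_area <- px_mm^2

test_that("ETDRS grid masks partition the outer disk and match analytic areas", {
  grid <- build_etdrs_grid(g320, center = c(160, 160))
  expect_false(any(grid$central & grid$parafoveal))
  expect_identical(grid$total, grid$central | grid$parafoveal)
  # annulus covers 2 pi / 9 of the scan area
  expect_equal(sum(grid$parafoveal), (pi * (1.5^2 - 0.5^2) / 9) * 320^2,
               tolerance = 0.01)
  expect_equal(grid$area_mm2[["total"]], pi * 1.5^2, tolerance = 0.01)
  expect_error(build_etdrs_grid(g320, center = c(1, 1)),
               class = "octa_grid_outside")
})

test_that("non-perfusion components honour the strict 0.02 mm^2 rule", {
  mk <- function(side) {
    px <- matrix(TRUE, 320, 320)
    px[10 + seq_len(side), 10 + seq_len(side)] <- FALSE
    binary_image(px, g320)
  }
  # 16 x 16 = 256 px = 0.0225 mm^2 > 0.02 -> listed
  inv16 <- find_nonperfusion(mk(16))
  expect_identical(nrow(inv16), 1L)
  expect_equal(inv16$area_mm2, 256 * px_area)
  # 15 x 15 = 225 px = 0.01978 mm^2 -> not listed
  expect_identical(nrow(find_nonperfusion(mk(15))), 0L)
  # all-white mask -> empty inventory
  all_white <- binary_image(matrix(TRUE, 320, 320), g320)
  expect_identical(nrow(find_nonperfusion(all_white)), 0L)
})

test_that("the 227 vs 228 pixel boundary flips the non-perfusion rule", {
  # 0.02 mm^2 = 227.56 px at this scale: 227 px is below, 228 px above
  mk_npx <- function(n) {
    px <- matrix(TRUE, 320, 320)
    cells <- arrayInd(1:n, c(20, 20))
    px[cbind(50 + cells[, 1], 50 + cells[, 2])] <- FALSE
    binary_image(px, g320)
  }
  expect_identical(nrow(find_nonperfusion(mk_npx(227))), 0L)
  inv <- find_nonperfusion(mk_npx(228))
  expect_identical(nrow(inv), 1L)
  expect_identical(inv$pixel_count, 228L)
  # and vessel density changes accordingly
  region <- matrix(TRUE, 320, 320)
  expect_equal(vessel_density(mk_npx(227), region), 100)
  expect_lt(vessel_density(mk_npx(228), region), 100)
})

test_that("vessel density follows its defining ratio", {
  region <- matrix(FALSE, 320, 320)
  region[1:100, 1:100] <- TRUE  # 10,000 px region
  px <- matrix(TRUE, 320, 320)
  px[1:25, 1:20] <- FALSE  # 500 px qualifying dark component
  expect_equal(vessel_density(binary_image(px, g320), region), 95)
  all_white <- binary_image(matrix(TRUE, 320, 320), g320)
  expect_equal(vessel_density(all_white, region), 100)
  all_black <- binary_image(matrix(FALSE, 320, 320), g320)
  expect_equal(vessel_density(all_black, region), 0)
  expect_error(vessel_density(all_white, matrix(FALSE, 320, 320)),
               class = "octa_empty_region")
})

test_that("adding a qualifying dark patch never increases vessel density", {
  set.seed(31)
  region <- matrix(TRUE, 320, 320)
  for (i in 1:5) {
    px <- matrix(runif(320 * 320) < 0.6, 320, 320)
    m1 <- binary_image(px, g320)
    v1 <- vessel_density(m1, region)
    px2 <- px
    r0 <- sample(1:300, 1); c0 <- sample(1:300, 1)
    px2[r0:(r0 + 19), c0:(c0 + 19)] <- FALSE  # 400 px > threshold
    v2 <- vessel_density(binary_image(px2, g320), region)
    expect_lte(v2, v1)
  }
})

test_that("a thick bar thins to a single one-pixel centreline", {
  px <- matrix(FALSE, 64, 320)
  px[30:34, ] <- TRUE
  sk <- skeletonize_mask(binary_image(px, scan_geometry(3, 3, 320, 64)))
  idx <- which(sk$pixels, arr.ind = TRUE)
  expect_identical(length(unique(idx[, 1])), 1L)  # one row survives
  expect_true(all(px[sk$pixels]))                 # skeleton subset of mask
  # no 2 x 2 block of skeleton pixels
  s <- sk$pixels
  expect_false(any(s[-1, -1] & s[-64, -1] & s[-1, -320] & s[-64, -320]))
})

test_that("thinning preserves component count on random blob masks", {
  set.seed(32)
  for (i in 1:20) {
    base <- matrix(runif(24 * 24) < 0.35, 24, 24)
    # dilate to blobs so components are chunky
    px <- matrix(FALSE, 48, 48)
    px[seq(1, 47, 2), seq(1, 47, 2)] <- base
    px <- px | rbind(px[-1, ], FALSE) | cbind(px[, -1], FALSE)
    px <- px | rbind(px[-1, ], FALSE) | cbind(px[, -1], FALSE)
    m <- binary_image(px, scan_geometry(3, 3, 48, 48))
    sk <- skeletonize_mask(m)
    expect_identical(n_components(sk$pixels, 8), n_components(px, 8))
    expect_true(all(px[sk$pixels]))
  }
})

test_that("skeleton length counts each 8-neighbour link once", {
  hline <- matrix(FALSE, 320, 320); hline[100, ] <- TRUE
  sk <- skeleton_image(hline, g320)
  expect_equal(skeleton_length(sk), 319 * px_mm)
  lone <- matrix(FALSE, 320, 320); lone[5, 5] <- TRUE
  expect_equal(skeleton_length(skeleton_image(lone, g320)), 0)
  diag100 <- matrix(FALSE, 320, 320)
  diag100[cbind(1:100, 1:100)] <- TRUE
  expect_equal(skeleton_length(skeleton_image(diag100, g320)),
               99 * sqrt(2) * px_mm)
})

test_that("box counting equals the triple-loop oracle on toy patterns", {
  set.seed(33)
  px <- matrix(runif(64 * 64) < 0.2, 64, 64)
  fd <- fractal_dimension(skeleton_image(px, scan_geometry(3, 3, 64, 64)))
  for (i in seq_along(attr(fd, "box_sizes"))) {
    s <- attr(fd, "box_sizes")[i]
    expect_identical(as.integer(attr(fd, "counts")[i]),
                     boxcount_oracle(px, s))
  }
  expect_true(all(diff(attr(fd, "counts")) <= 0))
})

test_that("fractal dimension hits the analytic limits for line and plane", {
  g256 <- scan_geometry(3, 3, 256, 256)
  line <- matrix(FALSE, 256, 256); line[128, ] <- TRUE
  fd_line <- fractal_dimension(skeleton_image(line, g256))
  expect_equal(as.numeric(fd_line), 1, tolerance = 0.05)
  expect_gt(attr(fd_line, "r_squared"), 0.95)
  plane <- matrix(TRUE, 256, 256)
  fd_plane <- fractal_dimension(binary_image(plane, g256))
  expect_equal(as.numeric(fd_plane), 2, tolerance = 0.05)
  expect_gt(attr(fd_plane, "r_squared"), 0.95)
  # degenerate input
  two <- matrix(FALSE, 16, 16); two[1, 1] <- TRUE
  expect_error(fractal_dimension(skeleton_image(two, scan_geometry(3, 3, 16, 16))),
               class = "octa_fd_degenerate")
})

test_that("FD of generated networks lies in (1, 2) and rises with branching", {
  fd_at <- function(bp, seeds) {
    vapply(seeds, function(s) {
      p <- scene_params(branch_prob = bp, capillary_infill = FALSE,
                        noise_sigma = 0, speckle_strength = 0, rng_seed = s)
      sc <- generate_scene(p)
      sk <- skeletonize_mask(sc$truth$vessel_mask)
      as.numeric(fractal_dimension(sk))
    }, numeric(1))
  }
  seeds <- 500 + 1:10
  f_lo <- fd_at(0.02, seeds); f_mid <- fd_at(0.10, seeds); f_hi <- fd_at(0.25, seeds)
  expect_true(all(c(f_lo, f_mid, f_hi) > 1 & c(f_lo, f_mid, f_hi) < 2))
  expect_lt(mean(f_lo), mean(f_mid))
  expect_lt(mean(f_mid), mean(f_hi))
})

test_that("VDI recovers the calibre of bars and scales with width", {
  mk_bar <- function(w) {
    px <- matrix(FALSE, 320, 320)
    px[160 + seq_len(w) - 1, ] <- TRUE
    binary_image(px, g320)
  }
  vdi5 <- vessel_diameter_index(mk_bar(5))
  expect_equal(vdi5, 5 * px_mm, tolerance = px_mm / (5 * px_mm))  # within 1 px
  vdi10 <- vessel_diameter_index(mk_bar(10))
  expect_equal(vdi10 / vdi5, 2, tolerance = 0.1)
  empty <- binary_image(matrix(FALSE, 320, 320), g320)
  expect_error(vessel_diameter_index(empty), class = "octa_zero_skeleton")
})

test_that("VDI grows by about two pixel sizes under one-pixel dilation", {
  px <- matrix(FALSE, 320, 320)
  px[100:104, 11:310] <- TRUE  # isolated straight vessel, width 5
  m <- binary_image(px, g320)
  dil <- px | rbind(px[-1, ], FALSE) | rbind(FALSE, px[-320, ]) |
    cbind(px[, -1], FALSE) | cbind(FALSE, px[, -320])
  vdi0 <- vessel_diameter_index(m)
  vdi1 <- vessel_diameter_index(binary_image(dil, g320))
  expect_equal(vdi1 - vdi0, 2 * px_mm, tolerance = 0.25)
})
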
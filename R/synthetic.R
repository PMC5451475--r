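#' Parameters of a synthetic en-face angiogram
#'
#' Describes one synthetic scene: a fovea-centred dark avascular zone whose
#' boundary is a radial Fourier perturbation of a circle, a network of
#' branching bright vessels rooted on the FAZ rim and growing outward
#' (including the terminal capillary ring that encloses the FAZ),
#' optional capillary-dropout patches, multiplicative speckle and additive
#' Gaussian noise. Defaults emulate a healthy-to-mild superficial-plexus
#' angiogram at the standard 3 mm / 320 px acquisition: FAZ radius 0.35 mm
#' (area about 0.38 mm^2), mild boundary irregularity, capillary calibre
#' around 3 px (28 um).
#'
#' @param geometry [scan_geometry()] (default 3 mm x 3 mm, 320 x 320 px).
#' @param faz_radius_mm Mean FAZ radius in mm (must be below half the scan
#'   width).
#' @param faz_irregularity Total relative amplitude of the radial Fourier
#'   perturbation (harmonics 2-6); 0 gives a perfect circle.
#' @param n_vessel_roots Number of vessel trees rooted on the FAZ rim.
#' @param branch_prob Probability per growth step of spawning a branch.
#' @param vessel_width_px Mean vessel calibre in pixels (jittered per tree).
#' @param dropout_patches List of patches, each `list(center = c(x, y))` in
#'   mm from the top-left corner and `radius_mm`; vessels are erased inside.
#' @param capillary_infill Seed short capillaries into residual avascular
#'   gaps outside the FAZ (default `TRUE`), emulating the near-uniform
#'   capillary mesh of the macula; without it the tree skeletons leave
#'   unrealistically large dark areas between vessel trunks.
#' @param noise_sigma SD of additive Gaussian noise (intensity units).
#' @param speckle_strength Relative amplitude of multiplicative speckle.
#' @param rng_seed Integer seed; all randomness in the scene derives from
#'   it (no global state is left disturbed).
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(geometry = scan_geometry(3, 3, 320, 320),
                         faz_radius_mm = 0.35, faz_irregularity = 0.1,
                         n_vessel_roots = 26, branch_prob = 0.12,
                         vessel_width_px = 3, dropout_patches = list(),
                         capillary_infill = TRUE,
                         noise_sigma = 0.05, speckle_strength = 0.15,
                         rng_seed = 1L) {
  stopifnot(inherits(geometry, "scan_geometry"),
            faz_radius_mm > 0, faz_irregularity >= 0,
            n_vessel_roots >= 0, branch_prob >= 0, branch_prob <= 1,
            vessel_width_px >= 1, noise_sigma >= 0, speckle_strength >= 0)
  if (faz_radius_mm * (1 + faz_irregularity) >= min(geometry$width_mm,
                                                    geometry$height_mm) / 2)
    stop("FAZ larger than the scan: reduce faz_radius_mm or irregularity")
  structure(list(geometry = geometry, faz_radius_mm = faz_radius_mm,
                 faz_irregularity = faz_irregularity,
                 n_vessel_roots = as.integer(n_vessel_roots),
                 branch_prob = branch_prob,
                 vessel_width_px = vessel_width_px,
                 dropout_patches = dropout_patches,
                 capillary_infill = isTRUE(capillary_infill),
                 noise_sigma = noise_sigma,
                 speckle_strength = speckle_strength,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_params")
}

# evaluate the Fourier boundary radius (and derivative) at angles theta
faz_boundary <- function(R, amps, phases, theta, deriv = FALSE) {
  out <- if (deriv) 0 else 1
  for (m in seq_along(amps)) {
    h <- m + 1L  # harmonics 2..6
    out <- out + if (deriv) -amps[m] * h * sin(h * theta + phases[m]) else
      amps[m] * cos(h * theta + phases[m])
  }
  R * out
}

# wrap an angle difference into [-pi, pi]
wrap_angle <- function(a) atan2(sin(a), cos(a))

#' Generate a synthetic angiogram with ground truth
#'
#' Deterministic given `rng_seed`: the same parameters always produce
#' byte-identical images. Ground-truth FAZ area, perimeter and circularity
#' are computed from the continuous Fourier boundary by quadrature at
#' 4096 angular samples, independent of any pixel-level processing, so
#' they are legitimate oracles for the measurement pipeline. Ground-truth
#' vessel densities are computed from the clean (noise-free) rasterized
#' vessel map using the non-perfusion definition.
#'
#' @param params A [scene_params()] object.
#' @param noise_seed Optional separate seed for the noise realization;
#'   defaults to `rng_seed`. Two calls with the same `params` but different
#'   `noise_seed` give the same anatomy under independent noise, emulating
#'   consecutive scans of one eye.
#' @return A list with elements `image` (a [gray_image()]) and `truth`, a
#'   list of class `scene_truth`: `faz_mask`, `faz_area_mm2`,
#'   `faz_perimeter_mm`, `faz_circularity`, `vessel_mask` (clean, as a
#'   [binary_image()]), `vd_pct` (named: central, parafoveal, total) and
#'   `dropout_patches`.
#' @export
generate_scene <- function(params, noise_seed = NULL) {
  stopifnot(inherits(params, "scene_params"))
  g <- params$geometry
  ps <- pixel_scale(g)
  nr <- g$height_px; nc <- g$width_px
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(params$rng_seed)

  # --- FAZ boundary (harmonics 2..6) ---
  raw <- stats::runif(5)
  amps <- if (params$faz_irregularity > 0)
    params$faz_irregularity * raw / sum(raw) else rep(0, 5)
  phases <- stats::runif(5, 0, 2 * pi)
  R <- params$faz_radius_mm
  th <- seq(0, 2 * pi, length.out = 4097L)[-4097L]
  rb <- faz_boundary(R, amps, phases, th)
  rd <- faz_boundary(R, amps, phases, th, deriv = TRUE)
  truth_perim <- mean(sqrt(rb^2 + rd^2)) * 2 * pi
  truth_area <- mean(rb^2) / 2 * 2 * pi
  truth_circ <- 4 * pi * truth_area / truth_perim^2

  cx <- g$width_mm / 2; cy <- g$height_mm / 2
  xs <- (seq_len(nc) - 0.5) * ps$x
  ys <- (seq_len(nr) - 0.5) * ps$y
  dx <- matrix(xs - cx, nr, nc, byrow = TRUE)
  dy <- matrix(ys - cy, nr, nc)
  rho <- sqrt(dx^2 + dy^2)
  theta_px <- atan2(dy, dx)
  r_at_px <- faz_boundary(R, amps, phases, theta_px)
  faz_mask <- rho <= r_at_px

  # --- vessels ---
  canvas <- matrix(0, nr, nc)
  cx_px <- cx / ps$x; cy_px <- cy / ps$y
  w_ring <- params$vessel_width_px
  segs <- vector("list", 0)
  if (params$n_vessel_roots > 0) {
    # terminal capillary ring just outside the boundary (inner edge at r)
    th_ring <- seq(0, 2 * pi, length.out = 513L)
    rr <- faz_boundary(R, amps, phases, th_ring) + (w_ring / 2) * ps$x
    rx <- (cx + rr * cos(th_ring)) / ps$x
    ry <- (cy + rr * sin(th_ring)) / ps$y
    n_ring <- length(th_ring) - 1L
    segs[[1]] <- cbind(rx[-length(rx)], ry[-length(ry)], rx[-1], ry[-1],
                       rep(w_ring, n_ring))
    # branching trees rooted on the rim, growing outward with a radial bias
    step_px <- 4
    max_segments <- 30000L  # safety guard; not binding at plausible settings
    n_seg <- 0L
    root_angles <- 2 * pi * (seq_len(params$n_vessel_roots) - 1) /
      params$n_vessel_roots + stats::runif(params$n_vessel_roots, -0.1, 0.1)
    stack <- vector("list", 0)
    for (a in root_angles) {
      r0 <- faz_boundary(R, amps, phases, a) + (w_ring / 2) * ps$x
      stack[[length(stack) + 1L]] <- list(
        x = (cx + r0 * cos(a)) / ps$x, y = (cy + r0 * sin(a)) / ps$y,
        dir = a, w = params$vessel_width_px * stats::runif(1, 0.7, 1.3))
    }
    while (length(stack) > 0 && n_seg < max_segments) {
      wk <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      repeat {
        if (n_seg >= max_segments || wk$w < 0.8) break
        ndir <- wk$dir + stats::rnorm(1, 0, 0.35)
        # pull gently back toward the outward radial direction so trees
        # spread over the field instead of wandering in place
        radial <- atan2(wk$y - cy_px, wk$x - cx_px)
        ndir <- ndir + 0.3 * wrap_angle(radial - ndir)
        nx <- wk$x + step_px * cos(ndir)
        ny <- wk$y + step_px * sin(ndir)
        n_seg <- n_seg + 1L
        segs[[length(segs) + 1L]] <- c(wk$x, wk$y, nx, ny, wk$w)
        if (nx < -4 || nx > nc + 4 || ny < -4 || ny > nr + 4) break
        if (stats::runif(1) < params$branch_prob) {
          # calibre divides between the continuing trunk and the branch,
          # which keeps total tree size bounded at any branch probability
          side <- sample(c(-1, 1), 1)
          stack[[length(stack) + 1L]] <- list(
            x = nx, y = ny, dir = ndir + side * stats::runif(1, 0.5, 1.0),
            w = wk$w * 0.7)
          wk$w <- wk$w * 0.9
        }
        wk$x <- nx; wk$y <- ny; wk$dir <- ndir; wk$w <- wk$w * 0.995
      }
    }
    seg_mat <- do.call(rbind, lapply(segs, function(s)
      matrix(s, ncol = 5)))
    canvas <- cpp_draw_segments(nr, nc, seg_mat)

    # capillary infill: seed short capillaries in any remaining avascular
    # gap outside the FAZ until gaps fall below the non-perfusion scale;
    # emulates the near-uniform capillary mesh of the macula
    if (isTRUE(params$capillary_infill)) {
      infill_w <- max(1, 0.7 * params$vessel_width_px)
      gap_r <- 4L  # half-width of the emptiness test window (px)
      for (round in 1:6) {
        cand_r <- sample.int(nr, 3000L, replace = TRUE)
        cand_c <- sample.int(nc, 3000L, replace = TRUE)
        drawn <- vector("list", 0)
        for (i in seq_len(3000L)) {
          r0 <- cand_r[i]; c0 <- cand_c[i]
          if (faz_mask[r0, c0]) next
          rr0 <- max(1L, r0 - gap_r):min(nr, r0 + gap_r)
          cc0 <- max(1L, c0 - gap_r):min(nc, c0 + gap_r)
          if (any(canvas[rr0, cc0] > 0.25)) next
          # short 3-segment wiggly capillary
          ang <- stats::runif(1, 0, 2 * pi)
          x <- c0 - 0.5; y <- r0 - 0.5
          for (k in 1:3) {
            ang <- ang + stats::rnorm(1, 0, 0.5)
            x1 <- x + 4 * cos(ang); y1 <- y + 4 * sin(ang)
            drawn[[length(drawn) + 1L]] <- c(x, y, x1, y1, infill_w)
            x <- x1; y <- y1
          }
        }
        if (length(drawn) == 0) break
        canvas <- pmax(canvas, cpp_draw_segments(
          nr, nc, do.call(rbind, lapply(drawn, function(s) matrix(s, ncol = 5)))))
      }
    }
  }
  # keep the avascular zone clear of stroke anti-aliasing
  canvas[faz_mask] <- 0
  # dropout patches erase vessels locally
  for (p in params$dropout_patches) {
    pr2 <- (dx + cx - p$center[1])^2 + (dy + cy - p$center[2])^2
    canvas[pr2 < p$radius_mm^2] <- 0
  }
  vessel_mask <- canvas > 0.5

  # --- truth vessel densities on the standard grid ---
  vm <- binary_image(vessel_mask, g)
  vd <- tryCatch({
    grid <- build_etdrs_grid(g)
    c(central = vessel_density(vm, grid$central),
      parafoveal = vessel_density(vm, grid$parafoveal),
      total = vessel_density(vm, grid$total))
  }, error = function(e) c(central = NA_real_, parafoveal = NA_real_,
                           total = NA_real_))

  # --- intensity model ---
  bg_level <- 0.08; vessel_level <- 0.85
  clean <- bg_level + (vessel_level - bg_level) * canvas
  if (!is.null(noise_seed)) set.seed(as.integer(noise_seed))
  img <- clean * (1 + params$speckle_strength * matrix(stats::rnorm(nr * nc), nr, nc)) +
    params$noise_sigma * matrix(stats::rnorm(nr * nc), nr, nc)
  img[img < 0] <- 0
  img[img > 1] <- 1

  truth <- structure(list(faz_mask = faz_mask, faz_area_mm2 = truth_area,
                          faz_perimeter_mm = truth_perim,
                          faz_circularity = truth_circ,
                          vessel_mask = vm, vd_pct = vd,
                          dropout_patches = params$dropout_patches),
                     class = "scene_truth")
  list(image = gray_image(img, g), truth = truth, params = params)
}

#' Generate a repeated-measures image set
#'
#' Emulates a test-retest reliability study: `n_subjects` eyes, each with
#' subject-specific anatomy (FAZ radius, irregularity, branching density
#' and calibre jittered around the base parameters) and two scans per eye
#' that differ only in the noise realization.
#'
#' @param params Base [scene_params()].
#' @param n_subjects Number of subjects (>= 3).
#' @param structural_sd Named list of between-subject SDs:
#'   `faz_radius_mm`, `faz_irregularity`, `branch_prob`, `vessel_width_px`.
#'   When all are 0 every subject shares the same anatomy (same scene seed),
#'   so between-subject spread in measured metrics is pure noise.
#' @return A list of class `repeatability_set`: `subjects` (per subject, a
#'   list with `scans` = two [gray_image()]s and `truth`), and
#'   `truth_table`, a `data.frame` of per-subject true FAZ area,
#'   circularity and vessel densities.
#' @export
generate_repeatability_set <- function(params, n_subjects,
                                       structural_sd = list(
                                         faz_radius_mm = 0.04,
                                         faz_irregularity = 0.04,
                                         branch_prob = 0.02,
                                         vessel_width_px = 0.3)) {
  stopifnot(inherits(params, "scene_params"), n_subjects >= 3)
  defaults <- list(faz_radius_mm = 0, faz_irregularity = 0, branch_prob = 0,
                   vessel_width_px = 0)
  sds <- utils::modifyList(defaults, structural_sd)
  # with zero structural variance every subject shares the same anatomy, so
  # any between-subject spread in measured metrics is pure noise
  identical_anatomy <- all(unlist(sds) == 0)
  subjects <- vector("list", n_subjects)
  rows <- vector("list", n_subjects)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  for (i in seq_len(n_subjects)) {
    set.seed(params$rng_seed + 7919L * i)
    p_i <- params
    p_i$faz_radius_mm <- max(0.1, params$faz_radius_mm +
                               stats::rnorm(1, 0, sds$faz_radius_mm))
    p_i$faz_irregularity <- max(0, params$faz_irregularity +
                                  stats::rnorm(1, 0, sds$faz_irregularity))
    p_i$branch_prob <- min(1, max(0, params$branch_prob +
                                    stats::rnorm(1, 0, sds$branch_prob)))
    p_i$vessel_width_px <- max(1, params$vessel_width_px +
                                 stats::rnorm(1, 0, sds$vessel_width_px))
    p_i$rng_seed <- if (identical_anatomy) params$rng_seed else
      params$rng_seed + 1000L * i
    s1 <- generate_scene(p_i, noise_seed = params$rng_seed + 100003L + 2L * i)
    s2 <- generate_scene(p_i, noise_seed = params$rng_seed + 100004L + 2L * i)
    subjects[[i]] <- list(scans = list(s1$image, s2$image), truth = s1$truth,
                          params = p_i)
    rows[[i]] <- data.frame(subject = i,
                            faz_area_mm2 = s1$truth$faz_area_mm2,
                            faz_circularity = s1$truth$faz_circularity,
                            total_vd_pct = s1$truth$vd_pct[["total"]],
                            parafoveal_vd_pct = s1$truth$vd_pct[["parafoveal"]])
  }
  structure(list(subjects = subjects, truth_table = do.call(rbind, rows)),
            class = "repeatability_set")
}
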
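#' Specification of a synthetic short-axis multi-gradient-echo phantom
#'
#' Describes one short-axis slice of a digital cardiac phantom: an annular LV
#' myocardium with a spatially varying T2* map, bright LV and RV blood pools,
#' low-signal lung, a bright chest-fat/body band and air background. The
#' noiseless signal of a pixel belonging to tissue r at echo time t is
#' `K_r * exp(-t / T2*_r(p)) + C`; air is strictly zero. Rician noise of scale
#' `noise_sigma` is applied to the magnitude images when `noise_sigma > 0`.
#'
#' Default geometry and tissue parameters emulate a 1.5 T bright-blood
#' acquisition (1.56 mm in-plane pixels, eight echoes from 2.69 to 18.86 ms in
#' 2.31 ms increments) with typical adult short-axis dimensions. LV (arterial)
#' and RV (venous, desaturated) blood carry different T2* values, which makes
#' the echo giving maximal blood/myocardium contrast region-dependent, as seen
#' on patient data. The default mid-ventricular slice contains a focal
#' inferolateral sector with T2* = 15 ms emulating local iron deposition.
#'
#' @param slice_level one of `"apical"`, `"mid"`, `"basal"`.
#' @param image_size image dimensions in pixels (length-2 integer).
#' @param pixel_spacing in-plane pixel spacing in mm (isotropic).
#' @param lv_center LV center (row, col), pixel-center coordinates.
#' @param endo_radius,epi_radius endo-/epicardial radii in mm. Defaults depend
#'   on `slice_level`.
#' @param myo_t2star,blood_t2star_lv,blood_t2star_rv,lung_t2star,body_t2star
#'   tissue T2* values in ms.
#' @param iron_sector `NULL`, or `list(t2star=, from_deg=, to_deg=)` describing
#'   an angular sector of the myocardium with reduced T2* (focal iron). Angles
#'   follow the package convention (0 = "east", counter-clockwise on screen).
#' @param k_myo,k_blood,k_lung,k_body signal amplitudes per tissue.
#' @param offset_c constant signal offset added to all tissue (not air).
#' @param te_list echo times in ms, strictly increasing, length >= 3.
#' @param noise_sigma Rician noise scale in raw intensity units (>= 0).
#' @param papillary list of `list(center=, radius=)` discs (pixel units) of
#'   myocardial-signal papillary muscle inside the LV blood pool, or `NULL`.
#' @param lung_vessel `NULL` or `list(center=, radius=)`: a bright blood-signal
#'   vessel disc inside the lung.
#' @param rv_center,rv_radius RV blood pool disc (pixel units); the pool is the
#'   part of the disc outside the epicardium.
#' @param rng_seed integer seed controlling the noise realization.
#'
#' @return An object of class `phantom_spec` (a validated list).
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(slice_level = c("mid", "apical", "basal"),
                         image_size = c(128L, 128L),
                         pixel_spacing = 1.56,
                         lv_center = c(64.5, 64.5),
                         endo_radius = NULL,
                         epi_radius = NULL,
                         myo_t2star = 30,
                         blood_t2star_lv = 150,
                         blood_t2star_rv = 40,
                         lung_t2star = 2,
                         body_t2star = 50,
                         iron_sector = NULL,
                         k_myo = 1000, k_blood = 1800, k_lung = 80, k_body = 2200,
                         offset_c = 20,
                         te_list = seq(2.69, by = 2.31, length.out = 8),
                         noise_sigma = 45,
                         papillary = NULL,
                         lung_vessel = NULL,
                         rv_center = NULL,
                         rv_radius = NULL,
                         rng_seed = 20260920L) {
  slice_level <- match.arg(slice_level)
  geom <- switch(slice_level,
                 basal  = c(endo = 26.5, wall = 9.4),
                 mid    = c(endo = 25.0, wall = 9.4),
                 apical = c(endo = 18.7, wall = 7.7))
  if (is.null(endo_radius)) endo_radius <- geom[["endo"]]
  if (is.null(epi_radius)) epi_radius <- geom[["endo"]] + geom[["wall"]]
  if (is.null(rv_center)) {
    rv_center <- if (slice_level == "apical") c(64.5, 46.5) else c(64.5, 41.5)
  }
  if (is.null(rv_radius)) rv_radius <- if (slice_level == "apical") 15 else 19
  spec <- structure(list(
    slice_level = slice_level, image_size = as.integer(image_size),
    pixel_spacing = pixel_spacing, lv_center = lv_center,
    endo_radius = endo_radius, epi_radius = epi_radius,
    myo_t2star = myo_t2star, blood_t2star_lv = blood_t2star_lv,
    blood_t2star_rv = blood_t2star_rv, lung_t2star = lung_t2star,
    body_t2star = body_t2star, iron_sector = iron_sector,
    k_myo = k_myo, k_blood = k_blood, k_lung = k_lung, k_body = k_body,
    offset_c = offset_c, te_list = te_list, noise_sigma = noise_sigma,
    papillary = papillary, lung_vessel = lung_vessel,
    rv_center = rv_center, rv_radius = rv_radius,
    rng_seed = as.integer(rng_seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (!(epi_radius > endo_radius && endo_radius > 0))
      stop("invalid phantom geometry: need epi_radius > endo_radius > 0 (got epi ",
           epi_radius, " mm, endo ", endo_radius, " mm)")
    if (length(te_list) < 3 || any(diff(te_list) <= 0))
      stop("te_list must be strictly increasing with length >= 3")
    if (noise_sigma < 0) stop("noise_sigma must be >= 0")
    t2 <- c(myo_t2star, blood_t2star_lv, blood_t2star_rv, lung_t2star, body_t2star,
            if (!is.null(iron_sector)) iron_sector$t2star)
    if (any(t2 <= 0)) stop("all T2* values must be > 0")
    if (pixel_spacing <= 0) stop("pixel_spacing must be > 0")
  })
  invisible(spec)
}

#' Default phantom specification for a slice level
#'
#' Convenience wrapper around [phantom_spec()] adding the default papillary
#' muscles, a lung vessel, and (on the mid-ventricular slice) the focal iron
#' sector. These defaults are the reference conditions the package's tests and
#' examples run under.
#'
#' @inheritParams phantom_spec
#' @param noise_sigma Rician noise scale; the default corresponds to a
#'   myocardial signal-to-noise ratio of roughly 20 at the shortest echo.
#' @param rng_seed integer seed.
#' @return A `phantom_spec`.
#' @export
default_phantom_spec <- function(slice_level = c("mid", "apical", "basal"),
                                 noise_sigma = 45, rng_seed = 20260920L) {
  slice_level <- match.arg(slice_level)
  endo_px <- switch(slice_level, basal = 26.5, mid = 25.0, apical = 18.7) / 1.56
  epi_px <- endo_px + switch(slice_level, basal = 9.4, mid = 9.4, apical = 7.7) / 1.56
  pap_r <- 0.55 * endo_px
  pap <- list(list(center = c(64.5 + pap_r * sin(pi / 6), 64.5 - pap_r * cos(pi / 6)),
                   radius = 2.2),
              list(center = c(64.5 + pap_r * sin(pi / 6), 64.5 + pap_r * cos(pi / 6)),
                   radius = 2.2))
  # a small bright vessel inside the lung, within typical traced lung contours
  vessel <- list(center = c(64.5 + 6, 64.5 + epi_px + 24 + 5), radius = 2)
  iron <- if (slice_level == "mid")
    list(t2star = 15, from_deg = -42, to_deg = -2) else NULL
  phantom_spec(slice_level = slice_level, iron_sector = iron,
               papillary = pap, lung_vessel = vessel,
               noise_sigma = noise_sigma, rng_seed = rng_seed)
}

#' Apply Rician noise to a magnitude image
#'
#' Models magnitude-MRI noise: `out = sqrt((img + g1)^2 + g2^2)` with `g1`,
#' `g2` zero-mean Gaussian of scale `sigma`. `sigma = 0` returns the input
#' unchanged.
#'
#' @param image numeric matrix of non-negative intensities.
#' @param sigma noise scale (>= 0).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return A matrix of the same dimensions.
#' @export
add_rician_noise <- function(image, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(image)
  if (!is.null(seed)) set.seed(as.integer(seed))
  g1 <- matrix(stats::rnorm(length(image), 0, sigma), nrow(image))
  g2 <- matrix(stats::rnorm(length(image), 0, sigma), nrow(image))
  sqrt((image + g1)^2 + g2^2)
}

# Build per-pixel tissue masks and parameter maps from a spec
phantom_geometry <- function(spec) {
  dim <- spec$image_size
  px <- spec$pixel_spacing
  ctr <- spec$lv_center
  g <- px_grid(dim)
  r_lv <- sqrt((g$row - ctr[1])^2 + (g$col - ctr[2])^2)
  theta <- px_angle(g$row, g$col, ctr)
  endo_px <- spec$endo_radius / px
  epi_px <- spec$epi_radius / px

  lv_disc <- r_lv < endo_px
  myo <- r_lv >= endo_px & r_lv < epi_px

  rv_full <- disc_mask(dim, spec$rv_center, spec$rv_radius)
  rvbp <- rv_full & r_lv >= epi_px

  # lung: a large disc lateral (east) of the heart whose curved boundary
  # meets the lateral epicardium tangentially, as the pleural surface does
  body_outer <- 48
  lung_center <- c(ctr[1], ctr[2] + epi_px + 24)
  lung_disc <- disc_mask(dim, lung_center, 28)
  lung <- lung_disc & r_lv >= epi_px & !rvbp
  body <- r_lv >= epi_px & r_lv < body_outer & !lung & !rvbp
  air <- !(lv_disc | myo | rvbp | lung | body)

  pap_mask <- matrix(FALSE, dim[1], dim[2])
  for (p in spec$papillary %||% list()) {
    pap_mask <- pap_mask | (disc_mask(dim, p$center, p$radius) & lv_disc)
  }
  vessel_mask <- matrix(FALSE, dim[1], dim[2])
  if (!is.null(spec$lung_vessel)) {
    vessel_mask <- disc_mask(dim, spec$lung_vessel$center, spec$lung_vessel$radius) & lung
  }

  t2_myo <- matrix(spec$myo_t2star, dim[1], dim[2])
  if (!is.null(spec$iron_sector)) {
    a0 <- spec$iron_sector$from_deg * pi / 180
    a1 <- spec$iron_sector$to_deg * pi / 180
    span <- (a1 - a0) %% (2 * pi)
    in_sector <- ((theta - a0) %% (2 * pi)) <= span
    t2_myo[in_sector] <- spec$iron_sector$t2star
  }

  # RV insertion points: intersections of the epicardial circle with the RV disc
  insertions <- circle_intersections(ctr, epi_px, spec$rv_center, spec$rv_radius)

  list(lv_disc = lv_disc, myo = myo, rvbp = rvbp, lung = lung, body = body,
       air = air, papillary = pap_mask, vessel = vessel_mask,
       t2_myo = t2_myo, r_lv = r_lv, theta = theta,
       endo_px = endo_px, epi_px = epi_px, insertions = insertions)
}

# Intersection points of two circles, ordered so the first has the smaller row
# (the anterior point in the package's orientation)
circle_intersections <- function(c1, r1, c2, r2) {
  d <- sqrt(sum((c2 - c1)^2))
  if (d >= r1 + r2 || d <= abs(r1 - r2))
    stop("circles do not intersect; RV disc must overlap the epicardial circle")
  a <- (r1^2 - r2^2 + d^2) / (2 * d)
  h <- sqrt(max(r1^2 - a^2, 0))
  mid <- c1 + a * (c2 - c1) / d
  perp <- c(-(c2 - c1)[2], (c2 - c1)[1]) / d
  p1 <- mid + h * perp
  p2 <- mid - h * perp
  if (p1[1] <= p2[1]) rbind(anterior = p1, inferior = p2)
  else rbind(anterior = p2, inferior = p1)
}

#' Generate a synthetic multi-gradient-echo series with ground truth
#'
#' Renders the noiseless forward model `K_r * exp(-TE / T2*_r(p)) + C` per
#' tissue and echo, applies Rician noise when `noise_sigma > 0`, and returns
#' the echo series together with ground-truth masks, the true myocardial T2*
#' map, and synthesized manual seeds for both ROI-placement methods.
#' Identical spec (including `rng_seed`) gives bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @param seed_jitter standard deviation (pixels) of the Gaussian perturbation
#'   applied to the synthesized seeds, emulating observer variability.
#' @return A list with elements `series` (an `mge_series`) and `truth`
#'   (masks, `t2star_true`, seed sets `seeds_method1` / `seeds_method2`,
#'   insertion points and the generating spec).
#' @export
generate_phantom <- function(spec, seed_jitter = 0.5) {
  validate_phantom_spec(spec)
  geo <- phantom_geometry(spec)
  dim <- spec$image_size

  k_map <- matrix(0, dim[1], dim[2])
  t2_map <- matrix(1, dim[1], dim[2])
  k_map[geo$body] <- spec$k_body;   t2_map[geo$body] <- spec$body_t2star
  k_map[geo$lung] <- spec$k_lung;   t2_map[geo$lung] <- spec$lung_t2star
  k_map[geo$rvbp] <- spec$k_blood;  t2_map[geo$rvbp] <- spec$blood_t2star_rv
  k_map[geo$lv_disc] <- spec$k_blood; t2_map[geo$lv_disc] <- spec$blood_t2star_lv
  k_map[geo$myo] <- spec$k_myo
  t2_map[geo$myo] <- geo$t2_myo[geo$myo]
  if (any(geo$papillary)) {
    k_map[geo$papillary] <- spec$k_myo
    t2_map[geo$papillary] <- spec$myo_t2star
  }
  if (any(geo$vessel)) {
    k_map[geo$vessel] <- spec$k_blood
    t2_map[geo$vessel] <- spec$blood_t2star_lv
  }
  c_map <- ifelse(geo$air, 0, spec$offset_c)

  images <- vector("list", length(spec$te_list))
  for (i in seq_along(spec$te_list)) {
    img <- k_map * exp(-spec$te_list[i] / t2_map) + c_map
    if (spec$noise_sigma > 0)
      img <- add_rician_noise(img, spec$noise_sigma,
                              seed = stage_seed(spec$rng_seed, paste0("echo", i)))
    images[[i]] <- img
  }

  series <- mge_series(images, te_list = spec$te_list,
                       pixel_spacing = spec$pixel_spacing,
                       slice_level = spec$slice_level,
                       scanner_id = "synthetic phantom")

  t2star_true <- matrix(NA_real_, dim[1], dim[2])
  t2star_true[geo$myo] <- geo$t2_myo[geo$myo]

  truth <- list(
    myo_mask = geo$myo,
    lvbp_mask = geo$lv_disc,       # includes papillary-muscle pixels as region
    rvbp_mask = geo$rvbp,
    lung_mask = geo$lung,
    air_mask = geo$air,
    papillary_mask = geo$papillary,
    t2star_true = t2star_true,
    insertion_anterior = geo$insertions["anterior", ],
    insertion_inferior = geo$insertions["inferior", ],
    endo_px = geo$endo_px, epi_px = geo$epi_px,
    spec = spec)
  truth$seeds_method1 <- synthesize_seeds(truth, method = 1L, jitter = seed_jitter,
                                          seed = stage_seed(spec$rng_seed, "seeds1"))
  truth$seeds_method2 <- synthesize_seeds(truth, method = 2L, jitter = seed_jitter,
                                          seed = stage_seed(spec$rng_seed, "seeds2"))
  list(series = series, truth = truth)
}

#' Synthesize manual seeds from phantom ground truth
#'
#' Builds the minimal manual input the pipeline needs (mid-wall polyline, air
#' point, and method-specific seeds) from the phantom geometry, with Gaussian
#' jitter emulating observer variability.
#'
#' @param truth the `truth` element returned by [generate_phantom()].
#' @param method ROI placement method, 1 or 2.
#' @param jitter per-coordinate Gaussian jitter SD in pixels.
#' @param seed integer seed for the jitter.
#' @return A `manual_seeds` list.
#' @export
synthesize_seeds <- function(truth, method = 2L, jitter = 0.5, seed = 1L) {
  spec <- truth$spec
  set.seed(as.integer(seed))
  ctr <- spec$lv_center
  mid_r <- (truth$endo_px + truth$epi_px) / 2
  ang <- seq(0, 2 * pi, length.out = 49)[-49]
  midwall <- cbind(ctr[1] - mid_r * sin(ang), ctr[2] + mid_r * cos(ang))
  jit <- function(x) x + stats::rnorm(length(x), 0, jitter)
  midwall <- matrix(jit(midwall), ncol = 2)
  air_point <- jit(c(14, 14))

  seeds <- list(midwall_polyline = midwall, air_point = air_point,
                method = as.integer(method))
  if (method == 1L) {
    seeds$insertion_point <- jit(truth$insertion_anterior)
    if (spec$slice_level == "apical") {
      # approximate manual marks: RVBP centroid and a vessel-free lung spot
      rv_idx <- which(truth$rvbp_mask, arr.ind = TRUE)
      seeds$apical_rvbp_point <- jit(colMeans(rv_idx))
      lung_pt <- c(ctr[1] - (truth$epi_px + 7) * sin(10 * pi / 180),
                   ctr[2] + (truth$epi_px + 7) * cos(10 * pi / 180))
      seeds$apical_lung_point <- jit(lung_pt)
    }
  } else {
    # open polyline along the free-wall boundary of the RVBP, anterior end first
    ins_a <- truth$insertion_anterior
    ins_i <- truth$insertion_inferior
    rc <- spec$rv_center
    a0 <- atan2(-(ins_a[1] - rc[1]), ins_a[2] - rc[2])
    a1 <- atan2(-(ins_i[1] - rc[1]), ins_i[2] - rc[2])
    # sweep from the anterior to the inferior insertion away from the LV
    lv_dir <- atan2(-(spec$lv_center[1] - rc[1]), spec$lv_center[2] - rc[2])
    d_ccw <- (a1 - a0) %% (2 * pi)
    mid_ccw <- (a0 + d_ccw / 2) %% (2 * pi)
    through_lv <- abs(ang_diff(mid_ccw, lv_dir)) < pi / 2
    ang_rv <- if (through_lv) a0 - seq(0, (2 * pi - d_ccw), length.out = 25)
              else a0 + seq(0, d_ccw, length.out = 25)
    rv_poly <- cbind(rc[1] - (spec$rv_radius - 1) * sin(ang_rv),
                     rc[2] + (spec$rv_radius - 1) * cos(ang_rv))
    seeds$rvbp_polyline <- matrix(jit(rv_poly), ncol = 2)
    # closed polygon inside the lung disc
    lung_center <- c(ctr[1], ctr[2] + truth$epi_px + 24)
    a_lung <- seq(0, 2 * pi, length.out = 17)[-17]
    seeds$lung_polyline <- matrix(jit(cbind(lung_center[1] - 12 * sin(a_lung),
                                            lung_center[2] + 12 * cos(a_lung))),
                                  ncol = 2)
  }
  class(seeds) <- "manual_seeds"
  seeds
}

#' Generate the default three-slice phantom set
#'
#' One apical, one mid-ventricular and one basal slice under the default
#' conditions, with seeds for the requested ROI method.
#'
#' @param noise_sigma Rician noise scale applied to every slice.
#' @param rng_seed base integer seed; each slice derives its own stream.
#' @param seed_jitter seed-synthesis jitter in pixels.
#' @return Named list (`apical`, `mid`, `basal`) of [generate_phantom()] results.
#' @export
phantom_slice_set <- function(noise_sigma = 45, rng_seed = 20260920L,
                              seed_jitter = 0.5) {
  out <- lapply(c(apical = "apical", mid = "mid", basal = "basal"), function(lv) {
    generate_phantom(default_phantom_spec(lv, noise_sigma = noise_sigma,
                                          rng_seed = stage_seed(rng_seed, lv)),
                     seed_jitter = seed_jitter)
  })
  out
}
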
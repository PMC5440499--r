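#' Options for ROI placement and CNR computation
#'
#' @param nf noise factor multiplying every CNR (cancels in TE selection).
#' @param roi_radius_px radius of the circular LVBP/RVBP/lung ROIs.
#' @param air_box_px side of the square air-background ROI. The air SD enters
#'   the denominator of every CNR, so the box is sized for a stable estimate.
#' @param extrap_factor method-1 junction-ray extrapolation, as a multiple of
#'   the center-to-midwall distance along the ray.
#' @param lung_candidates number of candidate lung ROI positions (method 2).
#' @param tie_break `"shortest"` (default) or `"longest"` TE on CNR ties.
#' @return List of options.
#' @export
composite_options <- function(nf = 1, roi_radius_px = 3, air_box_px = 9,
                              extrap_factor = 1.5, lung_candidates = 8,
                              tie_break = c("shortest", "longest")) {
  list(nf = nf, roi_radius_px = roi_radius_px, air_box_px = air_box_px,
       extrap_factor = extrap_factor, lung_candidates = lung_candidates,
       tie_break = match.arg(tie_break))
}

roi_regions <- c("LVBP", "RVBP", "lung")

sector_names_for <- function(slice_level) {
  if (slice_level == "apical") c("septal", "inferior", "lateral", "anterior")
  else c("anteroseptal", "inferoseptal", "inferior", "inferolateral",
         "anterolateral", "anterior")
}

# sector index (1-based, ordered from the anterior insertion ray in the septal
# rotation sense) for angles theta
sector_index <- function(theta, th_a, dir, n_sectors) {
  rel <- (dir * (theta - th_a)) %% (2 * pi)
  pmin(floor(rel / (2 * pi / n_sectors)) + 1, n_sectors)
}

disc_roi <- function(dim, center, radius) {
  m <- disc_mask(dim, center, radius + 0.5)
  if (!any(m)) stop("ROI at (", round(center[1], 1), ", ", round(center[2], 1),
                    ") falls outside the image")
  m
}

box_roi <- function(dim, center, side) {
  h <- (side - 1) / 2
  r <- round(center[1]) + (-h:h); c <- round(center[2]) + (-h:h)
  if (any(r < 1 | r > dim[1]) || any(c < 1 | c > dim[2]))
    stop("air ROI extends outside the image")
  m <- matrix(FALSE, dim[1], dim[2])
  m[r, c] <- TRUE
  m
}

# radius of the midwall contour along the ray at angle `ang` from `center`
midwall_radius_at <- function(midwall, center, ang) {
  th <- px_angle(midwall[, 1], midwall[, 2], center)
  r <- sqrt((midwall[, 1] - center[1])^2 + (midwall[, 2] - center[2])^2)
  d <- abs(ang_diff(th, ang))
  w <- exp(-(d / 0.12)^2)
  if (sum(w) < 1e-8) r[which.min(d)] else sum(w * r) / sum(w)
}

finish_roiset <- function(rois, dim) {
  # sector-label map of the wall band and pairwise-disjointness check
  band <- dilate_px(poly_band(rois$midwall_contour, dim), 4)
  g <- px_grid(dim)
  theta <- px_angle(g$row, g$col, rois$lv_center)
  lab <- matrix(NA_integer_, dim[1], dim[2])
  lab[band] <- sector_index(theta[band], rois$th_a, rois$dir, rois$n_sectors)
  rois$sector_labels <- lab
  masks <- rois[c("roi_lvbp", "roi_rvbp", "roi_lung", "roi_air")]
  tot <- Reduce(`+`, lapply(masks, function(m) m * 1))
  if (any(tot > 1)) stop("ROIs overlap; check seed placement")
  rois
}

#' Place surrounding-tissue ROIs by method 1 (insertion-point extrapolation)
#'
#' The wall is divided into 4 (apical) or 6 (mid/basal) angular sectors
#' anchored at the anterior RV insertion point. The LVBP ROI sits at the
#' sector cross-point (the mid-wall contour centroid); the RVBP and lung ROIs
#' are found by extrapolating the anteroseptal/inferoseptal and the
#' inferolateral/anterolateral sector junctions beyond the wall. On apical
#' slices RVBP and lung positions come from the manually marked points.
#' All ROIs propagate unchanged to every echo.
#'
#' @param series an [mge_series()].
#' @param seeds a `manual_seeds` with `method == 1`.
#' @param opts [composite_options()].
#' @return An ROI set: masks `roi_lvbp`, `roi_rvbp`, `roi_lung`, `roi_air`,
#'   the mid-wall contour and band, insertion points, and the angular sector
#'   map of the wall band.
#' @export
place_rois_method1 <- function(series, seeds, opts = composite_options()) {
  if (seeds$method != 1L) stop("seeds are not for method 1")
  if (is.null(seeds$insertion_point)) stop("method 1 needs insertion_point")
  dim <- series_dim(series)
  midwall <- poly_resample(seeds$midwall_polyline, 96)
  center <- poly_centroid(midwall)
  apical <- series$slice_level == "apical"
  n_sectors <- if (apical) 4L else 6L
  th_a <- px_angle(seeds$insertion_point[1], seeds$insertion_point[2], center)
  # standard short-axis display orientation (RV on the viewer's left):
  # the septum lies counter-clockwise of the anterior insertion ray
  dir <- 1
  rois <- list(midwall_contour = midwall, lv_center = center,
               th_a = th_a, dir = dir, n_sectors = n_sectors,
               sector_names = sector_names_for(series$slice_level),
               insertion_anterior = seeds$insertion_point)
  sector_span <- 2 * pi / n_sectors
  # synthetic inferior insertion ray two septal sectors past the anterior one
  th_i <- th_a + dir * 2 * sector_span
  r_ins <- midwall_radius_at(midwall, center, th_i) * 1.2
  rois$insertion_inferior <- c(center[1] - r_ins * sin(th_i),
                               center[2] + r_ins * cos(th_i))
  rois$roi_lvbp <- disc_roi(dim, center, opts$roi_radius_px)
  place_on_ray <- function(ang, what) {
    r_mid <- midwall_radius_at(midwall, center, ang)
    p <- c(center[1] - opts$extrap_factor * r_mid * sin(ang),
           center[2] + opts$extrap_factor * r_mid * cos(ang))
    if (any(p < 1 + opts$roi_radius_px) ||
        p[1] > dim[1] - opts$roi_radius_px || p[2] > dim[2] - opts$roi_radius_px)
      stop("extrapolated ", what, " ROI falls outside the image (sector junction ",
           "angle ", round(ang * 180 / pi, 1), " deg)")
    p
  }
  if (apical) {
    if (is.null(seeds$apical_rvbp_point) || is.null(seeds$apical_lung_point))
      stop("apical method-1 seeds need apical_rvbp_point and apical_lung_point")
    rois$roi_rvbp <- disc_roi(dim, seeds$apical_rvbp_point, opts$roi_radius_px)
    rois$roi_lung <- disc_roi(dim, seeds$apical_lung_point, opts$roi_radius_px)
  } else {
    rois$roi_rvbp <- disc_roi(dim, place_on_ray(th_a + dir * sector_span, "RVBP"),
                              opts$roi_radius_px)
    rois$roi_lung <- disc_roi(dim, place_on_ray(th_a + dir * 4 * sector_span, "lung"),
                              opts$roi_radius_px)
  }
  rois$roi_air <- box_roi(dim, seeds$air_point, opts$air_box_px)
  finish_roiset(rois, dim)
}

#' Place surrounding-tissue ROIs by method 2 (traced RVBP and lung contours)
#'
#' The anterior and inferior RV insertion points are taken automatically from
#' the two endpoints of the traced RVBP polyline (anterior end first). The
#' LVBP ROI sits at the mid-wall contour centroid, the RVBP ROI at the
#' centroid of the region enclosed by the RVBP contour closed across the
#' septum, and the lung ROI at the candidate position (inside the lung
#' contour) with minimum intensity variance on the shortest-TE image, which
#' keeps it clear of lung vessels.
#'
#' @inheritParams place_rois_method1
#' @param seeds a `manual_seeds` with `method == 2` carrying `rvbp_polyline`
#'   (open) and `lung_polyline` (closed).
#' @return Same structure as [place_rois_method1()].
#' @export
place_rois_method2 <- function(series, seeds, opts = composite_options()) {
  if (seeds$method != 2L) stop("seeds are not for method 2")
  if (is.null(seeds$rvbp_polyline) || is.null(seeds$lung_polyline))
    stop("method 2 needs rvbp_polyline and lung_polyline")
  dim <- series_dim(series)
  midwall <- poly_resample(seeds$midwall_polyline, 96)
  center <- poly_centroid(midwall)
  apical <- series$slice_level == "apical"
  n_sectors <- if (apical) 4L else 6L
  rv <- seeds$rvbp_polyline
  ins_a <- rv[1, ]; ins_i <- rv[nrow(rv), ]
  th_a <- px_angle(ins_a[1], ins_a[2], center)
  th_i <- px_angle(ins_i[1], ins_i[2], center)
  dir <- if (((th_i - th_a) %% (2 * pi)) < pi) 1 else -1
  rois <- list(midwall_contour = midwall, lv_center = center,
               th_a = th_a, dir = dir, n_sectors = n_sectors,
               sector_names = sector_names_for(series$slice_level),
               insertion_anterior = ins_a, insertion_inferior = ins_i)
  rois$roi_lvbp <- disc_roi(dim, center, opts$roi_radius_px)
  rois$roi_rvbp <- disc_roi(dim, poly_centroid(poly_close(rv)), opts$roi_radius_px)
  lung_poly <- seeds$lung_polyline
  lung_centroid <- poly_centroid(lung_poly)
  ring <- poly_resample(lung_poly, opts$lung_candidates)
  shortest <- series$images[[1]]
  best <- NULL; best_var <- Inf
  for (k in seq_len(nrow(ring))) {
    cand <- lung_centroid + 0.55 * (ring[k, ] - lung_centroid)
    m <- disc_mask(dim, cand, opts$roi_radius_px + 0.5)
    if (!any(m)) next
    pts <- which(m, arr.ind = TRUE)
    if (!all(mgcv::in.out(poly_close(lung_poly), pts))) next
    v <- stats::var(shortest[m])
    if (v < best_var) { best_var <- v; best <- m }
  }
  if (is.null(best)) stop("no lung ROI candidate fits inside the lung contour")
  rois$roi_lung <- best
  rois$roi_air <- box_roi(dim, seeds$air_point, opts$air_box_px)
  finish_roiset(rois, dim)
}

#' Contrast-to-noise ratio of the myocardium against each surrounding region
#'
#' `CNR = NF * |SI_s - SI_m| / sigma_b` per echo and region, where `SI_s` is
#' the mean intensity of the surrounding-region ROI and `SI_m` the mean along
#' the one-pixel mid-wall band on that echo. `sigma_b`, the SD of the
#' air-background ROI, is estimated once from the air pixels pooled across
#' all echoes: magnitude-MRI background noise does not depend on TE, and the
#' pooled estimate avoids per-echo sampling error perturbing the TE
#' selection. On strictly noiseless input the air SD is floored at a tiny
#' fraction of the maximum signal so that the (scale-invariant) TE selection
#' stays defined.
#'
#' @param series an [mge_series()].
#' @param rois an ROI set from [place_rois_method1()] / [place_rois_method2()].
#' @param nf noise factor.
#' @return Data frame with one row per (TE, region): `te`, `region`, `si_s`,
#'   `si_m`, `sigma_b`, `nf`, `cnr`.
#' @export
compute_cnr <- function(series, rois, nf = 1) {
  dim <- series_dim(series)
  band <- poly_band(rois$midwall_contour, dim)
  masks <- list(LVBP = rois$roi_lvbp, RVBP = rois$roi_rvbp, lung = rois$roi_lung)
  for (nm in names(masks)) {
    if (is.null(masks[[nm]]) || !any(masks[[nm]]))
      stop("empty ROI: ", nm)
  }
  if (!any(rois$roi_air)) stop("empty ROI: air")
  sigma_floor <- 1e-6 * max(vapply(series$images, max, 0))
  air_pooled <- unlist(lapply(series$images, function(im) im[rois$roi_air]))
  sigma_b <- max(stats::sd(air_pooled), sigma_floor)
  rows <- list()
  for (i in seq_along(series$te_list)) {
    img <- series$images[[i]]
    si_m <- mean(img[band])
    for (nm in roi_regions) {
      si_s <- mean(img[masks[[nm]]])
      rows[[length(rows) + 1]] <- data.frame(
        te = series$te_list[i], region = nm, si_s = si_s, si_m = si_m,
        sigma_b = sigma_b, nf = nf,
        cnr = nf * abs(si_s - si_m) / sigma_b,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Select the CNR-optimal echo per region and derive composite weights
#'
#' Per region the echo with maximal CNR is chosen (ties go to the shorter TE
#' by default). The unique selected echoes are weighted 1 (one echo), 2/3 and
#' 1/3 (two echoes, the doubly-selected echo getting 2/3), or 1/3 each
#' (three echoes).
#'
#' @param cnr_table data frame from [compute_cnr()].
#' @param tie_break `"shortest"` or `"longest"`.
#' @return List with `te_lvbp`, `te_rvbp`, `te_lung` (selected TEs in ms),
#'   `te_index` (named indices into the TE list) and `weights` (named by TE).
#' @export
select_optimal_tes <- function(cnr_table, tie_break = "shortest") {
  tes <- sort(unique(cnr_table$te))
  pick <- function(region) {
    sub <- cnr_table[cnr_table$region == region, , drop = FALSE]
    if (nrow(sub) != length(tes)) stop("CNR table incomplete for region ", region)
    sub <- sub[order(sub$te, decreasing = (tie_break == "longest")), , drop = FALSE]
    sub$te[which.max(sub$cnr)]   # first max, i.e. tie-break by sort order
  }
  sel <- c(LVBP = pick("LVBP"), RVBP = pick("RVBP"), lung = pick("lung"))
  counts <- table(sel)
  u <- as.numeric(names(counts))
  w <- as.numeric(counts) / 3
  weights <- stats::setNames(w, format(u, trim = TRUE))
  list(te_lvbp = sel[["LVBP"]], te_rvbp = sel[["RVBP"]], te_lung = sel[["lung"]],
       te_index = stats::setNames(match(sel, tes), names(sel)),
       weights = weights)
}

#' Build the contrast-optimized composite image
#'
#' The composite is the weighted sum of the selected echoes. When an ROI set
#' is supplied, the per-region CNR gain of the composite over the best
#' single-TE CNR (same ROIs) is reported as a percentage. The composite's
#' background noise level is obtained by propagation, `sqrt(sum(w^2))` times
#' the pooled per-echo air SD: the composite is a known linear combination of
#' independently acquired echoes, so propagating the pooled estimate is exact
#' and avoids the sampling error of re-estimating an SD from one small ROI.
#'
#' @param series an [mge_series()].
#' @param selection result of [select_optimal_tes()].
#' @param rois optional ROI set for the CNR gain computation.
#' @param nf noise factor.
#' @return List (`composite_image`) with `image`, `selection`, `cnr_table`
#'   (when `rois` given) and `cnr_gain_pct` (named per region).
#' @export
build_composite <- function(series, selection, rois = NULL, nf = 1) {
  tes <- series$te_list
  w <- selection$weights
  img <- 0
  for (j in seq_along(w)) {
    te_j <- as.numeric(names(w)[j])
    idx <- which.min(abs(tes - te_j))
    img <- img + w[j] * series$images[[idx]]
  }
  out <- list(image = img, selection = selection, cnr_table = NULL,
              cnr_gain_pct = NULL)
  if (!is.null(rois)) {
    tab <- compute_cnr(series, rois, nf = nf)
    dim <- series_dim(series)
    band <- poly_band(rois$midwall_contour, dim)
    sigma_c <- sqrt(sum(w^2)) * tab$sigma_b[1]
    si_m_c <- mean(img[band])
    gains <- sapply(roi_regions, function(nm) {
      mask <- rois[[paste0("roi_", tolower(nm))]]
      cnr_c <- nf * abs(mean(img[mask]) - si_m_c) / sigma_c
      best <- max(tab$cnr[tab$region == nm])
      100 * (cnr_c - best) / best
    })
    out$cnr_table <- tab
    out$cnr_gain_pct <- gains
  }
  class(out) <- "composite_image"
  out
}
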
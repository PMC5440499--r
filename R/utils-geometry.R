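# Internal geometry helpers shared by the segmentation stages.
#
# Conventions (used consistently across the package):
#  * images are numeric matrices indexed [row, col], 1-based, pixel centers at
#    integer coordinates;
#  * polylines are n x 2 matrices cbind(row, col), closed implicitly (last
#    vertex connects back to the first);
#  * angles are measured about a center with 0 pointing to increasing columns
#    ("east") and pi/2 pointing to decreasing rows ("up"/anterior), in [0, 2*pi).

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
px_angle <- function(row, col, center) {
  (atan2(-(row - center[1]), col - center[2])) %% (2 * pi)
}

# signed smallest difference a - b on the circle, in (-pi, pi]
ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

px_grid <- function(dim) {
  list(row = matrix(seq_len(dim[1]), dim[1], dim[2]),
       col = matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE))
}

disc_mask <- function(dim, center, radius) {
  g <- px_grid(dim)
  (g$row - center[1])^2 + (g$col - center[2])^2 < radius^2
}

poly_close <- function(xy) {
  if (!isTRUE(all.equal(xy[1, ], xy[nrow(xy), ]))) xy <- rbind(xy, xy[1, ])
  xy
}

# shoelace area (absolute)
poly_area <- function(xy) {
  xy <- poly_close(xy)
  n <- nrow(xy)
  x <- xy[, 2]; y <- xy[, 1]
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

poly_centroid <- function(xy) {
  # vertex-mean centroid is adequate for near-uniformly sampled contours
  xy <- xy[!duplicated(xy), , drop = FALSE]
  colMeans(xy)
}

poly_perimeter <- function(xy) {
  xy <- poly_close(xy)
  sum(sqrt(rowSums(diff(xy)^2)))
}

#' Resample a closed polyline to n vertices at uniform arc length
#' @noRd
poly_resample <- function(xy, n) {
  xy <- poly_close(xy)
  seg <- sqrt(rowSums(diff(xy)^2))
  s <- c(0, cumsum(seg))
  keep <- c(TRUE, seg > 1e-12)
  xy <- xy[keep, , drop = FALSE]
  s <- s[keep]
  total <- s[length(s)]
  if (total <= 0) return(matrix(xy[1, ], n, 2, byrow = TRUE))
  t_new <- seq(0, total, length.out = n + 1)[-(n + 1)]
  cbind(stats::approx(s, xy[, 1], xout = t_new)$y,
        stats::approx(s, xy[, 2], xout = t_new)$y)
}

#' Pixel-centers-strictly-inside polygon rasterization
#' @noRd
fill_polygon <- function(poly, dim) {
  poly <- poly_close(poly)
  rr <- range(poly[, 1]); cc <- range(poly[, 2])
  r_idx <- max(1L, floor(rr[1])):min(dim[1], ceiling(rr[2]))
  c_idx <- max(1L, floor(cc[1])):min(dim[2], ceiling(cc[2]))
  mask <- matrix(FALSE, dim[1], dim[2])
  if (!length(r_idx) || !length(c_idx)) return(mask)
  pts <- cbind(rep(r_idx, times = length(c_idx)),
               rep(c_idx, each = length(r_idx)))
  inside <- mgcv::in.out(poly, pts)
  mask[pts[inside, , drop = FALSE]] <- TRUE
  mask
}

#' Trace the outer boundary of a binary mask as a closed polyline (row, col)
#' @noRd
mask_boundary <- function(mask) {
  stopifnot(any(mask))
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  oc <- oc[[which.max(vapply(oc, nrow, 1L))]]
  oc + 1  # ocontour is 0-based
}

#' Euclidean distance of every pixel to the nearest mask pixel (0 on the mask)
#' @noRd
dist_to_mask <- function(mask) {
  EBImage::imageData(EBImage::distmap(EBImage::Image((!mask) * 1)))
}

dilate1 <- function(mask) {
  EBImage::imageData(EBImage::dilate(EBImage::Image(mask * 1),
                                     EBImage::makeBrush(3, "diamond"))) > 0
}

erode1 <- function(mask) {
  EBImage::imageData(EBImage::erode(EBImage::Image(mask * 1),
                                    EBImage::makeBrush(3, "diamond"))) > 0
}

dilate_px <- function(mask, n) {
  for (i in seq_len(n)) mask <- dilate1(mask)
  mask
}

#' Largest connected component, optionally the one containing a given point
#' @noRd
largest_component <- function(mask, contains = NULL) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  if (max(lab) == 0) return(mask & FALSE)
  if (!is.null(contains)) {
    p <- round(contains)
    if (p[1] >= 1 && p[1] <= nrow(lab) && p[2] >= 1 && p[2] <= ncol(lab)) {
      id <- lab[p[1], p[2]]
      if (id > 0) return(lab == id)
    }
  }
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

#' Fill interior holes of a mask
#' @noRd
fill_holes <- function(mask) {
  EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
}

#' Bilinear interpolation of a matrix at fractional (row, col) points
#' @noRd
bilinear_interp <- function(img, pts) {
  r <- clamp(pts[, 1], 1, nrow(img))
  c <- clamp(pts[, 2], 1, ncol(img))
  r0 <- clamp(floor(r), 1, nrow(img) - 1)
  c0 <- clamp(floor(c), 1, ncol(img) - 1)
  fr <- r - r0; fc <- c - c0
  i00 <- img[cbind(r0, c0)];     i01 <- img[cbind(r0, c0 + 1)]
  i10 <- img[cbind(r0 + 1, c0)]; i11 <- img[cbind(r0 + 1, c0 + 1)]
  (1 - fr) * (1 - fc) * i00 + (1 - fr) * fc * i01 +
    fr * (1 - fc) * i10 + fr * fc * i11
}

#' Gradient-magnitude edge map of a Gaussian-smoothed image, scaled to [0, 1]
#' @noRd
edge_map <- function(img, sigma = 1) {
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = sigma))
  gr <- sm * 0; gc <- sm * 0
  gr[2:(nrow(sm) - 1), ] <- (sm[3:nrow(sm), ] - sm[1:(nrow(sm) - 2), ]) / 2
  gc[, 2:(ncol(sm) - 1)] <- (sm[, 3:ncol(sm)] - sm[, 1:(ncol(sm) - 2)]) / 2
  g <- sqrt(gr^2 + gc^2)
  if (max(g) > 0) g <- g / max(g)
  g
}

#' Rasterize a closed polyline onto the pixel grid (1-pixel-wide band)
#' @noRd
poly_band <- function(poly, dim) {
  poly <- poly_close(poly)
  pts <- NULL
  for (i in seq_len(nrow(poly) - 1)) {
    d <- sqrt(sum((poly[i + 1, ] - poly[i, ])^2))
    n <- max(2L, ceiling(d * 3))
    t <- seq(0, 1, length.out = n)
    pts <- rbind(pts, cbind(poly[i, 1] + t * (poly[i + 1, 1] - poly[i, 1]),
                            poly[i, 2] + t * (poly[i + 1, 2] - poly[i, 2])))
  }
  px <- unique(round(pts))
  px <- px[px[, 1] >= 1 & px[, 1] <= dim[1] & px[, 2] >= 1 & px[, 2] <= dim[2], , drop = FALSE]
  mask <- matrix(FALSE, dim[1], dim[2])
  mask[px] <- TRUE
  mask
}

#' Derive a reproducible child seed from a base seed and a stage label
#' @noRd
stage_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) + offs * 1009L) %% 2147483629L
}
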
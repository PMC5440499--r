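#' Configuration of the myocardial border search
#'
#' Defaults follow the method's published constants: 20% coefficient-of-
#' variation stop threshold, 70%/40% false-layer occupancy cut-offs for the
#' anterior-septal-posterior and lateral walls, a maximum of 2 layers
#' difference between neighbouring radial segments, quartile-fence factor
#' 0.9825 for border outliers, 2 extra candidate layers inward/outward in the
#' final optimization, layer expansion limits of 14 mm (basal, mid) / 8 mm
#' (apical) derived from maximal normal wall thickness, and 72 (basal, mid) /
#' 40 (apical) radial segments so that innermost-layer cells hold at most two
#' pixel stacks.
#'
#' @param cov_threshold CoV stop threshold (fraction).
#' @param cutoff_main,cutoff_lateral occupancy cut-offs (fractions).
#' @param neighbor_max_diff maximum accepted-layer difference between
#'   neighbouring segments.
#' @param iqr_factor quartile-fence factor: outliers lie outside
#'   `[Q1 - f*IQR, Q3 + f*IQR]`.
#' @param extra_layers candidate layer shifts tested inward/outward.
#' @param expansion_limit_mm named layer-extent limits per slice level (mm).
#' @param n_radial named radial segment counts per slice level.
#' @param cov_mode `"cumulative"` (CoV over all accepted pixels of the segment
#'   including the candidate layer) or `"layer"` (candidate layer alone).
#' @return List of configuration values.
#' @export
border_config <- function(cov_threshold = 0.20, cutoff_main = 0.70,
                          cutoff_lateral = 0.40, neighbor_max_diff = 2,
                          iqr_factor = 0.9825, extra_layers = 2,
                          expansion_limit_mm = c(basal = 14, mid = 14, apical = 8),
                          n_radial = c(basal = 72, mid = 72, apical = 40),
                          cov_mode = c("cumulative", "layer")) {
  stopifnot(cov_threshold > 0, cov_threshold < 1,
            cutoff_main > 0, cutoff_main < 1,
            cutoff_lateral > 0, cutoff_lateral < 1,
            all(expansion_limit_mm > 0), all(n_radial >= 8))
  list(cov_threshold = cov_threshold, cutoff_main = cutoff_main,
       cutoff_lateral = cutoff_lateral, neighbor_max_diff = neighbor_max_diff,
       iqr_factor = iqr_factor, extra_layers = extra_layers,
       expansion_limit_mm = expansion_limit_mm, n_radial = n_radial,
       cov_mode = match.arg(cov_mode))
}

#' Radial layer grid around the LV blood pool
#'
#' Decomposes the band around the LVBP into one-pixel-thick expansion layers
#' (successive unit-disc dilations of the pool, i.e. Euclidean distance rings)
#' crossed with radial angular segments about the pool centroid. The grid
#' extends past any possible myocardial extent (14 mm basal/mid, 8 mm apical
#' by default) with 72 (basal/mid) or 40 (apical) segments.
#'
#' @param lvbp an `lvbp_region` (or list with `mask`).
#' @param composite_image the composite intensity matrix.
#' @param slice_level slice level.
#' @param pixel_spacing in-plane spacing, mm.
#' @param rois ROI set (for the anatomical sector grouping of segments).
#' @param cfg [border_config()].
#' @return A `radial_layer_grid`: `cells[[s]][[l]]` linear pixel indices,
#'   cached `counts` / `means` matrices, segment sector groups, geometry.
#' @export
build_layer_grid <- function(lvbp, composite_image, slice_level, pixel_spacing,
                             rois, cfg = border_config()) {
  mask <- lvbp$mask
  dim <- dim(mask)
  n_layers <- as.integer(ceiling(cfg$expansion_limit_mm[[slice_level]] / pixel_spacing))
  n_seg <- as.integer(cfg$n_radial[[slice_level]])
  idx <- which(mask, arr.ind = TRUE)
  margin <- n_layers + 1
  if (min(idx) <= margin || max(idx[, 1]) > dim[1] - margin ||
      max(idx[, 2]) > dim[2] - margin)
    stop("LVBP too close to the image border for ", n_layers, " expansion layers")
  centroid <- colMeans(idx)
  dist <- dist_to_mask(mask)
  layer <- ceiling(dist - 1e-9)
  in_grid <- layer >= 1 & layer <= n_layers
  g <- px_grid(dim)
  theta <- px_angle(g$row, g$col, centroid)
  seg <- pmin(floor(theta / (2 * pi / n_seg)) + 1, n_seg)
  cells <- lapply(seq_len(n_seg), function(s) vector("list", n_layers))
  w <- which(in_grid)
  split_key <- (seg[w] - 1L) * n_layers + layer[w]
  by_cell <- split(w, split_key)
  counts <- matrix(0L, n_seg, n_layers)
  means <- matrix(NA_real_, n_seg, n_layers)
  for (key in names(by_cell)) {
    kk <- as.integer(key)
    s <- (kk - 1L) %/% n_layers + 1L
    l <- (kk - 1L) %% n_layers + 1L
    px <- by_cell[[key]]
    cells[[s]][[l]] <- px
    counts[s, l] <- length(px)
    means[s, l] <- mean(composite_image[px])
  }
  # anatomical group of each radial segment via its bisector angle
  bis <- (seq_len(n_seg) - 0.5) * (2 * pi / n_seg)
  sec <- sector_index(bis, rois$th_a, rois$dir, rois$n_sectors)
  sec_name <- rois$sector_names[sec]
  group <- ifelse(sec_name %in% c("inferolateral", "anterolateral", "lateral"),
                  "lateral", "main")
  grid <- list(n_segments = n_seg, n_layers = n_layers, cells = cells,
               counts = counts, means = means, centroid = centroid,
               seg_group = group, seg_sector = sec_name,
               image = composite_image, slice_level = slice_level)
  class(grid) <- "radial_layer_grid"
  grid
}

cell_px <- function(grid, s, l) grid$cells[[s]][[l]] %||% integer(0)

cov_of <- function(values) {
  if (length(values) < 2) return(0)
  m <- mean(values)
  if (m <= 0) return(Inf)
  stats::sd(values) / m
}

#' Layer expansion by coefficient-of-variation assessment
#'
#' Starting from the adjacent segment pair whose combined innermost-layer
#' pixels have the smallest CoV, each radial segment expands outward layer by
#' layer (two fronts propagating circumferentially from the start pair); a
#' segment stops as soon as the CoV of its signal intensity exceeds the
#' threshold (20% by default). With `cov_mode = "cumulative"` the CoV is
#' computed over all accepted pixels of the segment including the candidate
#' layer.
#'
#' @param grid a `radial_layer_grid`.
#' @param cfg [border_config()].
#' @return Integer vector of accepted layer counts per segment, with the
#'   start pair as attribute `start_pair`.
#' @export
cov_expand <- function(grid, cfg = border_config()) {
  n <- grid$n_segments
  inner_cov <- vapply(seq_len(n), function(s) {
    px <- c(cell_px(grid, s, 1), cell_px(grid, (s %% n) + 1, 1))
    if (!length(px)) return(Inf)
    cov_of(grid$image[px])
  }, 0)
  start <- which.min(inner_cov)          # pair (start, start+1)
  order_idx <- unique(c(start, (start %% n) + 1,
                        as.vector(rbind(((start - 1 - seq_len(n)) %% n) + 1,
                                        ((start + seq_len(n)) %% n) + 1))))
  order_idx <- order_idx[seq_len(n)]
  accepted <- integer(n)
  for (s in order_idx) {
    cum <- integer(0)
    for (l in seq_len(grid$n_layers)) {
      px <- cell_px(grid, s, l)
      if (!length(px)) {
        # an empty cell (angular discretization) carries no evidence; only
        # count it as accepted when the expansion continues past it
        if (l < grid$n_layers && length(cell_px(grid, s, l + 1))) next
        break
      }
      test_px <- if (cfg$cov_mode == "cumulative") c(cum, px) else px
      if (cov_of(grid$image[test_px]) > cfg$cov_threshold) break
      cum <- c(cum, px)
      accepted[s] <- l
    }
  }
  attr(accepted, "start_pair") <- c(start, (start %% n) + 1)
  accepted
}

#' Refine anterior/septal/posterior layer counts by two-cluster k-means
#'
#' In the low-contrast anterior, septal and posterior walls the CoV expansion
#' overshoots; the accepted pixels there are clustered into two intensity
#' groups and the inner cluster (smaller mean layer index) is retained. A
#' layer stays accepted while at least half of its pixels belong to the inner
#' cluster; counts are recomputed as the outermost contiguous retained layer.
#' When the two cluster means differ by less than the CoV threshold
#' (relative to their pooled mean) the clustering is considered
#' non-informative and counts are returned unchanged. Lateral segments are
#' never modified.
#'
#' @param grid a `radial_layer_grid`.
#' @param counts accepted layers from [cov_expand()].
#' @param seed integer seed for the k-means.
#' @param cfg [border_config()].
#' @return Updated integer vector of accepted layers.
#' @export
kmeans_refine <- function(grid, counts, seed = 1L, cfg = border_config()) {
  scope <- which(grid$seg_group == "main")
  px <- integer(0); lay <- integer(0); seg_of <- integer(0)
  for (s in scope) {
    for (l in seq_len(counts[s])) {
      p <- cell_px(grid, s, l)
      px <- c(px, p); lay <- c(lay, rep(l, length(p)))
      seg_of <- c(seg_of, rep(s, length(p)))
    }
  }
  if (length(px) < 4 || length(unique(grid$image[px])) < 2) return(counts)
  cl <- kmeans_cluster(grid$image[px], k = 2, seed = seed)
  sep <- abs(diff(cl$centers)) / mean(grid$image[px])
  if (sep < cfg$cov_threshold) return(counts)  # no distinct tissue populations
  # the inner cluster is the one holding the majority of the two innermost
  # layers' pixels (robust against stray bright pixels at layer 1)
  in12 <- lay <= 2
  share1 <- mean(cl$labels[in12] == 1)
  inner_cluster <- if (share1 >= 0.5) 1L else 2L
  keep <- cl$labels == inner_cluster
  out <- counts
  for (s in scope) {
    acc <- 0L
    for (l in seq_len(counts[s])) {
      in_l <- seg_of == s & lay == l
      if (!any(in_l)) break
      if (mean(keep[in_l]) >= 0.5) acc <- l else break
    }
    out[s] <- acc
  }
  out
}

#' Remove under-occupied outer layers (false-area correction)
#'
#' Operates per anatomical wall position (anterior/septal/posterior walls
#' with a 70% cut-off, the lung-adjacent lateral wall with 40%): within each
#' position, the accepted pixel count of every expansion layer is totalled
#' over the position's radial segments, and outermost layers whose total
#' falls below the cut-off fraction of the position's maximum per-layer total
#' are stripped from all of its segments, iterating inward until the
#' condition fails. Totalling over a wall position (rather than judging each
#' 1-2-pixel cell alone) is what makes the occupancy fraction meaningful.
#'
#' @param grid a `radial_layer_grid`.
#' @param counts accepted layer counts.
#' @param cfg [border_config()].
#' @return Updated counts (never larger than the input).
#' @export
correct_false_layers <- function(grid, counts, cfg = border_config()) {
  out <- counts
  for (sector in unique(grid$seg_sector)) {
    segs <- which(grid$seg_sector == sector)
    cutoff <- if (grid$seg_group[segs[1]] == "lateral") cfg$cutoff_lateral
              else cfg$cutoff_main
    repeat {
      top <- max(out[segs])
      if (top == 0) break
      layer_tot <- vapply(seq_len(top), function(l)
        sum(grid$counts[segs[out[segs] >= l], l]), 0)
      if (layer_tot[top] < cutoff * max(layer_tot)) {
        out[segs] <- pmin(out[segs], top - 1L)
      } else break
    }
  }
  out
}

#' Cap the accepted-layer difference between neighbouring segments
#'
#' Iteratively clips each segment's accepted count so that it differs from
#' its circular neighbours by at most `neighbor_max_diff` (2 by default),
#' always reducing the larger value. The fixed point is computed in closed
#' form as the circular lower envelope
#' `a'[s] = min_t (a[t] + d * dist(s, t))`, which is what the relaxation
#' converges to irrespective of sweep order.
#'
#' @param counts integer vector of accepted layers (circular).
#' @param cfg [border_config()].
#' @return Smoothed counts (elementwise <= input).
#' @export
limit_neighbor_difference <- function(counts, cfg = border_config()) {
  n <- length(counts)
  d <- cfg$neighbor_max_diff
  s_idx <- seq_len(n)
  out <- vapply(s_idx, function(s) {
    dist <- pmin(abs(s_idx - s), n - abs(s_idx - s))
    min(counts + d * dist)
  }, 0)
  as.integer(out)
}

# endocardial-side erosion rings of the LVBP mask: ring k = pixels freed by
# the k-th unit erosion
endo_rings <- function(lvbp_mask, n) {
  rings <- vector("list", n)
  cur <- lvbp_mask
  for (k in seq_len(n)) {
    nxt <- erode1(cur)
    rings[[k]] <- which(cur & !nxt)
    cur <- nxt
  }
  rings
}

#' Final border optimization by quartile-fence outlier minimization
#'
#' Tests every global combination of endocardial and epicardial layer shifts
#' within `+/- extra_layers` (25 candidates by default). Border homogeneity is
#' judged relative to the whole myocardium: the quartile fences
#' `[Q1 - 0.9825*IQR, Q3 + 0.9825*IQR]` are computed once from the intensity
#' distribution of the initial (unshifted) annulus, and for each candidate
#' the pixels of its innermost and outermost one-pixel layers falling outside
#' those fences are counted as outliers. The candidate minimizing the
#' outlier-to-total ratio wins (ties: closest to the unshifted contour, then
#' smaller area); its outlier pixels are excluded from the final myocardial
#' mask.
#'
#' @param grid a `radial_layer_grid`.
#' @param counts accepted layer counts after steps 7-9.
#' @param lvbp the `lvbp_region` the grid was built from.
#' @param composite_image composite intensity matrix.
#' @param cfg [border_config()].
#' @return A `myocardial_contours`: `endo_mask`, `epi_mask`, `myo_mask`,
#'   `endo_polyline`, `epi_polyline`, `excluded_outliers` (mask), the chosen
#'   `delta` and the candidate `search` table.
#' @export
optimize_borders <- function(grid, counts, lvbp, composite_image,
                             cfg = border_config()) {
  if (all(counts == 0)) stop("no accepted layers: initial annulus is empty")
  n <- grid$n_segments
  ex <- cfg$extra_layers
  rings <- endo_rings(lvbp$mask, ex)
  dim <- dim(lvbp$mask)

  base_px <- unlist(lapply(seq_len(n), function(s)
    unlist(lapply(seq_len(counts[s]), function(l) cell_px(grid, s, l)))))
  if (length(base_px) < 8) stop("initial annulus too small for border optimization")
  q <- stats::quantile(composite_image[base_px], c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  fence_lo <- q[1] - cfg$iqr_factor * iqr
  fence_hi <- q[2] + cfg$iqr_factor * iqr

  candidate <- function(d_endo, d_epi) {
    # d_endo > 0: myocardium grows inward by |d_endo| erosion rings of the pool
    # d_endo < 0: innermost |d_endo| grid layers are surrendered to the pool
    first_layer <- 1L + max(0L, -d_endo)
    counts_c <- pmin(pmax(counts + d_epi, 0L), grid$n_layers)
    myo <- integer(0); inner <- integer(0); outer <- integer(0)
    if (d_endo > 0) {
      add <- unlist(rings[seq_len(d_endo)])
      myo <- add
      inner <- rings[[d_endo]]
    }
    for (s in seq_len(n)) {
      if (counts_c[s] < first_layer) next
      for (l in first_layer:counts_c[s]) myo <- c(myo, cell_px(grid, s, l))
      outer <- c(outer, cell_px(grid, s, counts_c[s]))
    }
    if (d_endo <= 0) {
      inner <- unlist(lapply(seq_len(n), function(s)
        if (counts_c[s] >= first_layer) cell_px(grid, s, first_layer) else integer(0)))
    }
    if (length(myo) < 8) return(NULL)
    border <- unique(c(inner, outer))
    is_out <- function(px) composite_image[px] < fence_lo |
                           composite_image[px] > fence_hi
    out_px <- border[is_out(border)]
    # rate of fence outliers in the border in excess of the candidate's own
    # whole-myocardium rate: pure noise tails cancel, foreign tissue remains
    p_ref <- mean(is_out(myo))
    n_excess <- max(0, length(out_px) - p_ref * length(border))
    list(d_endo = d_endo, d_epi = d_epi, myo = myo, outliers = out_px,
         ratio = n_excess / length(myo), area = length(myo),
         counts_c = counts_c, first_layer = first_layer)
  }

  cands <- list()
  for (de in -ex:ex) for (dp in -ex:ex) {
    cand <- candidate(de, dp)
    if (!is.null(cand)) cands[[length(cands) + 1]] <- cand
  }
  if (!length(cands)) stop("all border candidates degenerate")
  ratio <- vapply(cands, `[[`, 0, "ratio")
  l1 <- vapply(cands, function(cc) abs(cc$d_endo) + abs(cc$d_epi), 0)
  area <- vapply(cands, `[[`, 0, "area")
  # a shift must beat the best ratio by a clear margin to count as better:
  # differences within the sampling noise of the border outlier rate (about
  # 2 points at these border sizes) are ties. Among tied candidates the
  # largest annulus wins - expansion stops exactly where the border starts
  # picking up foreign tissue, i.e. at the tissue boundary
  near_best <- ratio <= min(ratio) + 0.02
  ord <- order(!near_best, -area, l1, ratio,
               vapply(cands, `[[`, 0, "d_endo"), vapply(cands, `[[`, 0, "d_epi"))
  win <- cands[[ord[1]]]

  excluded <- matrix(FALSE, dim[1], dim[2])
  excluded[win$outliers] <- TRUE
  myo_mask <- matrix(FALSE, dim[1], dim[2])
  myo_mask[win$myo] <- TRUE
  endo_mask <- lvbp$mask
  if (win$d_endo > 0) endo_mask[unlist(rings[seq_len(win$d_endo)])] <- FALSE
  if (win$d_endo < 0) {
    for (s in seq_len(n)) for (l in seq_len(min(-win$d_endo, grid$n_layers)))
      endo_mask[cell_px(grid, s, l)] <- TRUE
  }
  epi_mask <- fill_holes(endo_mask | myo_mask)
  myo_mask <- myo_mask & !excluded
  search <- data.frame(d_endo = vapply(cands, `[[`, 0, "d_endo"),
                       d_epi = vapply(cands, `[[`, 0, "d_epi"),
                       outlier_ratio = ratio, area = area)
  out <- list(endo_mask = endo_mask, epi_mask = epi_mask, myo_mask = myo_mask,
              endo_polyline = mask_boundary(endo_mask),
              epi_polyline = mask_boundary(epi_mask),
              excluded_outliers = excluded,
              delta = c(endo = win$d_endo, epi = win$d_epi),
              search = search)
  class(out) <- "myocardial_contours"
  out
}

#' Full endo/epicardial border chain (segmentation part II)
#'
#' Runs the layer-grid construction, CoV expansion, k-means refinement,
#' false-layer correction, neighbour-difference capping and quartile-fence
#' border optimization in sequence.
#'
#' @param lvbp an `lvbp_region` from [detect_lvbp()].
#' @param composite a `composite_image`.
#' @param rois the ROI set of the slice.
#' @param slice_level slice level.
#' @param pixel_spacing mm per pixel.
#' @param cfg [border_config()].
#' @param seed integer seed (k-means refinement).
#' @return A `myocardial_contours` (see [optimize_borders()]), with the grid
#'   and intermediate counts attached as attributes.
#' @export
find_myocardial_contours <- function(lvbp, composite, rois, slice_level,
                                     pixel_spacing, cfg = border_config(),
                                     seed = 1L) {
  img <- composite$image
  grid <- build_layer_grid(lvbp, img, slice_level, pixel_spacing, rois, cfg)
  counts0 <- cov_expand(grid, cfg)
  counts1 <- kmeans_refine(grid, counts0, seed = stage_seed(seed, "refine"),
                           cfg = cfg)
  counts2 <- correct_false_layers(grid, counts1, cfg)
  counts3 <- limit_neighbor_difference(counts2, cfg)
  contours <- optimize_borders(grid, counts3, lvbp, img, cfg)
  attr(contours, "grid") <- grid
  attr(contours, "counts") <- list(cov = counts0, refined = counts1,
                                   corrected = counts2, smoothed = counts3)
  contours
}
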
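#' Subtraction image for blood-pool localization
#'
#' Subtracts the echo giving optimal blood/myocardium contrast from the
#' shortest-TE echo (clipped at zero). Blood, with its slow transverse decay,
#' changes little between the two echoes and becomes low and homogeneous,
#' while myocardium retains strong signal: the bright-blood contrast problem
#' is inverted.
#'
#' @param series an [mge_series()].
#' @param selection result of [select_optimal_tes()].
#' @return Intensity matrix.
#' @export
make_subtraction_image <- function(series, selection) {
  te1 <- series$te_list[1]
  te_opt <- selection$te_lvbp
  if (isTRUE(all.equal(te_opt, te1)))
    stop("optimal LVBP TE equals the shortest TE: subtraction is degenerate")
  idx <- which.min(abs(series$te_list - te_opt))
  pmax(series$images[[1]] - series$images[[idx]], 0)
}

#' Intensity k-means with deterministic, mean-ordered labels
#'
#' Clusters a vector of intensities into `k` groups (multi-start Lloyd
#' iterations, seeded) and relabels the clusters so that cluster 1 has the
#' lowest mean.
#'
#' @param values numeric vector (length >= k).
#' @param k number of clusters (>= 2).
#' @param seed integer seed.
#' @param n_restarts number of random restarts.
#' @return List with `labels` (1 = lowest-mean cluster) and sorted `centers`.
#' @export
kmeans_cluster <- function(values, k = 2, seed = 1L, n_restarts = 10) {
  if (length(values) < k) stop("need at least k values")
  if (length(unique(values)) < k)
    stop("fewer distinct values (", length(unique(values)),
         ") than clusters (", k, ")")
  set.seed(as.integer(seed))
  km <- suppressWarnings(stats::kmeans(values, centers = k, nstart = n_restarts,
                                       iter.max = 200, algorithm = "Lloyd"))
  ord <- order(km$centers)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  list(labels = relabel[km$cluster], centers = as.numeric(km$centers)[ord])
}

#' Blood-pool mask from clustered subtraction intensities
#'
#' Pixels enclosed by the mid-wall contour are clustered on the subtraction
#' image; the lowest-mean cluster (blood) is retained, high clusters
#' (myocardium, papillary muscle, artefact) are removed, and the connected
#' component containing the enclosed-region centroid is returned.
#'
#' @param subimage subtraction image from [make_subtraction_image()].
#' @param midwall_contour closed polyline traced inside the LV wall.
#' @param k number of intensity clusters.
#' @param seed integer seed for the clustering.
#' @return Logical mask of the central blood-pool core.
#' @export
blood_pool_mask <- function(subimage, midwall_contour, k = 3, seed = 1L) {
  region <- fill_polygon(midwall_contour, dim(subimage))
  if (sum(region) <= k)
    stop("mid-wall contour encloses too few pixels")
  n_distinct <- length(unique(subimage[region]))
  if (n_distinct < 2)
    stop("uniform subtraction image inside the mid-wall contour: no clusters")
  k <- min(k, n_distinct)  # noiseless synthetic data can carry few levels
  cl <- kmeans_cluster(subimage[region], k = k, seed = seed)
  # retain the low-intensity cluster(s): every cluster whose center lies
  # closer to the lowest center than to the highest is blood; the rest
  # (myocardium, papillary muscle, artefact) is removed
  midpoint <- (cl$centers[1] + cl$centers[k]) / 2
  retained <- which(cl$centers < midpoint)
  mask <- region
  mask[region] <- cl$labels %in% retained
  centroid <- colMeans(which(region, arr.ind = TRUE))
  out <- largest_component(mask, contains = centroid)
  if (!any(out))
    stop("no blood-pool cluster found; review the mid-wall contour and seeds")
  out
}

#' Detect the LV blood-pool region (segmentation part I)
#'
#' Orchestrates the blood-pool stages: subtraction image, k-means blood
#' cluster, a first VFC snake on the subtraction-image edge map shaping the
#' central pool, and a second snake (initialized on the first result dilated
#' by 2 px) on the composite-image edge map that rejoins papillary muscles and
#' trabeculae. The final region is the filled second contour united with the
#' clustered blood component, so that no detected blood pixel is left outside
#' the pool.
#'
#' @param series an [mge_series()].
#' @param composite a `composite_image` from [build_composite()].
#' @param rois ROI set (supplies the mid-wall contour).
#' @param params [vfc_params()].
#' @param k intensity cluster count for the blood-pool step.
#' @param seed integer seed.
#' @return An `lvbp_region`: `mask`, `contour`, `center`, and the intermediate
#'   `blood_cluster` and `subtraction` images.
#' @export
detect_lvbp <- function(series, composite, rois, params = vfc_params(),
                        k = 3, seed = 1L) {
  sub <- make_subtraction_image(series, composite$selection)
  bp <- blood_pool_mask(sub, rois$midwall_contour, k = k,
                        seed = stage_seed(seed, "bloodpool"))
  # both snakes are refinement stages: their interiors are clipped to the
  # 2-pixel band around their initialization so that a strong off-target
  # edge cannot drag the contour through the myocardial wall
  edge4 <- edge_map(sub)
  snake4 <- evolve_snake(mask_boundary(bp), vfc_field(edge4, params), params)
  mask4 <- fill_polygon(snake4, dim(sub)) & dilate_px(bp, 2)
  base5 <- mask4 | bp
  init5 <- mask_boundary(dilate_px(base5, 2))
  edge5 <- edge_map(composite$image)
  snake5 <- evolve_snake(init5, vfc_field(edge5, params), params)
  mask5 <- (fill_polygon(snake5, dim(sub)) & dilate_px(base5, 2)) | bp
  mask5 <- fill_holes(largest_component(mask5))
  region <- list(mask = mask5, contour = mask_boundary(mask5),
                 center = colMeans(which(mask5, arr.ind = TRUE)),
                 blood_cluster = bp, subtraction = sub)
  class(region) <- "lvbp_region"
  region
}
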
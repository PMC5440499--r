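test_that("radial grid has the slice-level segment count and layer extent", {
  res_mid <- get_segmented("mid", 0)
  grid_mid <- attr(res_mid$contours, "grid")
  expect_identical(grid_mid$n_segments, 72L)
  expect_identical(grid_mid$n_layers, 9L)    # ceil(14 mm / 1.56 mm)
  res_ap <- get_segmented("apical", 0)
  grid_ap <- attr(res_ap$contours, "grid")
  expect_identical(grid_ap$n_segments, 40L)
  expect_identical(grid_ap$n_layers, 6L)     # ceil(8 mm / 1.56 mm)
})

test_that("grid layers are one-pixel-thick disjoint distance rings", {
  res <- get_segmented("mid", 0)
  grid <- attr(res$contours, "grid")
  lv <- res$lvbp
  dist <- t2starseg:::dist_to_mask(lv$mask)
  all_px <- integer(0)
  for (s in seq_len(grid$n_segments)) for (l in seq_len(grid$n_layers)) {
    px <- grid$cells[[s]][[l]]
    if (is.null(px)) next
    expect_true(all(ceiling(dist[px] - 1e-9) == l))
    all_px <- c(all_px, px)
  }
  expect_false(any(duplicated(all_px)))
  # innermost layer cells hold at most two pixel stacks
  expect_lte(max(grid$counts[, 1]), 2L)
})

test_that("grid construction rejects a pool touching the image border", {
  mask <- matrix(FALSE, 64, 64); mask[2:20, 2:20] <- TRUE
  img <- matrix(1, 64, 64)
  rois <- get_composite_stage("mid", 0)$rois
  expect_error(build_layer_grid(list(mask = mask), img, "mid", 1.56, rois),
               "image border")
})

test_that("CoV expansion accepts uniform tissue fully and stops at steps", {
  vals <- list(default = 100)
  counts_mat <- matrix(2L, 8, 5)
  g_uniform <- fake_grid(counts_mat, vals, groups = rep("main", 8))
  c_u <- cov_expand(g_uniform)
  expect_equal(as.integer(c_u), rep(5L, 8))
  # a bright step at layer 4 halts expansion at 3 accepted layers
  vals_step <- list(default = 100)
  for (s in 1:8) for (l in 4:5) vals_step[[paste(s, l)]] <- 300
  g_step <- fake_grid(counts_mat, vals_step, groups = rep("main", 8))
  expect_equal(as.integer(cov_expand(g_step)), rep(3L, 8))
})

test_that("the expansion start pair is the adjacent pair of minimal inner CoV", {
  set.seed(14)
  n <- 10
  counts_mat <- matrix(2L, n, 3)
  vals <- list(default = 100)
  inner <- lapply(seq_len(n), function(s) 100 + abs(rnorm(2, 0, 10 + 5 * s)))
  for (s in seq_len(n)) vals[[paste(s, 1)]] <- inner[[s]]
  g <- fake_grid(counts_mat, vals, groups = rep("main", n))
  pair_cov <- vapply(seq_len(n), function(s) {
    v <- c(inner[[s]], inner[[(s %% n) + 1]])
    sd(v) / mean(v)
  }, 0)
  got <- attr(cov_expand(g), "start_pair")
  want <- which.min(pair_cov)
  expect_equal(got, c(want, (want %% n) + 1))
})

test_that("k-means refinement drops the outer intensity population, main walls only", {
  n <- 6
  counts_mat <- matrix(3L, n, 6)
  vals <- list(default = 100)
  for (s in seq_len(n)) for (l in 4:6) vals[[paste(s, l)]] <- 200
  groups <- c(rep("main", 4), rep("lateral", 2))
  g <- fake_grid(counts_mat, vals, groups = groups)
  counts <- rep(6L, n)
  out <- kmeans_refine(g, counts, seed = 3)
  expect_equal(out[1:4], rep(3L, 4))      # outer cluster dropped
  expect_equal(out[5:6], rep(6L, 2))      # lateral untouched
  # uniform region: clustering carries no tissue signal, counts unchanged
  g_u <- fake_grid(counts_mat, list(default = 100), groups = groups)
  set.seed(1)
  g_u$image <- g_u$image + rnorm(length(g_u$image), 0, 2)
  expect_equal(kmeans_refine(g_u, counts, seed = 3), counts)
})

test_that("occupancy correction strips sparse outer layers at 70% but not 40%", {
  counts_mat <- cbind(matrix(3L, 4, 4), c(3L, 3L, 0L, 0L))
  vals <- list(default = 100)
  accepted <- c(5L, 5L, 4L, 4L)
  g_main <- fake_grid(counts_mat, vals, groups = rep("main", 4),
                      sectors = rep("inferoseptal", 4))
  out_main <- correct_false_layers(g_main, accepted)
  expect_equal(out_main, rep(4L, 4))   # 6 px < 70% of 12 px per layer
  g_lat <- fake_grid(counts_mat, vals, groups = rep("lateral", 4),
                     sectors = rep("anterolateral", 4))
  out_lat <- correct_false_layers(g_lat, accepted)
  expect_equal(out_lat, accepted)      # 6 px >= 40% of 12 px
  # fully occupied layers are never touched
  g_full <- fake_grid(matrix(3L, 4, 5), vals, groups = rep("main", 4),
                      sectors = rep("anterior", 4))
  expect_equal(correct_false_layers(g_full, rep(5L, 4)), rep(5L, 4))
})

test_that("neighbour-difference capping matches its brute-force relaxation", {
  expect_equal(limit_neighbor_difference(c(5L, 5L, 9L, 5L, 5L)),
               c(5L, 5L, 7L, 5L, 5L))
  smooth <- c(4L, 5L, 6L, 6L, 5L, 4L)
  expect_equal(limit_neighbor_difference(smooth), smooth)
  set.seed(9)
  for (rep in 1:20) {
    counts <- sample(0:9, 12, replace = TRUE)
    got <- limit_neighbor_difference(counts)
    expect_equal(got, limit_neighbors_bruteforce(counts))
    expect_true(all(got <= counts))
  }
})

test_that("count-reducing stages never increase any accepted count", {
  res <- get_segmented("mid", 45)
  cnt <- attr(res$contours, "counts")
  expect_true(all(cnt$corrected <= cnt$refined))
  expect_true(all(cnt$smoothed <= cnt$corrected))
})

test_that("border optimization enumerates 25 shifts and keeps the clean annulus", {
  res <- get_segmented("basal", 0)
  expect_identical(nrow(res$contours$search), 25L)
  expect_identical(sum(duplicated(res$contours$search[, c("d_endo", "d_epi")])), 0L)
  # on a homogeneous noiseless wall the unshifted annulus wins with no
  # excluded outliers
  expect_equal(unname(res$contours$delta), c(0, 0))
  expect_identical(sum(res$contours$excluded_outliers), 0L)
})

test_that("an overshot pool is corrected by adding one endocardial layer inward", {
  ph <- get_phantom("mid", 0)
  res <- get_segmented("mid", 0)
  lv_over <- res$lvbp
  lv_over$mask <- t2starseg:::dilate1(lv_over$mask)  # pool eats one myo ring
  comp <- res$composite
  contours <- find_myocardial_contours(lv_over, comp, res$rois, "mid",
                                       ph$series$pixel_spacing, seed = 11)
  expect_equal(unname(contours$delta["endo"]), 1)
  expect_gte(dice(contours$myo_mask, ph$truth$myo_mask), 0.9)
})

test_that("endocardial interior is contained in the epicardial interior", {
  for (key in list(c("mid", 45), c("apical", 0))) {
    res <- get_segmented(key[1], as.numeric(key[2]))
    ct <- res$contours
    expect_true(all(ct$epi_mask[ct$endo_mask]))
    expect_false(any(ct$myo_mask & ct$endo_mask))
    expect_false(any(ct$myo_mask & ct$excluded_outliers))
  }
})

test_that("the border chain is deterministic for a fixed seed", {
  ph <- get_phantom("mid", 45)
  cfg <- pipeline_config(seed = 19)
  r1 <- t2starseg:::segment_slice(ph$series, ph$truth$seeds_method2, cfg)
  r2 <- t2starseg:::segment_slice(ph$series, ph$truth$seeds_method2, cfg)
  expect_identical(r1$contours$myo_mask, r2$contours$myo_mask)
  expect_identical(r1$segments, r2$segments)
})
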
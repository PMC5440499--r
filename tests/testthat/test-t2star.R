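te8 <- seq(2.69, by = 2.31, length.out = 8)

test_that("the decay fit inverts noiseless curves exactly", {
  y <- 1000 * exp(-te8 / 20) + 50
  f <- fit_pixel_t2star(y, te8)
  expect_true(f$converged)
  expect_equal(f$k_amp, 1000, tolerance = 1e-6)
  expect_equal(f$t2star, 20, tolerance = 1e-6)
  expect_equal(f$c_offset, 50, tolerance = 1e-6)
  expect_lt(f$rss, 1e-10)
})

test_that("degenerate and invalid fit inputs are handled", {
  f <- fit_pixel_t2star(rep(80, 8), te8)
  expect_false(f$converged)
  expect_equal(f$k_amp, 0)
  expect_error(fit_pixel_t2star(c(1, NA, 3, 4), 1:4), "non-finite")
  expect_error(fit_pixel_t2star(1:3, 1:3), "at least 4")
})

test_that("a constant added to all echoes moves C and leaves T2* unchanged", {
  y <- 900 * exp(-te8 / 25) + 10
  f0 <- fit_pixel_t2star(y, te8)
  f1 <- fit_pixel_t2star(y + 130, te8)
  expect_equal(f1$t2star, f0$t2star, tolerance = 1e-6)
  expect_equal(f1$c_offset, f0$c_offset + 130, tolerance = 1e-4)
})

test_that("the T2* map is exact on the noiseless phantom and respects exclusions", {
  res <- get_segmented("mid", 0)
  ph <- get_phantom("mid", 0)
  map <- res$t2star_map
  myo <- res$contours$myo_mask
  truth <- ph$truth$t2star_true
  common <- myo & !is.na(truth) & !is.na(map$values)
  expect_gt(sum(common), 500)
  expect_lt(max(abs(map$values[common] - truth[common])), 1e-5)
  expect_true(all(is.na(map$values[res$contours$excluded_outliers])))
  expect_true(all(is.na(map$values[!myo])))
  # the reduced-T2* sector boundary is reproduced
  sector_px <- common & truth == 15
  expect_gt(sum(sector_px), 30)
  expect_lt(max(abs(map$values[sector_px] - 15)), 1e-5)
})

test_that("AHA partition yields 6 labels mid/basal and 4 apically", {
  res_mid <- get_segmented("mid", 0)
  ids_mid <- sort(unique(res_mid$aha_labels[!is.na(res_mid$aha_labels)]))
  expect_identical(ids_mid, 7:12)
  res_ap <- get_segmented("apical", 0)
  ids_ap <- sort(unique(res_ap$aha_labels[!is.na(res_ap$aha_labels)]))
  expect_identical(ids_ap, 13:16)
  res_b <- get_segmented("basal", 0)
  ids_b <- sort(unique(res_b$aha_labels[!is.na(res_b$aha_labels)]))
  expect_identical(ids_b, 1:6)
})

test_that("rotating the insertion points rotates the AHA labels equivariantly", {
  mask <- matrix(FALSE, 80, 80)
  for (r in 1:80) for (cc in 1:80) {
    d <- sqrt((r - 40)^2 + (cc - 40)^2)
    if (d >= 14 && d < 20) mask[r, cc] <- TRUE
  }
  ctr <- c(40, 40)
  pt <- function(ang, rad = 20) c(ctr[1] - rad * sin(ang), ctr[2] + rad * cos(ang))
  a0 <- 140 * pi / 180
  lab1 <- partition_aha(mask, pt(a0), pt(a0 + 2 * pi / 3), "mid", lv_center = ctr)
  rot <- pi / 3
  lab2 <- partition_aha(mask, pt(a0 + rot), pt(a0 + rot + 2 * pi / 3), "mid",
                        lv_center = ctr)
  # a pixel rotated by the same angle carries the same label
  idx <- which(mask, arr.ind = TRUE)
  set.seed(2); pick <- idx[sample(nrow(idx), 200), ]
  th <- atan2(-(pick[, 1] - ctr[1]), pick[, 2] - ctr[2])
  rad <- sqrt((pick[, 1] - ctr[1])^2 + (pick[, 2] - ctr[2])^2)
  rot_r <- round(ctr[1] - rad * sin(th + rot))
  rot_c <- round(ctr[2] + rad * cos(th + rot))
  ok <- rot_r >= 1 & rot_r <= 80 & rot_c >= 1 & rot_c <= 80
  ok[ok] <- mask[cbind(rot_r[ok], rot_c[ok])]
  agree <- lab1[pick[ok, , drop = FALSE]] == lab2[cbind(rot_r[ok], rot_c[ok])]
  expect_gt(mean(agree), 0.95)  # boundary pixels may round across a sector edge
  expect_error(partition_aha(mask, pt(a0), pt(a0), "mid", lv_center = ctr),
               "distinct")
})

test_that("segment medians, iron flags and summaries follow their definitions", {
  vals <- matrix(NA_real_, 10, 10)
  labs <- matrix(NA_integer_, 10, 10)
  vals[1, 1:3] <- c(18, 19, 21); labs[1, 1:3] <- 7L
  vals[2, 1:5] <- c(30, 30, 200, 30, 30); labs[2, 1:5] <- 8L
  tab <- segmental_medians(vals, labs, "mid")
  expect_equal(tab$median_t2star_ms[tab$aha_segment_id == 7], 19)
  expect_true(tab$iron_flag[tab$aha_segment_id == 7])
  expect_equal(tab$median_t2star_ms[tab$aha_segment_id == 8], 30)  # robust to one extreme
  expect_false(tab$iron_flag[tab$aha_segment_id == 8])
  expect_true(is.na(tab$median_t2star_ms[tab$aha_segment_id == 9]))
  expect_identical(tab$n_pixels[tab$aha_segment_id == 9], 0L)

  # permutation invariance of the medians
  perm <- sample(which(!is.na(vals)))
  vals2 <- vals; vals2[!is.na(vals)] <- vals[perm]
  labs2 <- labs; labs2[!is.na(labs)] <- labs[perm]
  tab2 <- segmental_medians(vals2, labs2, "mid")
  expect_equal(tab2$median_t2star_ms[tab2$aha_segment_id == 8],
               tab$median_t2star_ms[tab$aha_segment_id == 8])
})

test_that("global and mid-septal summaries average the advertised segments", {
  full <- t2starseg:::aha_segment_table()
  full$median_t2star_ms <- 30; full$n_pixels <- 10L; full$iron_flag <- FALSE
  s <- summarize_t2star(split(full, full$slice_level))
  expect_equal(s$global_t2star, 30)
  expect_equal(s$mid_septal_t2star, 30)
  full$median_t2star_ms[full$aha_segment_id == 8] <- 20
  full$median_t2star_ms[full$aha_segment_id == 9] <- 30
  s2 <- summarize_t2star(split(full, full$slice_level))
  expect_equal(s2$mid_septal_t2star, 25)
  # a missing segment leaves the global undefined and is named
  part <- full[full$aha_segment_id != 5, ]
  expect_warning(s3 <- summarize_t2star(split(part, part$slice_level)), "5")
  expect_true(is.na(s3$global_t2star))
})
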
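#' Fit the monoexponential decay with constant offset to one pixel
#'
#' Fits `y = K * exp(-TE / T2*) + C` by bounded Levenberg-Marquardt nonlinear
#' least squares. The offset term counters the noise-floor bias that makes
#' plain monoexponential fits underestimate T2* at low signal. Initialization
#' comes from a log-linear fit of `y - min(y) + eps` against TE; T2* is
#' bounded to (0.1, 500] ms.
#'
#' @param y signal intensities (one per echo).
#' @param te echo times in ms, same length as `y`, at least 4 points.
#' @return List with `k_amp`, `t2star`, `c_offset`, `rss`, `converged`,
#'   `te_used`, `y_used`.
#' @export
fit_pixel_t2star <- function(y, te) {
  if (length(y) != length(te)) stop("y and te lengths differ")
  if (length(y) < 4) stop("need at least 4 echoes to fit 3 parameters")
  if (any(!is.finite(y)) || any(!is.finite(te))) stop("non-finite input")
  out <- list(k_amp = NA_real_, t2star = NA_real_, c_offset = mean(y),
              rss = NA_real_, converged = FALSE, te_used = te, y_used = y)
  if (stats::sd(y) < 1e-10 * (abs(mean(y)) + 1)) {
    out$k_amp <- 0
    out$rss <- sum((y - mean(y))^2)
    return(out)  # constant signal: degenerate, flagged
  }
  rng <- max(y) - min(y)
  eps <- 0.01 * rng + 1e-12
  ylow <- y - min(y) + eps
  lin <- stats::lm.fit(cbind(1, te), log(ylow))
  slope <- unname(lin$coefficients[2])
  t2_0 <- if (is.finite(slope) && slope < 0) clamp(-1 / slope, 0.5, 400) else 20
  k_0 <- max(exp(unname(lin$coefficients[1])), eps)
  c_0 <- min(y)
  resid_fn <- function(p) y - (p[1] * exp(-te / p[2]) + p[3])
  fit <- try(minpack.lm::nls.lm(
    par = c(k_0, t2_0, c_0), fn = resid_fn,
    lower = c(0, 0.1, -1e8), upper = c(1e9, 500, 1e9),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14)), silent = TRUE)
  if (inherits(fit, "try-error")) return(out)
  p <- unname(fit$par)
  out$k_amp <- p[1]; out$t2star <- p[2]; out$c_offset <- p[3]
  out$rss <- sum(resid_fn(p)^2)
  # estimates that settle on the T2* bounds are reported at the bound
  # (censoring them would bias segment medians low at realistic SNR)
  out$converged <- is.finite(out$rss) && fit$info %in% 1:4
  out
}

#' Pixel-wise T2* map over the myocardium
#'
#' Runs [fit_pixel_t2star()] for every myocardial pixel of the contours
#' (excluded-outlier pixels are omitted from the domain); pixels whose fit
#' fails are flagged and excluded from downstream medians.
#'
#' @param series an [mge_series()].
#' @param contours a `myocardial_contours` object (see [optimize_borders()]),
#'   or any list with a logical `myo_mask`.
#' @return List with `values` (ms matrix, `NA` off-domain), `fit_flags`
#'   (logical matrix, `TRUE` = converged), `n_failed`.
#' @export
build_t2star_map <- function(series, contours) {
  myo <- contours$myo_mask
  if (is.null(myo) || !any(myo)) stop("empty myocardium: nothing to fit")
  d <- series_dim(series)
  if (!identical(dim(myo), d)) stop("myocardium mask shape does not match series")
  te <- series$te_list
  stack <- vapply(series$images, identity, series$images[[1]])
  idx <- which(myo, arr.ind = TRUE)
  values <- matrix(NA_real_, d[1], d[2])
  flags <- matrix(NA, d[1], d[2])
  for (i in seq_len(nrow(idx))) {
    y <- stack[idx[i, 1], idx[i, 2], ]
    f <- fit_pixel_t2star(y, te)
    flags[idx[i, 1], idx[i, 2]] <- f$converged
    if (f$converged) values[idx[i, 1], idx[i, 2]] <- f$t2star
  }
  list(values = values, fit_flags = flags,
       n_failed = sum(!flags[myo]))
}

aha_segment_table <- function() {
  data.frame(
    aha_segment_id = 1:16,
    slice_level = rep(c("basal", "mid", "apical"), c(6, 6, 4)),
    segment_name = c(
      "basal_anterior", "basal_anteroseptal", "basal_inferoseptal",
      "basal_inferior", "basal_inferolateral", "basal_anterolateral",
      "mid_anterior", "mid_anteroseptal", "mid_inferoseptal",
      "mid_inferior", "mid_inferolateral", "mid_anterolateral",
      "apical_anterior", "apical_septal", "apical_inferior", "apical_lateral"),
    stringsAsFactors = FALSE)
}

#' Partition the myocardium into AHA segments
#'
#' Labels myocardial pixels by angle about the LV centroid following the AHA
#' 16-segment model: six 60-degree segments on basal and mid-ventricular
#' slices, four 90-degree segments apically. The anterior insertion point
#' fixes the anterior/anteroseptal (or anterior/septal) boundary; the
#' inferior insertion point determines on which side the septum lies.
#'
#' @param myo_mask logical myocardium mask (or a `myocardial_contours`).
#' @param insertion_anterior,insertion_inferior RV insertion points (row, col).
#' @param slice_level `"apical"`, `"mid"` or `"basal"`.
#' @param lv_center optional LV center; defaults to the mask centroid.
#' @return Integer matrix of AHA segment ids (`NA` off the myocardium).
#' @export
partition_aha <- function(myo_mask, insertion_anterior, insertion_inferior,
                          slice_level, lv_center = NULL) {
  if (is.list(myo_mask)) myo_mask <- myo_mask$myo_mask
  slice_level <- match.arg(slice_level, c("apical", "mid", "basal"))
  if (isTRUE(all.equal(insertion_anterior, insertion_inferior)))
    stop("insertion points must be distinct")
  idx <- which(myo_mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty myocardium mask")
  if (is.null(lv_center)) lv_center <- colMeans(idx)
  th_a <- px_angle(insertion_anterior[1], insertion_anterior[2], lv_center)
  th_i <- px_angle(insertion_inferior[1], insertion_inferior[2], lv_center)
  d_ccw <- (th_i - th_a) %% (2 * pi)
  dir <- if (d_ccw < pi) 1 else -1   # septal rotation sense from the anterior ray
  theta <- px_angle(idx[, 1], idx[, 2], lv_center)
  rel <- (dir * (theta - th_a)) %% (2 * pi)
  if (slice_level == "apical") {
    local <- findInterval(rel, c(0, pi / 2, pi, 3 * pi / 2)) # 1..4
    ids <- c(14L, 15L, 16L, 13L)[local]                      # septal, inf, lat, ant
  } else {
    local <- findInterval(rel, (0:5) * pi / 3)               # 1..6
    base_ids <- c(2L, 3L, 4L, 5L, 6L, 1L)                    # from anteroseptal
    ids <- base_ids[local] + if (slice_level == "mid") 6L else 0L
  }
  labels <- matrix(NA_integer_, nrow(myo_mask), ncol(myo_mask))
  labels[idx] <- ids
  if (!any(!is.na(labels)))
    stop("insertion rays do not intersect the myocardium")
  labels
}

#' Median T2* per AHA segment for one slice
#'
#' The median (not the mean) summarizes each segment to suppress pixel-wise
#' noise and artefact errors; segments whose median is at or below 20 ms are
#' flagged as iron-loaded.
#'
#' @param map result of [build_t2star_map()] (or a values matrix).
#' @param labels AHA label matrix from [partition_aha()].
#' @param slice_level slice level of the labels.
#' @param iron_threshold iron flag threshold in ms.
#' @return Data frame: one row per expected segment of the slice level with
#'   `median_t2star_ms`, `n_pixels`, `iron_flag` (`NA` median for empty
#'   segments).
#' @export
segmental_medians <- function(map, labels, slice_level,
                              iron_threshold = 20) {
  values <- if (is.list(map)) map$values else map
  slice_level <- match.arg(slice_level, c("apical", "mid", "basal"))
  tab <- aha_segment_table()
  tab <- tab[tab$slice_level == slice_level, , drop = FALSE]
  med <- n_px <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    v <- values[!is.na(labels) & labels == tab$aha_segment_id[i]]
    v <- v[!is.na(v)]
    n_px[i] <- length(v)
    med[i] <- if (length(v)) stats::median(v) else NA_real_
  }
  tab$median_t2star_ms <- med
  tab$n_pixels <- as.integer(n_px)
  tab$iron_flag <- ifelse(is.na(med), NA, med <= iron_threshold)
  rownames(tab) <- NULL
  tab
}

#' Global and mid-septal T2* summaries over a complete slice set
#'
#' Global T2* is the unweighted mean of the 16 segment medians; mid-septal
#' T2* is the mean of the mid-anteroseptal and mid-inferoseptal medians
#' (AHA segments 8 and 9).
#'
#' @param seg_tables list of per-slice data frames from [segmental_medians()].
#' @return List with `segments` (combined table), `global_t2star`,
#'   `mid_septal_t2star`. Global is `NA` (with a warning naming the absent
#'   segments) unless all 16 medians are present.
#' @export
summarize_t2star <- function(seg_tables) {
  segments <- do.call(rbind, seg_tables)
  segments <- segments[!duplicated(segments$aha_segment_id), , drop = FALSE]
  segments <- segments[order(segments$aha_segment_id), , drop = FALSE]
  rownames(segments) <- NULL
  have <- segments$aha_segment_id[!is.na(segments$median_t2star_ms)]
  missing <- setdiff(1:16, have)
  if (length(missing)) {
    warning("global T2* undefined; missing segments: ",
            paste(missing, collapse = ", "))
    global <- NA_real_
  } else {
    global <- mean(segments$median_t2star_ms)
  }
  septal <- segments$median_t2star_ms[match(c(8L, 9L), segments$aha_segment_id)]
  mid_septal <- if (anyNA(septal)) NA_real_ else mean(septal)
  list(segments = segments, global_t2star = global,
       mid_septal_t2star = mid_septal)
}
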
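#' Pipeline configuration
#'
#' Bundles the per-stage options with a single global seed from which every
#' stochastic sub-step (clustering restarts, refinements) derives its own
#' reproducible stream.
#'
#' @param method ROI placement method, 1 or 2.
#' @param composite [composite_options()].
#' @param vfc [vfc_params()].
#' @param borders [border_config()].
#' @param k_cluster blood-pool intensity cluster count.
#' @param seed global integer seed.
#' @param save_intermediates write intermediate masks when an output directory
#'   is given.
#' @return List of configuration values.
#' @export
pipeline_config <- function(method = 2L, composite = composite_options(),
                            vfc = vfc_params(), borders = border_config(),
                            k_cluster = 3L, seed = 1L,
                            save_intermediates = FALSE) {
  list(method = as.integer(method), composite = composite, vfc = vfc,
       borders = borders, k_cluster = as.integer(k_cluster),
       seed = as.integer(seed), save_intermediates = save_intermediates)
}

segment_slice <- function(series, seeds, config) {
  place <- if (config$method == 1L) place_rois_method1 else place_rois_method2
  rois <- place(series, seeds, config$composite)
  cnr <- compute_cnr(series, rois, nf = config$composite$nf)
  selection <- select_optimal_tes(cnr, tie_break = config$composite$tie_break)
  composite <- build_composite(series, selection, rois, nf = config$composite$nf)
  seed <- stage_seed(config$seed, paste0(series$slice_level, "-slice"))
  lvbp <- detect_lvbp(series, composite, rois, params = config$vfc,
                      k = config$k_cluster, seed = seed)
  contours <- find_myocardial_contours(lvbp, composite, rois,
                                       series$slice_level,
                                       series$pixel_spacing,
                                       cfg = config$borders, seed = seed)
  map <- build_t2star_map(series, contours)
  labels <- partition_aha(contours$myo_mask, rois$insertion_anterior,
                          rois$insertion_inferior, series$slice_level,
                          lv_center = rois$lv_center)
  seg <- segmental_medians(map, labels, series$slice_level)
  list(series = series, rois = rois, cnr = cnr, selection = selection,
       composite = composite, lvbp = lvbp, contours = contours,
       t2star_map = map, aha_labels = labels, segments = seg)
}

#' Run the full segmentation and T2* quantification pipeline
#'
#' Executes, per slice: ROI placement, CNR-optimal composite generation,
#' LV blood-pool detection, endo/epicardial border search, pixel-wise T2*
#' mapping and AHA segmental medians; then combines the slices into the
#' 16-segment report with global and mid-septal summaries. A failing slice is
#' skipped with a stage-named diagnostic; the remaining slices proceed (the
#' global summary is then undefined).
#'
#' @param slices named list (`apical`, `mid`, `basal`, any subset) of
#'   `list(series =, seeds =)` pairs; series may be [mge_series()] objects or
#'   NIfTI paths, seeds may be `manual_seeds` or JSON paths.
#' @param config [pipeline_config()].
#' @param out_dir optional output directory: segmental report CSV, per-slice
#'   masks (NIfTI), contours (JSON) and a provenance JSON are written there.
#' @return A `t2star_run`: per-slice results (`slices`), the combined
#'   `summary` ([summarize_t2star()]), `errors` (named diagnostics for failed
#'   slices) and the `config`.
#' @export
run_pipeline <- function(slices, config = pipeline_config(), out_dir = NULL) {
  results <- list(); errors <- list()
  for (nm in names(slices)) {
    sl <- slices[[nm]]
    series <- if (is.character(sl$series)) read_mge_series(sl$series) else sl$series
    seeds <- if (is.character(sl$seeds)) read_seeds(sl$seeds) else sl$seeds
    if (is.null(seeds)) {
      errors[[nm]] <- "seeds: missing manual seeds; slice skipped"
      next
    }
    res <- tryCatch(segment_slice(series, seeds, config), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[nm]] <- conditionMessage(res)
      next
    }
    results[[nm]] <- res
  }
  seg_tables <- lapply(results, `[[`, "segments")
  summary <- if (length(seg_tables)) {
    withCallingHandlers(summarize_t2star(seg_tables),
                        warning = function(w) invokeRestart("muffleWarning"))
  } else NULL
  run <- structure(list(slices = results, summary = summary, errors = errors,
                        config = config), class = "t2star_run")
  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(run$summary))
    write_segmental_report(run$summary, file.path(out_dir, "segmental_t2star.csv"))
  for (nm in names(run$slices)) {
    res <- run$slices[[nm]]
    write_mask(res$contours$myo_mask, file.path(out_dir, paste0(nm, "_myo_mask.nii")))
    write_contours(list(endocardium = res$contours$endo_polyline,
                        epicardium = res$contours$epi_polyline),
                   file.path(out_dir, paste0(nm, "_contours.json")),
                   image_dim = dim(res$contours$myo_mask))
    if (isTRUE(run$config$save_intermediates)) {
      write_mask(res$lvbp$mask, file.path(out_dir, paste0(nm, "_lvbp_mask.nii")))
      RNifti::writeNifti(RNifti::asNifti(
        array(ifelse(is.na(res$t2star_map$values), 0, res$t2star_map$values),
              dim = c(dim(res$t2star_map$values), 1))),
        file.path(out_dir, paste0(nm, "_t2star_map.nii")))
    }
  }
  prov <- list(package = "t2starseg",
               version = as.character(utils::packageVersion("t2starseg")),
               seed = run$config$seed, method = run$config$method,
               config = run$config[c("composite", "vfc", "borders", "k_cluster")],
               errors = run$errors)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.t2star_run <- function(x, ...) {
  cat("<t2star_run> ", length(x$slices), " slice(s) segmented",
      if (length(x$errors)) paste0(", ", length(x$errors), " failed"), "\n",
      sep = "")
  if (!is.null(x$summary)) {
    cat("  global T2*:", round(x$summary$global_t2star, 2), "ms;",
        "mid-septal T2*:", round(x$summary$mid_septal_t2star, 2), "ms\n")
  }
  for (nm in names(x$errors)) cat("  [failed] ", nm, ": ", x$errors[[nm]], "\n",
                                  sep = "")
  invisible(x)
}

#' Compare repeated pipeline runs (contour and T2* reproducibility)
#'
#' Computes per-slice Dice coefficients between myocardial masks, Bland-
#' Altman mean difference and limits of agreement plus the test-retest CoV on
#' matched segmental T2* medians between the first two runs, and the
#' two-way random absolute-agreement ICC across all supplied runs (segments
#' as subjects, runs as raters).
#'
#' @param runs list of two or more `t2star_run` objects over the same slices.
#' @return A `repro_report` list: `dsc_values`, `dsc_median`, `dsc_mad`,
#'   `mean_difference`, `loa`, `cov_pct`, `icc`, `n`.
#' @export
compare_runs <- function(runs) {
  if (length(runs) < 2) stop("need at least two runs")
  a <- runs[[1]]; b <- runs[[2]]
  common <- intersect(names(a$slices), names(b$slices))
  if (!length(common)) stop("runs share no successfully segmented slices")
  if (!setequal(names(a$slices), names(b$slices)))
    warning("runs differ in segmented slices; comparing the intersection")
  dsc <- vapply(common, function(nm)
    dice(a$slices[[nm]]$contours$myo_mask, b$slices[[nm]]$contours$myo_mask), 0)
  med_of <- function(run) {
    s <- run$summary$segments
    stats::setNames(s$median_t2star_ms, s$aha_segment_id)
  }
  meds <- lapply(runs, med_of)
  ids <- Reduce(intersect, lapply(meds, names))
  mat <- vapply(meds, function(m) m[ids], numeric(length(ids)))
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  ba <- bland_altman(mat[, 1], mat[, 2])
  mm <- median_mad(dsc)
  rep <- list(dsc_values = dsc, dsc_median = mm[["median"]],
              dsc_mad = mm[["mad"]],
              mean_difference = ba$mean_difference, loa = ba$loa,
              cov_pct = repro_cov(mat[, 1], mat[, 2]),
              icc = if (nrow(mat) >= 2) icc_two_way_random(mat) else NA_real_,
              n = nrow(mat))
  class(rep) <- "repro_report"
  rep
}

#' @export
print.repro_report <- function(x, ...) {
  cat("<repro_report> n =", x$n, "segments\n")
  cat(sprintf("  DSC: %.3f +/- %.3f (median +/- MAD)\n", x$dsc_median, x$dsc_mad))
  cat(sprintf("  T2* mean difference %+.3f ms, LoA %.3f ms, CoV %.2f%%, ICC %.3f\n",
              x$mean_difference, x$loa, x$cov_pct, x$icc))
  invisible(x)
}
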
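#' Multi-gradient-echo series container
#'
#' Holds the echo-time-indexed stack of magnitude images for one short-axis
#' slice, its in-plane pixel spacing and its slice level. Echoes are stored in
#' ascending echo-time order.
#'
#' @param images list of numeric matrices (equal dimensions, non-negative),
#'   one per echo.
#' @param te_list echo times in ms, same length as `images`.
#' @param pixel_spacing in-plane pixel spacing in mm (isotropic assumed).
#' @param slice_level `"apical"`, `"mid"` or `"basal"`.
#' @param scanner_id free-text scanner identifier.
#' @return An object of class `mge_series`.
#' @export
mge_series <- function(images, te_list, pixel_spacing, slice_level,
                       scanner_id = "") {
  slice_level <- match.arg(slice_level, c("apical", "mid", "basal"))
  if (length(images) != length(te_list))
    stop("images and te_list lengths differ (", length(images), " vs ",
         length(te_list), ")")
  if (length(te_list) < 3) stop("an MGE series needs at least 3 echoes")
  dims <- vapply(images, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all echo images must share the same dimensions")
  ord <- order(te_list)
  te_list <- te_list[ord]
  images <- images[ord]
  if (any(diff(te_list) <= 0)) stop("echo times must be distinct")
  if (any(vapply(images, function(im) any(im < 0), TRUE)))
    stop("magnitude images must be non-negative")
  structure(list(images = images, te_list = te_list,
                 pixel_spacing = pixel_spacing, slice_level = slice_level,
                 scanner_id = scanner_id),
            class = "mge_series")
}

#' @export
print.mge_series <- function(x, ...) {
  cat("<mge_series> ", x$slice_level, " slice, ", length(x$te_list),
      " echoes (", round(min(x$te_list), 2), "-", round(max(x$te_list), 2),
      " ms), ", paste(dim(x$images[[1]]), collapse = "x"), " px @ ",
      x$pixel_spacing, " mm\n", sep = "")
  invisible(x)
}

series_dim <- function(series) dim(series$images[[1]])

COORD_CONVENTION <- "pixel-center, 0-based, (row, col)"

#' Write an MGE series as NIfTI + JSON sidecar
#'
#' The echoes become the 4th dimension of a NIfTI-1 volume; acquisition
#' metadata (`te_list_ms`, `pixel_spacing_mm`, `slice_level`, `scanner_id`)
#' goes to a JSON sidecar next to it.
#'
#' @param series an [mge_series()].
#' @param path output path; `.nii` is appended when absent, and the sidecar is
#'   written with extension `.json`.
#' @return The NIfTI path, invisibly.
#' @export
write_mge_series <- function(series, path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii")
  d <- series_dim(series)
  arr <- array(0, dim = c(d[1], d[2], 1, length(series$images)))
  for (i in seq_along(series$images)) arr[, , 1, i] <- series$images[[i]]
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = c(series$pixel_spacing,
                                                     series$pixel_spacing, 1, 1)),
                     path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(te_list_ms = series$te_list,
                            pixel_spacing_mm = series$pixel_spacing,
                            slice_level = series$slice_level,
                            scanner_id = series$scanner_id),
                       sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an MGE series from NIfTI + JSON sidecar
#'
#' Reads a 3D/4D NIfTI volume whose last dimension indexes echoes, together
#' with the JSON sidecar carrying the echo-time list. Echoes are sorted to
#' ascending echo time regardless of on-disk order.
#'
#' @param path path to the `.nii` file (a sidecar with the same stem and
#'   `.json` extension must exist).
#' @return An [mge_series()].
#' @export
read_mge_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(sidecar))
    stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (key in c("te_list_ms", "pixel_spacing_mm", "slice_level")) {
    if (is.null(meta[[key]]))
      stop("sidecar ", sidecar, " is missing required key '", key, "'")
  }
  vol <- RNifti::readNifti(path)
  arr <- as.array(vol)
  if (length(dim(arr)) == 4) arr <- arr[, , 1, , drop = TRUE]
  if (length(dim(arr)) != 3)
    stop("expected a volume with echoes in the last dimension, got dims ",
         paste(dim(arr), collapse = "x"))
  te <- as.numeric(meta$te_list_ms)
  if (dim(arr)[3] != length(te))
    stop("echo count mismatch: volume has ", dim(arr)[3], ", sidecar lists ",
         length(te))
  if (length(te) < 3) stop("fewer than 3 echoes in ", path)
  images <- lapply(seq_len(dim(arr)[3]), function(i) arr[, , i])
  mge_series(images, te_list = te,
             pixel_spacing = as.numeric(meta$pixel_spacing_mm),
             slice_level = meta$slice_level,
             scanner_id = meta$scanner_id %||% "")
}

#' Write/read boolean masks as NIfTI
#'
#' Masks are persisted as 0/1 volumes; the round-trip is lossless.
#'
#' @param mask logical matrix.
#' @param path output path (`.nii` appended when absent).
#' @return `write_mask`: the path, invisibly. `read_mask`: a logical matrix.
#' @export
write_mask <- function(mask, path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) path <- paste0(path, ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask), dim = c(dim(mask), 1))),
                     path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  arr > 0
}

#' Persist contours as JSON polygon lists
#'
#' Vertices are written 0-based in (row, col) pixel-center coordinates; the
#' convention is stated in the file header.
#'
#' @param contours named list of n x 2 matrices (row, col), 1-based in memory.
#' @param path output JSON path.
#' @param image_dim reference image dimensions recorded for shape checking.
#' @return `write_contours`: the path, invisibly; `read_contours`: the named
#'   list of 1-based (row, col) matrices.
#' @export
write_contours <- function(contours, path, image_dim = NULL) {
  payload <- list(coordinate_convention = COORD_CONVENTION,
                  image_dim = image_dim,
                  contours = lapply(contours, function(m) unname(as.matrix(m)) - 1))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(payload$contours, function(m) as.matrix(m) + 1)
}

#' Write manual seeds to JSON / read them back
#'
#' @param seeds a `manual_seeds` list (see [synthesize_seeds()]).
#' @param path JSON path.
#' @return `write_seeds`: the path invisibly; `read_seeds`: a `manual_seeds`.
#' @export
write_seeds <- function(seeds, path) {
  enc <- lapply(unclass(seeds), function(v) {
    if (is.matrix(v)) unname(v) - 1 else if (is.numeric(v) && length(v) == 2 &&
      !is.integer(v)) v - 1 else v
  })
  enc$coordinate_convention <- COORD_CONVENTION
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_seeds
#' @export
read_seeds <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$coordinate_convention <- NULL
  out <- lapply(raw, function(v) {
    if (is.matrix(v)) v + 1
    else if (is.numeric(v) && length(v) == 2) v + 1
    else v
  })
  out$method <- as.integer(out$method)
  class(out) <- "manual_seeds"
  out
}

#' Write the AHA segmental T2* report as CSV
#'
#' One row per AHA segment (16 for a complete apical+mid+basal run) followed
#' by `global` and `mid_septal` summary rows. Missing medians (empty segments)
#' are written as `NA`. Output is deterministic: fixed column order, segments
#' sorted by AHA id.
#'
#' @param seg result of [summarize_t2star()] (or a compatible data frame list).
#' @param path output CSV path.
#' @return The report data frame, invisibly.
#' @export
write_segmental_report <- function(seg, path) {
  tab <- seg$segments
  tab <- tab[order(tab$aha_segment_id), , drop = FALSE]
  summary_rows <- data.frame(
    slice_level = c("all", "mid"),
    aha_segment_id = NA_integer_,
    segment_name = c("global", "mid_septal"),
    median_t2star_ms = c(seg$global_t2star, seg$mid_septal_t2star),
    n_pixels = c(sum(tab$n_pixels), NA_integer_),
    iron_flag = NA)
  out <- rbind(tab[, names(summary_rows)], summary_rows)
  rownames(out) <- NULL
  utils::write.csv(format(out, digits = 10, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(out)
}
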
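#' Dice similarity coefficient of two masks
#'
#' `DSC(A, B) = 2|A n B| / (|A| + |B|)`: 1 for total overlap, 0 for disjoint
#' regions. When both masks are empty the coefficient is defined as 1
#' (vacuous perfect agreement) and a warning is emitted.
#'
#' @param a,b logical matrices of identical dimensions.
#' @return A number in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("mask shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}

#' Bland-Altman mean difference and limits of agreement
#'
#' For paired measurements, `d_i = x_i - y_i`; the limit of agreement is
#' `1.96 * SD(d)` (sample standard deviation).
#'
#' @param x,y numeric vectors of paired measurements (length >= 2).
#' @return List with `mean_difference` and `loa`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  list(mean_difference = mean(d), loa = 1.96 * stats::sd(d))
}

#' Test-retest coefficient of variation (percent)
#'
#' Within-pair RMS convention: `SD_w = sqrt(mean(d_i^2) / 2)` with
#' `d_i = x_i - y_i`, reported as a percentage of the grand mean of all
#' measurements. Scale-invariant; 0 for identical pairs.
#'
#' @param x,y numeric vectors of paired repeated measurements.
#' @return CoV in percent.
#' @export
repro_cov <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  gm <- mean(c(x, y))
  if (gm <= 0) stop("grand mean must be positive for a CoV")
  sd_w <- sqrt(mean((x - y)^2) / 2)
  100 * sd_w / gm
}

#' Two-way random-effects, absolute-agreement, single-measure ICC
#'
#' ICC(2,1) from the two-way ANOVA decomposition with subjects as rows and
#' raters as columns:
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`.
#'
#' @param m numeric matrix, n subjects x k raters, complete.
#' @return The ICC (can be slightly negative by sampling).
#' @export
icc_two_way_random <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  if (anyNA(m)) stop("ICC requires a complete matrix")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  denom <- ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e)
  if (denom <= 0 || (ms_r == 0 && ms_e == 0))
    stop("ICC undefined: no variance in the measurements")
  (ms_r - ms_e) / denom
}

#' Summarize a vector as median +/- median absolute deviation
#' @param x numeric vector.
#' @return Named vector `c(median =, mad =)` (MAD without consistency scaling).
#' @export
median_mad <- function(x) {
  c(median = stats::median(x), mad = stats::median(abs(x - stats::median(x))))
}
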
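#' Parameters of the vector-field-convolution active contour
#'
#' @param kernel_radius radius of the VFC kernel support in pixels.
#' @param gamma magnitude decay exponent of the kernel, `m(r) = (r+eps)^-gamma`.
#' @param epsilon small positive regularizer in the kernel magnitude.
#' @param alpha snake tension (first-derivative smoothness).
#' @param beta snake rigidity (second-derivative smoothness).
#' @param step evolution step size.
#' @param max_iter iteration cap.
#' @param tol stop when the mean vertex displacement per iteration falls below
#'   this many pixels.
#' @param n_vertices number of (uniform arc-length) snake vertices.
#' @return List of parameters.
#' @export
vfc_params <- function(kernel_radius = 32, gamma = 1.7, epsilon = 1e-8,
                       alpha = 0.3, beta = 0.1, step = 0.5, max_iter = 300,
                       tol = 0.05, n_vertices = 100) {
  p <- list(kernel_radius = kernel_radius, gamma = gamma, epsilon = epsilon,
            alpha = alpha, beta = beta, step = step, max_iter = max_iter,
            tol = tol, n_vertices = n_vertices)
  stopifnot(all(unlist(p) > 0), p$tol < 1, p$kernel_radius >= 1)
  p
}

vfc_kernel <- function(params) {
  R <- params$kernel_radius
  off <- -R:R
  i <- matrix(off, 2 * R + 1, 2 * R + 1)                 # row offsets
  j <- matrix(off, 2 * R + 1, 2 * R + 1, byrow = TRUE)   # col offsets
  r <- sqrt(i^2 + j^2)
  m <- (r + params$epsilon)^(-params$gamma)
  m[r > R | r == 0] <- 0
  list(kr = -i / pmax(r, 1e-300) * m, kc = -j / pmax(r, 1e-300) * m)
}

# zero-padded linear convolution via FFT; kernel offsets -R..R
conv_fft <- function(img, kernel, R) {
  H <- nrow(img); W <- ncol(img)
  P1 <- H + 2 * R; P2 <- W + 2 * R
  A <- matrix(0, P1, P2); A[1:H, 1:W] <- img
  B <- matrix(0, P1, P2)
  idx1 <- ((-R:R) %% P1) + 1
  idx2 <- ((-R:R) %% P2) + 1
  B[idx1, idx2] <- kernel
  C <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (P1 * P2)
  C[1:H, 1:W]
}

#' Vector field convolution external-force field
#'
#' Convolves a non-negative edge map with a radially attracting vector kernel
#' `K(x, y) = (r + eps)^-gamma * (-x/r, -y/r)` (zero at the origin and beyond
#' `kernel_radius`), producing a force field that points toward edges with a
#' long capture range. The FFT-based convolution equals direct summation to
#' floating-point accuracy.
#'
#' @param edge non-negative edge-strength matrix.
#' @param params [vfc_params()].
#' @return List with matrices `fr` (row component) and `fc` (col component).
#' @export
vfc_field <- function(edge, params = vfc_params()) {
  if (any(edge < 0)) stop("edge map must be non-negative")
  if (all(edge == 0))
    message("all-zero edge map: VFC field is identically zero")
  k <- vfc_kernel(params)
  list(fr = conv_fft(edge, k$kr, params$kernel_radius),
       fc = conv_fft(edge, k$kc, params$kernel_radius))
}

# periodic pentadiagonal internal-force (stiffness) matrix for n vertices
snake_stiffness <- function(n, alpha, beta) {
  A <- matrix(0, n, n)
  sten <- c(beta, -alpha - 4 * beta, 2 * alpha + 6 * beta, -alpha - 4 * beta, beta)
  for (d in -2:2) {
    idx <- cbind(1:n, ((1:n - 1 + d) %% n) + 1)
    A[idx] <- A[idx] + sten[d + 3]
  }
  A
}

#' Evolve a closed snake under a VFC field
#'
#' Semi-implicit active-contour evolution: the internal (tension/rigidity)
#' forces are handled implicitly through the periodic pentadiagonal stiffness
#' matrix, the external VFC force is interpolated bilinearly at sub-pixel
#' vertex positions. Vertices are resampled to uniform arc length every
#' iteration; evolution stops when the mean vertex displacement drops below
#' `tol` or after `max_iter` iterations.
#'
#' @param init closed polyline (n x 2, row/col), at least 8 vertices.
#' @param field VFC field from [vfc_field()].
#' @param params [vfc_params()].
#' @return The evolved closed polyline (`n_vertices` x 2).
#' @export
evolve_snake <- function(init, field, params = vfc_params()) {
  if (nrow(init) < 8) stop("snake needs at least 8 initial vertices")
  n <- params$n_vertices
  v <- poly_resample(init, n)
  A <- snake_stiffness(n, params$alpha, params$beta)
  M <- solve(diag(n) + params$step * A)
  dims <- dim(field$fr)
  for (it in seq_len(params$max_iter)) {
    fr <- bilinear_interp(field$fr, v)
    fc <- bilinear_interp(field$fc, v)
    v_new <- cbind(M %*% (v[, 1] + params$step * fr),
                   M %*% (v[, 2] + params$step * fc))
    v_new[, 1] <- clamp(v_new[, 1], 1, dims[1])
    v_new[, 2] <- clamp(v_new[, 2], 1, dims[2])
    disp <- mean(sqrt(rowSums((v_new - v)^2)))
    v <- poly_resample(v_new, n)
    if (poly_area(v) < 4)
      stop("active contour collapsed (area < 4 px)")
    if (disp < params$tol) break
  }
  v
}
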
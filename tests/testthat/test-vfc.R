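test_that("a single edge pixel produces the kernel's attracting field", {
  p <- vfc_params(kernel_radius = 8, gamma = 1.7, epsilon = 1e-8)
  edge <- matrix(0, 21, 21); edge[11, 11] <- 1
  f <- vfc_field(edge, p)
  for (d in c(2, 5)) {
    expect_equal(f$fc[11, 11 + d], -(d + p$epsilon)^(-p$gamma), tolerance = 1e-10)
    expect_equal(f$fr[11, 11 + d], 0, tolerance = 1e-12)
    expect_equal(f$fr[11 - d, 11], (d + p$epsilon)^(-p$gamma), tolerance = 1e-10)
  }
  expect_equal(f$fr[11, 11], 0)
  expect_equal(f$fc[11, 11], 0)
})

test_that("the field vanishes at the center of a symmetric circular edge map", {
  p <- vfc_params(kernel_radius = 16)
  edge <- matrix(0, 33, 33)
  for (r in 1:33) for (cc in 1:33) {
    d <- sqrt((r - 17)^2 + (cc - 17)^2)
    if (d >= 9.5 && d < 10.5) edge[r, cc] <- 1
  }
  f <- vfc_field(edge, p)
  expect_lt(abs(f$fr[17, 17]), 1e-10)
  expect_lt(abs(f$fc[17, 17]), 1e-10)
})

test_that("FFT field equals the direct-sum oracle on random small edge maps", {
  p <- vfc_params(kernel_radius = 5)
  set.seed(21)
  for (rep in 1:3) {
    edge <- matrix(runif(16 * 16), 16, 16)
    f <- vfc_field(edge, p)
    o <- vfc_field_bruteforce(edge, p)
    expect_equal(f$fr, o$fr, tolerance = 1e-8)
    expect_equal(f$fc, o$fc, tolerance = 1e-8)
  }
  p32 <- vfc_params(kernel_radius = 9)
  edge <- matrix(rbinom(32 * 32, 1, 0.1) * runif(32 * 32), 32, 32)
  f <- vfc_field(edge, p32)
  o <- vfc_field_bruteforce(edge, p32)
  expect_equal(f$fr, o$fr, tolerance = 1e-8)
  expect_equal(f$fc, o$fc, tolerance = 1e-8)
})

test_that("a snake under zero field shrinks monotonically in perimeter", {
  p <- vfc_params(alpha = 0.3, beta = 0.05, step = 0.5, max_iter = 20,
                  tol = 1e-6, n_vertices = 48)
  zero <- list(fr = matrix(0, 64, 64), fc = matrix(0, 64, 64))
  ang <- seq(0, 2 * pi, length.out = 33)[-33]
  circle <- cbind(32 + 15 * sin(ang), 32 + 15 * cos(ang))
  per <- t2starseg:::poly_perimeter(circle)
  v <- circle
  for (k in 1:4) {
    p_k <- vfc_params(alpha = 0.3, beta = 0.05, step = 0.5, max_iter = 5,
                      tol = 1e-9, n_vertices = 48)
    v <- evolve_snake(v, zero, p_k)
    per_new <- t2starseg:::poly_perimeter(v)
    expect_lt(per_new, per)
    per <- per_new
  }
})

test_that("a snake converges onto a circular edge from 1.5x its radius", {
  edge <- matrix(0, 64, 64)
  for (r in 1:64) for (cc in 1:64) {
    d <- sqrt((r - 32)^2 + (cc - 32)^2)
    if (d >= 9.5 && d < 10.5) edge[r, cc] <- 1
  }
  p <- vfc_params(kernel_radius = 24, max_iter = 400, tol = 0.01,
                  n_vertices = 64)
  f <- vfc_field(edge, p)
  ang <- seq(0, 2 * pi, length.out = 33)[-33]
  init <- cbind(32 + 15 * sin(ang), 32 + 15 * cos(ang))
  v <- evolve_snake(init, f, p)
  radii <- sqrt((v[, 1] - 32)^2 + (v[, 2] - 32)^2)
  expect_lt(abs(mean(radii) - 10), 0.5)
  # initializing on the edge with a loose tolerance returns (about) the init
  p_loose <- vfc_params(kernel_radius = 24, max_iter = 300, tol = 0.5,
                        n_vertices = 32)
  on_edge <- cbind(32 + 10 * sin(ang), 32 + 10 * cos(ang))
  v2 <- evolve_snake(on_edge, f, p_loose)
  expect_lt(max(abs(sqrt((v2[, 1] - 32)^2 + (v2[, 2] - 32)^2) - 10)), 1)
})

test_that("the converged contour is insensitive to the initial vertex count", {
  edge <- matrix(0, 64, 64)
  for (r in 1:64) for (cc in 1:64) {
    d <- sqrt((r - 32)^2 + (cc - 32)^2)
    if (d >= 9.5 && d < 10.5) edge[r, cc] <- 1
  }
  ang16 <- seq(0, 2 * pi, length.out = 17)[-17]
  ang64 <- seq(0, 2 * pi, length.out = 65)[-65]
  masks <- lapply(list(ang16, ang64), function(a) {
    init <- cbind(32 + 14 * sin(a), 32 + 14 * cos(a))
    p <- vfc_params(kernel_radius = 24, max_iter = 400, tol = 0.01)
    v <- evolve_snake(init, vfc_field(edge, p), p)
    t2starseg:::fill_polygon(v, c(64, 64))
  })
  expect_gte(dice(masks[[1]], masks[[2]]), 0.98)
})

test_that("degenerate snake inputs are rejected", {
  p <- vfc_params(max_iter = 50, n_vertices = 16)
  zero <- list(fr = matrix(0, 32, 32), fc = matrix(0, 32, 32))
  expect_error(evolve_snake(cbind(c(1, 2, 3), c(1, 2, 3)), zero, p),
               "at least 8")
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  tiny <- cbind(16 + 1.2 * sin(ang), 16 + 1.2 * cos(ang))
  p_shrink <- vfc_params(alpha = 2, step = 1, max_iter = 200, tol = 1e-9,
                         n_vertices = 16)
  expect_error(evolve_snake(tiny, zero, p_shrink), "collapsed")
})
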
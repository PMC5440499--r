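# Shared fixtures: phantoms and segmentation runs are deterministic for a
# given spec, so they are generated once per session and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

get_phantom <- function(level = "mid", sigma = 0) {
  cached(paste0("ph_", level, "_", sigma),
         generate_phantom(default_phantom_spec(level, noise_sigma = sigma)))
}

get_segmented <- function(level = "mid", sigma = 0, method = 2L) {
  cached(paste0("seg_", level, "_", sigma, "_m", method), {
    ph <- get_phantom(level, sigma)
    seeds <- if (method == 1L) ph$truth$seeds_method1 else ph$truth$seeds_method2
    t2starseg:::segment_slice(ph$series, seeds,
                              pipeline_config(method = method, seed = 11L))
  })
}

get_composite_stage <- function(level = "mid", sigma = 0) {
  cached(paste0("comp_", level, "_", sigma), {
    ph <- get_phantom(level, sigma)
    rois <- place_rois_method2(ph$series, ph$truth$seeds_method2)
    cnr <- compute_cnr(ph$series, rois)
    sel <- select_optimal_tes(cnr)
    list(rois = rois, cnr = cnr, selection = sel,
         composite = build_composite(ph$series, sel, rois))
  })
}

# exhaustive-search optimum of 1D k=2 squared-error clustering (optimal 1D
# clusters are contiguous in sorted order)
best_split_inertia <- function(values) {
  v <- sort(values)
  n <- length(v)
  best <- Inf
  for (cut in 1:(n - 1)) {
    a <- v[1:cut]; b <- v[(cut + 1):n]
    inertia <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    best <- min(best, inertia)
  }
  best
}

# direct-summation VFC field oracle (double loop over kernel offsets)
vfc_field_bruteforce <- function(edge, params) {
  R <- params$kernel_radius
  H <- nrow(edge); W <- ncol(edge)
  fr <- matrix(0, H, W); fc <- matrix(0, H, W)
  for (r in 1:H) for (c in 1:W) {
    for (i in -R:R) for (j in -R:R) {
      rr <- r - i; cc <- c - j
      if (rr < 1 || rr > H || cc < 1 || cc > W) next
      d <- sqrt(i^2 + j^2)
      if (d == 0 || d > R) next
      m <- (d + params$epsilon)^(-params$gamma)
      fr[r, c] <- fr[r, c] + edge[rr, cc] * (-i / d) * m
      fc[r, c] <- fc[r, c] + edge[rr, cc] * (-j / d) * m
    }
  }
  list(fr = fr, fc = fc)
}

# brute-force relaxation oracle for the neighbour-difference cap
limit_neighbors_bruteforce <- function(counts, d = 2) {
  n <- length(counts)
  repeat {
    changed <- FALSE
    for (s in seq_len(n)) {
      for (nb in c((s %% n) + 1, ((s - 2) %% n) + 1)) {
        if (counts[s] - counts[nb] > d) {
          counts[s] <- counts[nb] + d
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  counts
}

# fabricate a minimal radial_layer_grid for unit tests of the count rules
fake_grid <- function(counts_mat, image_values, groups, sectors = NULL) {
  n_seg <- nrow(counts_mat); n_lay <- ncol(counts_mat)
  cells <- lapply(seq_len(n_seg), function(s) vector("list", n_lay))
  img <- c()
  idx <- 0L
  means <- matrix(NA_real_, n_seg, n_lay)
  for (s in seq_len(n_seg)) for (l in seq_len(n_lay)) {
    k <- counts_mat[s, l]
    if (k > 0) {
      vals <- rep(image_values[[paste(s, l)]] %||%
                    image_values[["default"]], length.out = k)
      cells[[s]][[l]] <- idx + seq_len(k)
      img <- c(img, vals)
      means[s, l] <- mean(vals)
      idx <- idx + k
    }
  }
  structure(list(n_segments = n_seg, n_layers = n_lay, cells = cells,
                 counts = counts_mat, means = means,
                 centroid = c(0, 0), seg_group = groups,
                 seg_sector = sectors %||% groups,
                 image = matrix(img, ncol = 1), slice_level = "mid"),
            class = "radial_layer_grid")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a complete 16-segment summary with one deliberately empty segment (id 16)
aha_report_fixture <- function() {
  tab <- t2starseg:::aha_segment_table()
  tab$median_t2star_ms <- c(seq(22, 52, by = 2))
  tab$n_pixels <- 50L
  tab$iron_flag <- tab$median_t2star_ms <= 20
  tab$median_t2star_ms[16] <- NA_real_
  tab$n_pixels[16] <- 0L
  tab$iron_flag[16] <- NA
  tabs <- split(tab, tab$slice_level)
  suppressWarnings(summarize_t2star(tabs))
}
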
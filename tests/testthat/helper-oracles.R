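# Brute-force reference implementations, kept deliberately independent of
# the package's code paths: contour tracing, hull, distance transform and
# morphological openings are re-derived from first principles here.

# --- independent Moore-neighbour boundary trace ------------------------------
# Returns the ordered boundary-pixel centres of the single foreground
# component, walking the 8-neighbourhood clockwise from the backtrack
# direction (classic Moore tracing with Jacob's stopping criterion relaxed
# to first-return for these simple fixtures).
oracle_trace_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  # start: first foreground pixel in column-major order, entered from the left
  start <- which(mask)[1]
  r0 <- (start - 1) %% nr + 1; c0 <- (start - 1) %/% nr + 1
  # neighbour offsets clockwise starting west
  off <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
               c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  path <- matrix(c(r0, c0), ncol = 2)
  prev_dir <- 1 # came from west
  cur <- c(r0, c0)
  repeat {
    found <- FALSE
    for (s in 0:7) {
      d <- (prev_dir - 1 + s) %% 8 + 1
      cand <- cur + off[d, ]
      if (at(cand[1], cand[2])) {
        # backtrack direction: neighbour before the found one
        back <- (d - 2) %% 8 + 1
        prev_dir <- (back + 3) %% 8 + 1 # direction from cand towards backtrack cell, rotated
        # recompute properly: direction of previous cell relative to cand
        rel <- cur + off[back, ] - cand
        prev_dir <- which(apply(off, 1, function(o) all(o == rel)))
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break # isolated pixel
    if (all(cur == c(r0, c0))) break
    path <- rbind(path, cur)
    if (nrow(path) > 8 * (nr * nc)) stop("runaway trace")
  }
  # pixel centres in (x, y) with the same half-pixel convention as the package
  cbind(x = path[, 2] - 0.5, y = path[, 1] - 0.5)
}

oracle_smooth_closed <- function(poly, window = 3) {
  n <- nrow(poly)
  if (n < 2 * window) return(poly)
  half <- window %/% 2
  t(vapply(seq_len(n), function(i) {
    j <- ((i - half - 1):(i + half - 1)) %% n + 1
    colMeans(poly[j, , drop = FALSE])
  }, numeric(2)))
}

oracle_closed_length <- function(poly) {
  nxt <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - poly)^2)))
}

# --- exhaustive (gift-wrapping) convex hull ----------------------------------
oracle_hull_area <- function(points) {
  pts <- unique(points)
  n <- nrow(pts)
  start <- which.min(pts[, 2] + 1e-9 * pts[, 1])
  hull <- start
  cur <- start
  dir_prev <- c(1, 0)
  repeat {
    best <- NULL; best_ang <- Inf; best_d <- -Inf
    p <- pts[cur, ]
    for (j in seq_len(n)) {
      if (j == cur) next
      v <- pts[j, ] - p
      ang <- atan2(v[2], v[1]) - atan2(dir_prev[2], dir_prev[1])
      ang <- ang %% (2 * pi)
      d <- sqrt(sum(v^2))
      if (ang < best_ang - 1e-12 ||
          (abs(ang - best_ang) <= 1e-12 && d > best_d)) {
        best <- j; best_ang <- ang; best_d <- d
      }
    }
    v <- pts[best, ] - p
    dir_prev <- v
    cur <- best
    if (cur == hull[1]) break
    hull <- c(hull, cur)
    if (length(hull) > n + 1) stop("hull runaway")
  }
  hp <- pts[hull, , drop = FALSE]
  x <- hp[, 1]; y <- hp[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# --- brute-force Euclidean distance transform --------------------------------
# distance of each foreground pixel to the nearest background pixel,
# exhaustively over the background rim (background pixels 8-adjacent to
# foreground, which contains every minimiser for these fixtures), plus the
# frame border when the object touches it (fixtures avoid that).
oracle_median_radius <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  # restrict to the background rim for tractability
  rim <- bg[vapply(seq_len(nrow(bg)), function(i) {
    r <- bg[i, 1]; c <- bg[i, 2]
    any(mask[max(1, r - 1):min(nr, r + 1), max(1, c - 1):min(nc, c + 1)])
  }, logical(1)), , drop = FALSE]
  d <- vapply(seq_len(nrow(fg)), function(i) {
    sqrt(min((rim[, 1] - fg[i, 1])^2 + (rim[, 2] - fg[i, 2])^2))
  }, numeric(1))
  median(d)
}

oracle_shape_features <- function(mask) {
  area <- sum(mask)
  poly <- oracle_smooth_closed(oracle_trace_boundary(mask))
  perimeter <- oracle_closed_length(poly)
  idx <- which(mask, arr.ind = TRUE)
  px <- idx[, 2] - 0.5; py <- idx[, 1] - 0.5
  corners <- cbind(c(px - 0.5, px + 0.5, px - 0.5, px + 0.5),
                   c(py - 0.5, py - 0.5, py + 0.5, py + 0.5))
  hull_area <- oracle_hull_area(corners)
  msd <- mean((px - mean(px))^2 + (py - mean(py))^2)
  list(area = area, perimeter = perimeter,
       form_factor = 4 * pi * area / perimeter^2,
       compactness = 2 * pi * msd / area,
       solidity = area / hull_area,
       median_radius = oracle_median_radius(mask))
}

# --- brute-force grayscale opening granulometry ------------------------------
oracle_disc_offsets <- function(radius) {
  sz <- 2L * as.integer(radius) + 1L
  b <- EBImage::makeBrush(sz, shape = "disc") # same structuring element spec
  w <- which(b == 1, arr.ind = TRUE)
  cbind(w[, 1] - (radius + 1), w[, 2] - (radius + 1))
}

oracle_minmax_filter <- function(img, offs, fun) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rr <- r + offs[, 1]; cc <- c + offs[, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    # out-of-frame treated as 0 for erosion padding parity with the package
    vals <- if (all(ok)) img[cbind(rr, cc)] else c(img[cbind(rr[ok], cc[ok])], 0)
    out[r, c] <- fun(vals)
  }
  out
}

oracle_opening <- function(img, radius) {
  offs <- oracle_disc_offsets(radius)
  er <- oracle_minmax_filter(img, offs, min)
  oracle_minmax_filter(er, offs, max)
}

oracle_granularity <- function(img, mask, n_scales) {
  masked <- img * mask
  total <- sum(masked)
  prev <- masked
  vals <- numeric(n_scales)
  for (k in seq_len(n_scales)) {
    op <- oracle_opening(masked, k) * mask
    vals[k] <- 100 * (sum(prev) - sum(op)) / total
    prev <- op
  }
  vals
}

# --- full-eigendecomposition PCA weighting oracle ----------------------------
oracle_pca_weights <- function(X, threshold = 0.90, scale = TRUE) {
  Xs <- scale(X, center = TRUE, scale = scale)
  S <- crossprod(Xs) / (nrow(Xs) - 1)
  e <- eigen(S, symmetric = TRUE)
  a <- e$values / sum(e$values)
  k <- which(cumsum(a) >= threshold - 1e-12)[1]
  raw <- as.numeric(abs(e$vectors[, seq_len(k), drop = FALSE]) %*% a[seq_len(k)])
  raw / sum(raw)
}

# --- random blob fixture -----------------------------------------------------
random_blob_mask <- function(seed, size = 72, radius = 18) {
  spec <- image_spec(width = size, height = size, radius = radius,
                     boundary_roughness = 0.25, seed = seed)
  segment_spheroid(make_spheroid_image(spec)$image)
}

# small multi-compound screen used by robustness / recovery checks
make_screen_table <- function(seed, ic50s = c(50, 150, 500, 1500, 4000),
                              noise_cv = 10, outlier_rate = 0) {
  tabs <- lapply(seq_along(ic50s), function(i) {
    scn <- dose_scenario(feature_specs = default_feature_specs(true_ic50 = ic50s[i]),
                         noise_cv = noise_cv, outlier_rate = outlier_rate,
                         compound = paste0("CPD", i), seed = seed * 1000L + i)
    make_dose_tables(scn)$features
  })
  dplyr::bind_rows(tabs)
}
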
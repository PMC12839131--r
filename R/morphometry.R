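# Single-spheroid segmentation and CellProfiler-compatible morphometry.
# One object per frame is the assay design: segmentation is a global Otsu
# threshold, largest connected component, holes filled. Shape descriptors
# follow CellProfiler conventions so native tables and CellProfiler CSV
# exports are interchangeable downstream.

as_ebimage <- function(img) {
  # internal matrices are row = y, col = x; EBImage stores x in dim 1
  EBImage::Image(t(img))
}

#' Segment the single spheroid in a brightfield frame
#'
#' Global Otsu threshold, retain the largest connected component
#' (8-connectivity), fill interior holes. Polarity is configurable because
#' brightfield spheroids may appear bright on dark or dark on bright.
#'
#' @param image Numeric matrix (row = y, col = x) with finite values;
#'   grey levels are rescaled to \[0, 1\] internally.
#' @param polarity `"bright"` if the object is brighter than the
#'   background, `"dark"` otherwise.
#' @return Object of class `spheroid_mask`: list with `mask` (logical
#'   matrix), `pixel_size` (um/px, default 1).
#' @export
segment_spheroid <- function(image, polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  if (!is.matrix(image) || !all(is.finite(image))) {
    abort("`image` must be a numeric matrix of finite values")
  }
  rng <- range(image)
  if (diff(rng) == 0) abort("empty segmentation: image is uniform")
  img01 <- (image - rng[1]) / diff(rng)
  if (polarity == "dark") img01 <- 1 - img01

  thr <- EBImage::otsu(as_ebimage(img01), range = c(0, 1))
  fg <- img01 > thr
  if (!any(fg)) abort("empty segmentation: no foreground after thresholding")

  lab <- EBImage::bwlabel(as_ebimage(fg * 1))
  labm <- t(EBImage::imageData(lab))
  sizes <- tabulate(labm[labm > 0])
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1) {
    # deterministic tie-break: component whose topmost-leftmost pixel comes
    # first in row-major order
    firsts <- vapply(biggest, function(b) which(t(labm) == b)[1], numeric(1))
    warn("multiple equal-size largest components; keeping the topmost-leftmost")
    biggest <- biggest[which.min(firsts)]
  }
  keep <- labm == biggest
  filled <- EBImage::fillHull(as_ebimage(keep * 1))
  mask <- t(EBImage::imageData(filled)) > 0

  structure(list(mask = mask, pixel_size = 1), class = "spheroid_mask")
}

check_mask <- function(mask) {
  if (!inherits(mask, "spheroid_mask")) abort("expected a `spheroid_mask`")
  if (!any(mask$mask)) abort("mask is empty")
  invisible(mask)
}

# Ordered boundary polygon through boundary-pixel centres (Moore contour via
# EBImage::ocontour); perimeter is its closed polygonal length, the
# CellProfiler-compatible convention (not a raw boundary-pixel count).
boundary_polygon <- function(mask) {
  oc <- EBImage::ocontour(as_ebimage(mask$mask * 1))[[1]]
  # ocontour returns 0-based (x, y); shift to pixel centres
  cbind(x = oc[, 1] + 0.5, y = oc[, 2] + 0.5)
}

polygon_length <- function(poly) {
  nxt <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - poly)^2)))
}

# Circular moving average of a closed contour. A 3-point window removes the
# pixel staircase so the perimeter of a digitised disc approaches 2*pi*r
# (raw chain length overestimates it by ~5%) while barely rounding true
# corners (a 200 px square loses ~1.5%).
smooth_contour <- function(poly, window = 3) {
  n <- nrow(poly)
  if (n < 2 * window) return(poly)
  half <- window %/% 2
  out <- poly
  for (i in seq_len(n)) {
    j <- ((i - half - 1):(i + half - 1)) %% n + 1
    out[i, ] <- colMeans(poly[j, , drop = FALSE])
  }
  out
}

shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Shape features of a segmented spheroid
#'
#' CellProfiler-convention descriptors:
#' * `area`: foreground pixel count (px^2);
#' * `perimeter`: closed boundary-polygon length through boundary-pixel
#'   centres, de-staircased by a 3-point circular moving average so a
#'   digitised disc measures close to `2 * pi * r` (px);
#' * `form_factor`: `4 * pi * area / perimeter^2` (1 for a circle);
#' * `solidity`: area / convex-hull area, the hull taken over pixel
#'   corners so the ratio never exceeds 1;
#' * `compactness`: mean squared pixel distance from the centroid
#'   normalised so a filled circle scores 1 (`2 * pi * msd / area`);
#' * `median_radius`: median of the Euclidean distance transform over
#'   foreground pixels (px).
#'
#' @param mask A `spheroid_mask` from [segment_spheroid()].
#' @return One-row tibble with the six features.
#' @export
shape_features <- function(mask) {
  check_mask(mask)
  m <- mask$mask
  area <- sum(m)

  poly <- smooth_contour(boundary_polygon(mask))
  perimeter <- polygon_length(poly)
  if (perimeter == 0) perimeter <- 4 # single pixel: treat as unit square
  form_factor <- 4 * pi * area / perimeter^2

  idx <- which(m, arr.ind = TRUE) # (row = y, col = x) pixel indices
  px <- idx[, 2] - 0.5; py <- idx[, 1] - 0.5
  corners <- cbind(x = c(px - 0.5, px + 0.5, px - 0.5, px + 0.5),
                   y = c(py - 0.5, py - 0.5, py + 0.5, py + 0.5))
  hull <- corners[grDevices::chull(corners), , drop = FALSE]
  solidity <- area / shoelace_area(hull)

  cx <- mean(px); cy <- mean(py)
  msd <- mean((px - cx)^2 + (py - cy)^2)
  compactness <- 2 * pi * msd / area

  dm <- t(EBImage::imageData(EBImage::distmap(as_ebimage(m * 1))))
  median_radius <- median(dm[m])

  tibble(area = area, perimeter = perimeter, form_factor = form_factor,
         compactness = compactness, solidity = solidity,
         median_radius = median_radius)
}

disc_brush <- function(radius) {
  # odd-sized disc structuring element of given radius (pixel centres)
  sz <- 2L * as.integer(radius) + 1L
  EBImage::makeBrush(sz, shape = "disc")
}

#' Granularity spectrum by iterative grayscale opening
#'
#' Granulometry restricted to the spheroid mask: the image is opened with
#' disc structuring elements of radius 1, 2, ..., `n_scales`; the spectrum
#' value at scale k is the percentage of the initial in-mask signal removed
#' by step k,
#' `value_k = 100 * (signal_(k-1) - signal_k) / signal_0`.
#'
#' @param image Numeric matrix (same frame the mask came from).
#' @param mask A `spheroid_mask`.
#' @param n_scales Number of opening scales (default 16, matching common
#'   CellProfiler settings).
#' @param subsample Integer down-sampling factor applied to image and mask
#'   before the openings (default 1 = none).
#' @return Object of class `granularity_spectrum`: list with `scales`,
#'   `values` (percent of total initial signal removed per scale) and
#'   `kept_indices` (filled by [filter_granularity()], initially all).
#' @export
granularity_spectrum <- function(image, mask, n_scales = 16, subsample = 1) {
  check_mask(mask)
  if (n_scales < 1) abort("n_scales must be >= 1")
  m <- mask$mask
  img <- image
  if (subsample > 1) {
    s <- as.integer(subsample)
    ri <- seq(1, nrow(img), by = s); ci <- seq(1, ncol(img), by = s)
    img <- img[ri, ci, drop = FALSE]
    m <- m[ri, ci, drop = FALSE]
    if (!any(m)) abort("mask is empty after subsampling")
  }
  masked <- img * m
  total <- sum(masked)
  if (total <= 0) abort("no in-mask signal to analyse")

  values <- numeric(n_scales)
  prev <- masked
  for (k in seq_len(n_scales)) {
    opened <- t(EBImage::imageData(
      EBImage::opening(as_ebimage(masked), disc_brush(k))))
    opened <- opened * m
    values[k] <- 100 * (sum(prev) - sum(opened)) / total
    prev <- opened
  }
  structure(list(scales = seq_len(n_scales), values = values,
                 kept_indices = seq_len(n_scales)),
            class = "granularity_spectrum")
}

#' Filter a granularity spectrum by the relative 5% rule
#'
#' Scales whose value falls below `rel_threshold` times the maximum
#' spectrum value are treated as background / minor brightness fluctuation
#' and dropped; the arg-max scale is always kept. An all-zero spectrum
#' keeps nothing (with a warning).
#'
#' @param spec A `granularity_spectrum`.
#' @param rel_threshold Fraction of the maximum amplitude (default 0.05).
#' @return The spectrum with `kept_indices` updated.
#' @export
filter_granularity <- function(spec, rel_threshold = 0.05) {
  stopifnot(inherits(spec, "granularity_spectrum"))
  v <- spec$values
  if (length(v) == 0) abort("empty spectrum")
  mx <- max(v)
  if (mx <= 0) {
    warn("all-zero granularity spectrum; no scales kept")
    spec$kept_indices <- integer(0)
    return(spec)
  }
  keep <- which(v >= rel_threshold * mx)
  keep <- sort(union(keep, which.max(v)))
  spec$kept_indices <- keep
  spec
}

#' Extract a CellProfiler-style feature row from one image
#'
#' Segments the frame, computes the six shape features and the filtered
#' granularity spectrum, and returns them under CellProfiler column names
#' (`AreaShape_*`, `Granularity_k`).
#'
#' @param image Numeric matrix.
#' @param polarity Passed to [segment_spheroid()].
#' @param n_scales,rel_threshold Granularity settings.
#' @return One-row tibble.
#' @export
extract_image_features <- function(image, polarity = "bright",
                                   n_scales = 16, rel_threshold = 0.05) {
  mask <- segment_spheroid(image, polarity)
  shp <- shape_features(mask)
  names(shp) <- c("AreaShape_Area", "AreaShape_Perimeter",
                  "AreaShape_FormFactor", "AreaShape_Compactness",
                  "AreaShape_Solidity", "AreaShape_MedianRadius")
  gs <- suppressWarnings(
    filter_granularity(granularity_spectrum(image, mask, n_scales),
                       rel_threshold))
  if (length(gs$kept_indices) == 0) return(shp)
  gran <- as_tibble(setNames(as.list(gs$values[gs$kept_indices]),
                             paste0("Granularity_", gs$kept_indices)))
  dplyr::bind_cols(shp, gran)
}

#' Extract features for a directory of spheroid images
#'
#' Reads TIFF/PNG frames, parses well metadata from each file name and
#' binds one feature row per image.
#'
#' @param dir Directory of grayscale `.tif`/`.png` frames.
#' @param pattern Filename metadata pattern, see [parse_filename()].
#' @param ... Passed to [extract_image_features()].
#' @return Feature table tibble (metadata + feature columns).
#' @export
extract_plate_features <- function(dir, pattern = default_filename_pattern(), ...) {
  files <- list.files(dir, pattern = "\\.(tiff?|png)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0) abort("no TIFF/PNG images found")
  rows <- map(files, function(f) {
    meta <- parse_filename(basename(f), pattern)
    img <- EBImage::readImage(f)
    if (length(dim(img)) > 2) img <- img[, , 1]
    dplyr::bind_cols(as_tibble(meta[c("cell_line", "compound",
                                      "concentration", "replicate")]),
                     extract_image_features(t(EBImage::imageData(img)), ...))
  })
  list_rbind(rows)
}
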
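# Synthetic spheroid images and dose-structured tables with known ground
# truth. The generator encodes the study conditions the pipeline assumes:
# one spheroid per frame, ten-point half-log dose ladders with zero-dose
# controls, triplicates, monotone sigmoidal per-feature responses with
# feature-specific directionality, lognormal multiplicative noise and
# occasional gross outliers.

#' Default ten-point half-log concentration ladder (nM)
#'
#' Zero-dose control plus nine half-log steps from 1 nM to 10 uM.
#'
#' @return Numeric vector of ten concentrations in nM, including 0.
#' @export
default_concentrations <- function() {
  c(0, round(10^seq(0, 4, by = 0.5), 3))
}

#' Default per-feature response specification
#'
#' Six morphometric features with mixed response directions: size-type
#' features (area, perimeter, median radius) fall with dose, shape-type
#' features (form factor, compactness, solidity) rise as spheroids
#' disintegrate. Plateaus are expressed as fraction-of-control: a
#' decreasing feature bottoms out at 0.2 x control, an increasing one at
#' 1.8 x control.
#'
#' @param true_ic50 Midpoint concentration in nM shared by all features.
#' @param hill Hill slope (dimensionless), shared by all features.
#' @return Tibble with columns `feature`, `direction`, `true_ic50`, `hill`,
#'   `top`, `bottom`.
#' @export
default_feature_specs <- function(true_ic50 = 500, hill = 1.2) {
  tibble(
    feature = c("AreaShape_Area", "AreaShape_Perimeter", "AreaShape_MedianRadius",
                "AreaShape_FormFactor", "AreaShape_Compactness", "AreaShape_Solidity"),
    direction = c("decreasing", "decreasing", "decreasing",
                  "increasing", "increasing", "increasing"),
    true_ic50 = true_ic50,
    hill = hill,
    top = 1,
    bottom = c(0.2, 0.2, 0.2, 1.8, 1.8, 1.8)
  )
}

#' Dose scenario for the synthetic screen generator
#'
#' @param concentrations Concentrations in nM; must contain exactly one 0
#'   (the control) and positive doses.
#' @param n_replicates Technical replicates per concentration (default 3).
#' @param feature_specs Tibble as returned by [default_feature_specs()]:
#'   one row per feature with `direction` ("decreasing"/"increasing"),
#'   `true_ic50` (nM, > 0), `hill`, and plateaus `top`/`bottom` as
#'   fraction-of-control.
#' @param noise_cv Multiplicative lognormal noise, as percent CV (>= 0).
#' @param outlier_rate Probability that a triplicate receives one injected
#'   gross outlier (one replicate multiplied by a factor drawn uniformly
#'   from \[3, 5\]).
#' @param cell_line,compound Labels carried into the metadata columns.
#' @param seed Integer seed; identical seeds give identical output.
#' @return Object of class `dose_scenario`.
#' @export
dose_scenario <- function(concentrations = default_concentrations(),
                          n_replicates = 3,
                          feature_specs = default_feature_specs(),
                          noise_cv = 10,
                          outlier_rate = 0,
                          cell_line = "SYN1",
                          compound = "CPD1",
                          seed = 1L) {
  if (sum(concentrations == 0) != 1) {
    abort("`concentrations` must include exactly one zero-dose control")
  }
  if (any(concentrations < 0)) abort("concentrations must be >= 0")
  if (any(feature_specs$true_ic50 <= 0)) abort("true_ic50 must be > 0")
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  if (outlier_rate < 0 || outlier_rate > 1) abort("outlier_rate must be in [0, 1]")
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  structure(
    list(concentrations = sort(unique(concentrations)),
         n_replicates = as.integer(n_replicates),
         feature_specs = as_tibble(feature_specs),
         noise_cv = noise_cv, outlier_rate = outlier_rate,
         cell_line = cell_line, compound = compound, seed = as.integer(seed)),
    class = "dose_scenario"
  )
}

# 4PL expectation: f(0) = top exactly, f(ic50) = (top + bottom)/2,
# f(Inf) = bottom. "Increasing" features simply have bottom > top.
fourpl_expect <- function(conc, top, bottom, ic50, hill) {
  ifelse(conc == 0, top, bottom + (top - bottom) / (1 + (conc / ic50)^hill))
}

lognormal_factor <- function(n, cv_percent) {
  if (cv_percent == 0) return(rep(1, n))
  cv <- cv_percent / 100
  sdlog <- sqrt(log(1 + cv^2))
  # meanlog chosen so the multiplicative factor has mean 1
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic feature table and fluorescence table for a scenario
#'
#' Every feature follows a four-parameter logistic expectation in its stated
#' direction around a control value of 1; triplicates receive lognormal
#' multiplicative noise at `noise_cv` percent; with probability
#' `outlier_rate` per (feature, concentration) triplicate one replicate is
#' multiplied by a factor in \[3, 5\]. The fluorescence table mimics a
#' resazurin-type viability readout (decreasing, control about 50,000 RFU).
#'
#' @param scn A [dose_scenario()].
#' @return List with elements `features` (well-level tibble: metadata plus
#'   one column per feature), `fluorescence` (tibble: concentration,
#'   replicate, rfu), and `truth` (list: `feature_specs`, `outliers` tibble
#'   of injected positions, `fluor_ic50`).
#' @export
make_dose_tables <- function(scn) {
  stopifnot(inherits(scn, "dose_scenario"))
  withr_seed <- scn$seed
  set.seed(withr_seed)
  conc <- scn$concentrations
  reps <- seq_len(scn$n_replicates)
  grid <- tidyr::expand_grid(concentration = conc, replicate = reps)

  feats <- scn$feature_specs
  outlog <- list()
  cols <- list()
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    mu <- fourpl_expect(grid$concentration, f$top, f$bottom, f$true_ic50, f$hill)
    val <- mu * lognormal_factor(nrow(grid), scn$noise_cv)
    # outlier injection per triplicate
    for (cc in conc) {
      if (runif(1) < scn$outlier_rate) {
        idx <- which(grid$concentration == cc)
        hit <- sample(idx, 1)
        fac <- runif(1, 3, 5)
        val[hit] <- val[hit] * fac
        outlog[[length(outlog) + 1]] <- tibble(
          feature = f$feature, concentration = cc,
          replicate = grid$replicate[hit], factor = fac)
      }
    }
    cols[[f$feature]] <- val
  }

  features <- dplyr::bind_cols(
    tibble(cell_line = scn$cell_line, compound = scn$compound),
    grid, as_tibble(cols))

  fluor_ic50 <- feats$true_ic50[1]
  mu_rfu <- fourpl_expect(grid$concentration, 1, 0.1, fluor_ic50, 1.2) * 5e4
  fluorescence <- tibble(
    cell_line = scn$cell_line, compound = scn$compound,
    concentration = grid$concentration, replicate = grid$replicate,
    rfu = mu_rfu * lognormal_factor(nrow(grid), scn$noise_cv))

  truth <- list(
    feature_specs = feats,
    outliers = if (length(outlog)) list_rbind(outlog) else
      tibble(feature = character(), concentration = numeric(),
             replicate = integer(), factor = numeric()),
    fluor_ic50 = fluor_ic50)

  list(features = features, fluorescence = fluorescence, truth = truth)
}

#' Image specification for the synthetic spheroid renderer
#'
#' @param width,height Frame size in pixels.
#' @param radius Nominal spheroid radius in pixels; must fit in the frame.
#' @param boundary_roughness Amplitude of the radial boundary perturbation,
#'   in \[0, 1): 0 gives an exact disc.
#' @param texture_grain Characteristic internal speckle half-width in
#'   pixels (the granulometry spectrum of the interior peaks near this
#'   opening radius); 0 gives a uniform interior.
#' @param fg_intensity,bg_intensity Foreground / background grey levels in
#'   \[0, 1\].
#' @param noise_sd Additive Gaussian noise SD in grey-level units.
#' @param dark_object If `TRUE`, render a dark spheroid on a bright field
#'   (brightfield polarity varies between setups).
#' @param seed Integer seed.
#' @return Object of class `image_spec`.
#' @export
image_spec <- function(width = 256, height = 256, radius = 50,
                       boundary_roughness = 0, texture_grain = 0,
                       fg_intensity = 0.8, bg_intensity = 0.1,
                       noise_sd = 0, dark_object = FALSE, seed = 1L) {
  if (radius >= min(width, height) / 2) {
    abort("radius must be smaller than half the frame size")
  }
  if (radius <= 0 || width < 8 || height < 8) abort("invalid image dimensions")
  ints <- c(fg_intensity, bg_intensity)
  if (any(ints < 0 | ints > 1)) abort("intensities must lie in [0, 1]")
  if (boundary_roughness < 0 || boundary_roughness >= 1) {
    abort("boundary_roughness must lie in [0, 1)")
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         radius = radius, boundary_roughness = boundary_roughness,
         texture_grain = texture_grain, fg_intensity = fg_intensity,
         bg_intensity = bg_intensity, noise_sd = noise_sd,
         dark_object = isTRUE(dark_object), seed = as.integer(seed)),
    class = "image_spec"
  )
}

#' Render one synthetic spheroid image
#'
#' Draws a single connected disc-like object with an optionally perturbed
#' boundary (random low-order harmonics of amplitude `boundary_roughness`),
#' optional internal speckle of characteristic size `texture_grain`, and
#' additive Gaussian noise. The analytic area of the rendered region is
#' returned alongside so segmentation accuracy can be tested against truth.
#'
#' @param spec An [image_spec()].
#' @return List with `image` (height x width numeric matrix in \[0, 1\],
#'   row = y), and `truth` (list: `area` in px^2 from the radial boundary
#'   function, `radius`, `centre` = (x, y), `dark_object`).
#' @export
make_spheroid_image <- function(spec) {
  stopifnot(inherits(spec, "image_spec"))
  set.seed(spec$seed)
  w <- spec$width; h <- spec$height
  cx <- w / 2; cy <- h / 2

  # radial boundary function R(theta) = r * (1 + roughness * p(theta)),
  # p a random 3-harmonic perturbation normalised to max |p| = 1
  if (spec$boundary_roughness > 0) {
    kh <- 3:5
    amp <- runif(3, 0.3, 1); ph <- runif(3, 0, 2 * pi)
    pfun <- function(theta) {
      v <- rowSums(vapply(1:3, function(i) amp[i] * cos(kh[i] * theta + ph[i]),
                          numeric(length(theta))))
      v / max(abs(rowSums(vapply(1:3, function(i)
        amp[i] * cos(kh[i] * seq(0, 2 * pi, length.out = 2048) + ph[i]),
        numeric(2048)))))
    }
  } else {
    pfun <- function(theta) rep(0, length(theta))
  }
  rad <- function(theta) spec$radius * (1 + spec$boundary_roughness * pfun(theta))

  xs <- matrix(rep(seq_len(w) - 0.5, each = h), nrow = h)
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), nrow = h)
  dx <- xs - cx; dy <- ys - cy
  theta <- atan2(dy, dx)
  inside <- sqrt(dx^2 + dy^2) <= matrix(rad(as.vector(theta)), nrow = h)

  img <- matrix(spec$bg_intensity, nrow = h, ncol = w)
  img[inside] <- spec$fg_intensity

  if (spec$texture_grain > 0) {
    # speckle cells of side 2g so bright patches have half-width ~g px and
    # the granulometry spectrum peaks near opening radius g
    g <- max(1, round(2 * spec$texture_grain))
    nr <- ceiling(h / g); nc <- ceiling(w / g)
    coarse <- matrix(rnorm(nr * nc, 0, 0.15), nr, nc)
    fine <- coarse[ceiling(seq_len(h) / g), ceiling(seq_len(w) / g), drop = FALSE]
    img[inside] <- pmin(1, pmax(0, img[inside] + fine[inside]))
  }
  if (spec$noise_sd > 0) {
    img <- img + matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
  }
  img <- pmin(pmax(img, 0), 1)
  if (spec$dark_object) img <- 1 - img

  # analytic area of the region bounded by R(theta): (1/2) int R^2 dtheta
  th <- seq(0, 2 * pi, length.out = 4096 + 1)[-1]
  true_area <- 0.5 * sum(rad(th)^2) * (2 * pi / 4096)

  list(image = img,
       truth = list(area = true_area, radius = spec$radius,
                    centre = c(cx, cy), dark_object = spec$dark_object))
}

#' Construct well file names for a scenario
#'
#' Names round-trip losslessly through [parse_filename()] with the same
#' pattern.
#'
#' @param scn A [dose_scenario()].
#' @param template A [sprintf()]-style template with `{cell_line}`,
#'   `{compound}`, `{conc}` (nM, integer if whole) and `{rep}` placeholders.
#' @param ext File extension.
#' @return Character vector, one name per well.
#' @export
make_plate_filenames <- function(scn,
                                 template = "{cell_line}_{compound}_{conc}nM_r{rep}",
                                 ext = ".tif") {
  stopifnot(inherits(scn, "dose_scenario"))
  needed <- c("{cell_line}", "{compound}", "{conc}", "{rep}")
  miss <- needed[!vapply(needed, function(p) grepl(p, template, fixed = TRUE), logical(1))]
  if (length(miss) > 0) {
    abort(paste0("filename template is missing placeholder(s): ",
                 paste(miss, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(concentration = scn$concentrations,
                             replicate = seq_len(scn$n_replicates))
  fmt_conc <- vapply(grid$concentration, function(x)
    format(x, trim = TRUE, scientific = FALSE, drop0trailing = TRUE),
    character(1))
  out <- template
  out <- stringr::str_replace_all(out, stringr::fixed("{cell_line}"), scn$cell_line)
  out <- stringr::str_replace_all(out, stringr::fixed("{compound}"), scn$compound)
  out <- vapply(seq_len(nrow(grid)), function(i) {
    s <- stringr::str_replace_all(out, stringr::fixed("{conc}"), fmt_conc[i])
    stringr::str_replace_all(s, stringr::fixed("{rep}"), as.character(grid$replicate[i]))
  }, character(1))
  paste0(out, ext)
}

#' Write a synthetic plate to disk (images + truth sidecar)
#'
#' Convenience wrapper used by the command-line interface: renders one image
#' per well name and writes a JSON truth sidecar.
#'
#' @param scn A [dose_scenario()].
#' @param dir Output directory.
#' @param image_args Extra arguments passed to [image_spec()].
#' @return Invisibly, the vector of written file paths.
#' @export
write_synthetic_plate <- function(scn, dir, image_args = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  names <- make_plate_filenames(scn)
  paths <- file.path(dir, names)
  for (i in seq_along(paths)) {
    sp <- do.call(image_spec, c(list(seed = scn$seed + i), image_args))
    img <- make_spheroid_image(sp)$image
    EBImage::writeImage(EBImage::Image(t(img)), paths[i], type = "tiff",
                        bits.per.sample = 16L)
  }
  truth <- make_dose_tables(scn)$truth
  jsonlite::write_json(
    list(feature_specs = truth$feature_specs, outliers = truth$outliers),
    file.path(dir, "truth.json"), dataframe = "rows", auto_unbox = TRUE)
  invisible(paths)
}
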